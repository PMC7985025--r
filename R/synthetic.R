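#' Synthetic cohort specification
#'
#' Parameters of the fully synthetic H&E-like cohort used to exercise the
#' pipeline without clinical data. Grade is the only image-generating
#' factor: per-grade nuclear size (with pleomorphism as the diameter
#' coefficient of variation), nucleolus probability, central necrosis for
#' high-grade solid ducts, and cribriform lumina for low grade.
#'
#' Lesion grades are drawn hierarchically: a patient-level grade from
#' `patient_grade_priors`, then lesion grades conditionally with
#' downward-adjacent spill solved so that the lesion-level marginal equals
#' `grade_priors` exactly. The defaults reproduce the grade margins of a
#' reference clinical cohort at both levels (152/645/204 of 1001 lesions;
#' 7/24/19 of 50 patients) and keep the patient-level maximum rule
#' consistent with the drawn patient grade.
#'
#' @param n_patients Number of patients.
#' @param lesions_per_patient Integer range `c(lo, hi)`; lesion counts are
#'   uniform on it (default 5-30, mirroring the reported mean of about 20).
#' @param grade_priors Target lesion-level grade marginal (sums to 1).
#' @param patient_grade_priors Patient-level grade distribution (sums to 1).
#' @param observer_error Probability epsilon that a simulated observer
#'   reports an adjacent grade instead of the true one; in \[0, 0.5).
#' @param image_params Per-grade rendering parameters; see Details.
#' @param small_lesion_fraction Fraction of lesions rendered below the
#'   512-px patch size to exercise the padding path.
#' @param seed Integer seed; the generated dataset is byte-identical for a
#'   fixed spec.
#'
#' @details `image_params` is a list with per-grade (length-3) entries
#' `nuclear_diameter_um` (mean nuclear diameter, strictly increasing with
#' grade), `diameter_cv` (pleomorphism), `nucleolus_prob`, `necrosis_prob`
#' (non-decreasing with grade), `cribriform_lumina` (count of punched-out
#' lumina), plus scalars `nuclei_density_per_px2`, `resolution` (um/px of
#' the rendered image, 0.88 = x10), `duct_box_px` (side range of regular
#' lesions) and `small_box_px` (side range of deliberately small lesions).
#'
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 60L,
                           lesions_per_patient = c(5L, 30L),
                           grade_priors = c(152, 645, 204) / 1001,
                           patient_grade_priors = c(7, 24, 19) / 50,
                           observer_error = 0.15,
                           image_params = default_image_params(),
                           small_lesion_fraction = 0.15,
                           seed = 1L) {
  stopifnot(n_patients >= 1, length(lesions_per_patient) == 2L,
            lesions_per_patient[1] >= 1,
            lesions_per_patient[2] >= lesions_per_patient[1])
  if (abs(sum(grade_priors) - 1) > 1e-8 || any(grade_priors < 0))
    stop("grade_priors must be non-negative and sum to 1")
  if (abs(sum(patient_grade_priors) - 1) > 1e-8 || any(patient_grade_priors < 0))
    stop("patient_grade_priors must be non-negative and sum to 1")
  if (observer_error < 0 || observer_error >= 0.5)
    stop("observer_error must be in [0, 0.5)")
  ip <- image_params
  if (any(diff(ip$nuclear_diameter_um) <= 0))
    stop("nuclear diameter must be strictly increasing with grade")
  if (any(diff(ip$necrosis_prob) < 0))
    stop("necrosis probability must be non-decreasing with grade")
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 grade_priors = grade_priors,
                 patient_grade_priors = patient_grade_priors,
                 observer_error = observer_error,
                 image_params = ip,
                 small_lesion_fraction = small_lesion_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_image_params <- function() {
  list(nuclear_diameter_um = c(7, 9.5, 13),
       diameter_cv = c(0.10, 0.18, 0.30),
       nucleolus_prob = c(0.05, 0.25, 0.70),
       necrosis_prob = c(0, 0.10, 0.60),
       cribriform_lumina = c(4L, 1L, 0L),
       nuclei_density_per_px2 = 0.003,
       resolution = 0.88,
       duct_box_px = c(520L, 700L),
       small_box_px = c(300L, 480L))
}

# Conditional lesion-grade distribution per patient grade such that the
# lesion marginal matches `lesion_priors` given `patient_priors`, spilling
# downward to adjacent grades only (grade-1 patients carry only grade-1
# lesions; grade-2/3 patients keep as many lesions at the patient grade as
# the marginal allows).
solve_lesion_mixture <- function(patient_priors, lesion_priors) {
  pi_ <- patient_priors; m <- lesion_priors
  p33 <- m[3] / pi_[3]
  if (p33 > 1 + 1e-9)
    stop("infeasible priors: more grade-3 lesions than grade-3 patients can carry")
  p33 <- min(p33, 1)
  if (pi_[2] <= m[2]) {
    p22 <- 1
    p32 <- (m[2] - pi_[2]) / pi_[3]
  } else {
    p22 <- m[2] / pi_[2]
    p32 <- 0
  }
  p31 <- 1 - p33 - p32
  if (p31 < -1e-9)
    stop("infeasible priors: grade-3 patients cannot absorb the grade-2 deficit")
  mix <- rbind(c(1, 0, 0),
               c(1 - p22, p22, 0),
               c(max(p31, 0), p32, p33))
  mix / rowSums(mix)
}

#' Render a synthetic grade-dependent lesion image
#'
#' Renders, at the working resolution (0.88 um/px by default), an
#' eosin-pink stromal background, a duct ellipse, hematoxylin-purple
#' elliptical nuclei with the grade's diameter distribution, optional dark
#' nucleoli, cribriform white lumina (low grade), and a central pale
#' necrosis core (high grade, with its configured probability). The duct
#' outline, slightly inflated so it encloses every rendered duct pixel, is
#' returned as the lesion annotation in level-0 (x40) pixel coordinates.
#' Deterministic under `set.seed()`.
#'
#' @param true_grade Grade in \{1, 2, 3\} driving the phenotype.
#' @param image_params See [default_image_params()].
#' @param size_px Side length of the rendered image (pixels at the working
#'   resolution); default drawn from `image_params$duct_box_px`.
#' @param lesion_id,slide_id Identifiers stored on the outputs.
#' @param base_magnification,target_magnification Magnification of the
#'   annotation coordinate system vs the rendered image (default x40 vs
#'   x10, i.e. annotation coordinates are 4x the image pixels).
#' @return List with `image` (a [lesion_image()]), `annotation` (a
#'   [lesion_annotation()]) and `nuclei` (data frame of rendered nuclei:
#'   center, diameter in pixels — the generator's own mask measurements).
#' @export
generate_lesion_image <- function(true_grade, image_params = default_image_params(),
                                  size_px = NULL, lesion_id = "L1",
                                  slide_id = "S1", base_magnification = 40,
                                  target_magnification = 10) {
  stopifnot(true_grade %in% 1:3)
  ip <- image_params
  g <- as.integer(true_grade)
  if (is.null(size_px))
    size_px <- sample(ip$duct_box_px[1]:ip$duct_box_px[2], 1L)
  H <- W <- as.integer(size_px)
  scale0 <- base_magnification / target_magnification

  # stroma background: eosin pink with shared luminance noise
  noise <- matrix(stats::rnorm(H * W, 0, 5), H, W)
  px <- array(0, c(H, W, 3L))
  bg <- c(235, 186, 209)
  for (c in 1:3) px[, , c] <- bg[c] + noise

  # duct ellipse
  cx <- W / 2 + stats::runif(1, -0.03, 0.03) * W
  cy <- H / 2 + stats::runif(1, -0.03, 0.03) * H
  a <- 0.40 * W * stats::runif(1, 0.85, 1)
  b <- 0.40 * H * stats::runif(1, 0.85, 1)
  th <- stats::runif(1, 0, pi)
  X <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  Y <- matrix(rep(seq_len(H) - 0.5, W), H, W)
  u <- cos(th) * (X - cx) + sin(th) * (Y - cy)
  v <- -sin(th) * (X - cx) + cos(th) * (Y - cy)
  duct <- (u / a)^2 + (v / b)^2 <= 1
  cyto <- c(219, 181, 207)
  for (c in 1:3) {
    ch <- px[, , c]
    ch[duct] <- cyto[c] + noise[duct]
    px[, , c] <- ch
  }

  keepout <- !duct  # nuclei must fall inside the duct, outside lumina/necrosis

  # central necrosis core (solid high-grade ducts)
  if (stats::runif(1) < ip$necrosis_prob[g]) {
    core <- (u / (0.45 * a))^2 + (v / (0.45 * b))^2 +
      matrix(stats::rnorm(H * W, 0, 0.15), H, W) <= 1
    core <- core & duct
    necro <- c(229, 204, 189)
    for (c in 1:3) {
      ch <- px[, , c]
      ch[core] <- necro[c] + noise[core]
      px[, , c] <- ch
    }
    keepout <- keepout | core
  }

  # cribriform lumina (punched-out holes, low grade)
  n_lum <- ip$cribriform_lumina[g]
  if (n_lum > 0) {
    for (k in seq_len(n_lum)) {
      phi <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 0.15, 0.55)
      lcx <- cx + r * a * cos(phi) * cos(th) - r * b * sin(phi) * sin(th)
      lcy <- cy + r * a * cos(phi) * sin(th) + r * b * sin(phi) * cos(th)
      lr <- stats::runif(1, 0.10, 0.16) * min(a, b)
      lum <- ((X - lcx)^2 + (Y - lcy)^2 <= lr^2) & duct
      white <- c(247, 243, 246)
      for (c in 1:3) {
        ch <- px[, , c]
        ch[lum] <- white[c] + noise[lum]
        px[, , c] <- ch
      }
      keepout <- keepout | lum
    }
  }

  # nuclei: constant areal density, grade-dependent diameter distribution
  d_px <- ip$nuclear_diameter_um[g] / ip$resolution
  cv <- ip$diameter_cv[g]
  duct_area <- sum(duct)
  n_nuc <- max(1L, round(ip$nuclei_density_per_px2 * duct_area))
  sdlog <- sqrt(log(1 + cv^2))
  nx <- numeric(0); ny <- numeric(0)
  tries <- 0L
  while (length(nx) < n_nuc && tries < 20L) {
    need <- n_nuc - length(nx)
    candx <- stats::runif(2 * need, cx - a, cx + a)
    candy <- stats::runif(2 * need, cy - b, cy + b)
    ii <- clamp(ceiling(candy), 1, H); jj <- clamp(ceiling(candx), 1, W)
    ok <- !keepout[cbind(ii, jj)]
    nx <- c(nx, candx[ok]); ny <- c(ny, candy[ok])
    tries <- tries + 1L
  }
  if (length(nx) > n_nuc) { nx <- nx[seq_len(n_nuc)]; ny <- ny[seq_len(n_nuc)] }
  diam <- stats::rlnorm(length(nx), log(d_px) - sdlog^2 / 2, sdlog)
  aspect <- stats::runif(length(nx), 0.65, 1)
  rot <- stats::runif(length(nx), 0, pi)
  has_nucleolus <- stats::runif(length(nx)) < ip$nucleolus_prob[g]
  shade <- stats::rnorm(length(nx), 0, 10)
  base_nuc <- c(94, 66, 148)
  for (i in seq_along(nx)) {
    ra <- diam[i] / 2
    rb <- ra * aspect[i]
    r <- ceiling(ra) + 1L
    i0 <- max(1L, floor(ny[i]) - r); i1 <- min(H, ceiling(ny[i]) + r)
    j0 <- max(1L, floor(nx[i]) - r); j1 <- min(W, ceiling(nx[i]) + r)
    if (i1 < i0 || j1 < j0) next
    xs <- (j0:j1) - 0.5 - nx[i]
    ys <- (i0:i1) - 0.5 - ny[i]
    lu <- outer(ys, xs, function(yy, xx) cos(rot[i]) * xx + sin(rot[i]) * yy)
    lv <- outer(ys, xs, function(yy, xx) -sin(rot[i]) * xx + cos(rot[i]) * yy)
    m <- (lu / ra)^2 + (lv / rb)^2 <= 1
    if (!any(m)) next
    for (c in 1:3) {
      blk <- px[i0:i1, j0:j1, c]
      blk[m] <- base_nuc[c] + shade[i]
      px[i0:i1, j0:j1, c] <- blk
    }
    if (has_nucleolus[i]) {
      mn <- (lu / (0.28 * ra))^2 + (lv / (0.28 * rb))^2 <= 1
      if (any(mn)) {
        dark <- c(42, 28, 72)
        for (c in 1:3) {
          blk <- px[i0:i1, j0:j1, c]
          blk[mn] <- dark[c]
          px[i0:i1, j0:j1, c] <- blk
        }
      }
    }
  }
  # (values are clamped to [0, 255] by the lesion_image constructor)

  # duct outline (inflated 5%) as the annotation polygon, level-0 coordinates
  phi <- seq(0, 2 * pi, length.out = 33L)[-33L]
  ex <- cx + 1.05 * a * cos(phi) * cos(th) - 1.05 * b * sin(phi) * sin(th)
  ey <- cy + 1.05 * a * cos(phi) * sin(th) + 1.05 * b * sin(phi) * cos(th)
  poly <- cbind(pmax(ex, 0), pmax(ey, 0)) * scale0
  ann <- lesion_annotation(lesion_id, slide_id, poly)
  img <- lesion_image(px, resolution = ip$resolution, origin = c(0, 0),
                      lesion_id = lesion_id)
  nuclei <- data.frame(x = nx, y = ny, diameter_px = diam, aspect = aspect)
  list(image = img, annotation = ann, nuclei = nuclei)
}

#' Simulate three noisy observers
#'
#' Each observer independently reports the true grade with probability
#' `1 - epsilon` and an adjacent grade otherwise; grade-2 errors split
#' evenly between grades 1 and 3 (disagreement by two grade points never
#' occurs, matching the rarity of grade 1-vs-3 disagreement in practice).
#'
#' @param true_grade Grade in \{1, 2, 3\}.
#' @param epsilon Error probability in \[0, 0.5).
#' @return Integer vector of three observer grades.
#' @export
simulate_observers <- function(true_grade, epsilon = 0.15) {
  stopifnot(true_grade %in% 1:3, epsilon >= 0, epsilon < 0.5)
  vapply(1:3, function(o) {
    if (stats::runif(1) >= epsilon) return(as.integer(true_grade))
    if (true_grade == 1L) 2L
    else if (true_grade == 3L) 2L
    else if (stats::runif(1) < 0.5) 1L else 3L
  }, integer(1))
}

#' Generate a synthetic cohort on disk
#'
#' Draws patients, lesions, images and simulated observer grades from a
#' [synthetic_spec()] and writes, under `dir`: `images/<lesion_id>.png`,
#' `annotations/<slide_id>.xml` (ASAP dialect), `grades.csv` (three
#' observers per lesion), `truth.csv` (lesion_id, slide_id, patient_id,
#' true_grade), `patients.csv` (patient-level truth, consensus and lesion
#' counts) and `spec.yaml`. The patient-level true grade is the maximum
#' lesion true grade. Fully reproducible: the same spec (including seed)
#' produces a byte-identical dataset.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created).
#' @param keep_images Also return the rendered [lesion_image()]s in memory
#'   (stored as compact 8-bit arrays).
#' @param write_images Write per-lesion PNGs (disable to speed up runs that
#'   only need grades/annotations).
#' @return Invisibly, a manifest list: `dir`, data frames `truth`, `grades`,
#'   `patients`, the per-slide annotation lists, and (if `keep_images`)
#'   `images`, a named list of lesion images.
#' @export
generate_cohort <- function(spec, dir, keep_images = FALSE,
                            write_images = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  old <- local_rng_seed(spec$seed)
  on.exit(restore_rng(old))
  mix <- solve_lesion_mixture(spec$patient_grade_priors, spec$grade_priors)
  ip <- spec$image_params
  truth <- list(); grades <- list(); patients <- list()
  annotations <- list(); images <- list()
  lesion_counter <- 0L
  for (p in seq_len(spec$n_patients)) {
    patient_id <- sprintf("P%03d", p)
    slide_id <- sprintf("S%03d", p)
    gp <- sample.int(3L, 1L, prob = spec$patient_grade_priors)
    n_les <- sample(spec$lesions_per_patient[1]:spec$lesions_per_patient[2], 1L)
    slide_anns <- list()
    obs_patient <- matrix(0L, n_les, 3L)
    true_g <- integer(n_les)
    for (l in seq_len(n_les)) {
      lesion_counter <- lesion_counter + 1L
      lesion_id <- sprintf("%s_L%04d", slide_id, lesion_counter)
      g <- sample.int(3L, 1L, prob = mix[gp, ])
      true_g[l] <- g
      small <- stats::runif(1) < spec$small_lesion_fraction
      rng <- if (small) ip$small_box_px else ip$duct_box_px
      size <- sample(rng[1]:rng[2], 1L)
      les <- generate_lesion_image(g, ip, size_px = size,
                                   lesion_id = lesion_id, slide_id = slide_id)
      obs <- simulate_observers(g, spec$observer_error)
      obs_patient[l, ] <- obs
      slide_anns[[l]] <- les$annotation
      truth[[lesion_counter]] <- data.frame(
        lesion_id = lesion_id, slide_id = slide_id, patient_id = patient_id,
        true_grade = g, stringsAsFactors = FALSE)
      grades[[lesion_counter]] <- data.frame(
        lesion_id = lesion_id, observer1 = obs[1], observer2 = obs[2],
        observer3 = obs[3], stringsAsFactors = FALSE)
      if (write_images)
        write_image(lesion_pixels(les$image),
                    file.path(dir, "images", paste0(lesion_id, ".png")))
      if (keep_images) images[[lesion_id]] <- les$image
    }
    write_asap_annotations(slide_anns,
                           file.path(dir, "annotations", paste0(slide_id, ".xml")))
    annotations[[slide_id]] <- slide_anns
    cons <- consensus_labels(do.call(rbind, grades[(lesion_counter - n_les + 1L):lesion_counter]))
    patients[[p]] <- data.frame(
      patient_id = patient_id, slide_id = slide_id, n_lesions = n_les,
      true_grade = max(true_g),
      consensus_grade = max(cons$grade), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  grades <- do.call(rbind, grades)
  patients <- do.call(rbind, patients)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  write_grade_table(grades, file.path(dir, "grades.csv"))
  utils::write.csv(patients, file.path(dir, "patients.csv"), row.names = FALSE,
                   quote = FALSE)
  yaml::write_yaml(spec_to_list(spec), file.path(dir, "spec.yaml"))
  invisible(list(dir = dir, truth = truth, grades = grades,
                 patients = patients, annotations = annotations,
                 images = if (keep_images) images else NULL))
}

spec_to_list <- function(spec) {
  x <- unclass(spec)
  x$image_params <- lapply(x$image_params, function(v) as.numeric(v))
  x
}

#' Load a synthetic cohort from disk
#'
#' Reads back the dataset written by [generate_cohort()]: the grade and
#' truth tables, the patient manifest, per-slide annotations, and (on
#' demand) the lesion images.
#'
#' @param dir Cohort directory.
#' @param load_images Read the per-lesion PNGs into [lesion_image()]s.
#' @return List with `truth`, `grades`, `patients`, `annotations` and
#'   optionally `images`.
#' @export
load_cohort <- function(dir, load_images = FALSE) {
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  grades <- read_grade_table(file.path(dir, "grades.csv"))
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  spec <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  ann_files <- list.files(file.path(dir, "annotations"), full.names = TRUE)
  annotations <- lapply(ann_files, function(f)
    parse_asap_annotations(f, slide_id = tools::file_path_sans_ext(basename(f))))
  names(annotations) <- tools::file_path_sans_ext(basename(ann_files))
  images <- NULL
  if (load_images) {
    res <- spec$image_params$resolution %||% 0.88
    images <- lapply(truth$lesion_id, function(id)
      lesion_image(read_image(file.path(dir, "images", paste0(id, ".png"))),
                   resolution = res, lesion_id = id))
    names(images) <- truth$lesion_id
  }
  list(truth = truth, grades = grades, patients = patients,
       annotations = annotations, images = images, spec = spec)
}
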