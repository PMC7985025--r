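test_that("lesion rendering is deterministic under a fixed seed", {
  ip <- tiny_image_params()
  set.seed(31); a <- generate_lesion_image(2, ip, size_px = 100)
  set.seed(31); b <- generate_lesion_image(2, ip, size_px = 100)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$annotation$polygon, b$annotation$polygon)
})

test_that("rendered nuclear size increases strictly with grade", {
  ip <- tiny_image_params()
  set.seed(32)
  diam <- function(g) unlist(replicate(40, {
    generate_lesion_image(g, ip, size_px = 120)$nuclei$diameter_px
  }, simplify = FALSE))
  d1 <- diam(1); d2 <- diam(2); d3 <- diam(3)
  expect_lt(stats::t.test(d1, d2, alternative = "less")$p.value, 1e-6)
  expect_lt(stats::t.test(d2, d3, alternative = "less")$p.value, 1e-6)
  expect_lt(mean(d1), mean(d2))
  expect_lt(mean(d2), mean(d3))
})

test_that("generated annotations enclose the duct and round-trip through ASAP XML", {
  ip <- tiny_image_params()
  set.seed(33)
  les <- generate_lesion_image(1, ip, size_px = 110, lesion_id = "rt",
                               slide_id = "s9")
  back <- parse_asap_annotations(write_asap_annotations(list(les$annotation)),
                                 "s9")
  expect_identical(back[[1]]$polygon, les$annotation$polygon)
  # polygon coordinates are level-0 (x4 the rendered pixels)
  expect_lte(max(les$annotation$polygon), 110 * 4)
  # all rendered nuclei fall inside the annotation polygon (scaled back to x10)
  poly <- les$annotation$polygon / 4
  nuc <- les$nuclei
  inside <- vapply(seq_len(nrow(nuc)), function(i) {
    point_in_polygon(nuc$x[i], nuc$y[i], poly)
  }, logical(1))
  expect_true(all(inside))
})

test_that("simulated observers follow the adjacent-error model", {
  set.seed(34)
  # epsilon = 0: always the true grade, hence unanimous consensus
  for (g in 1:3) {
    obs <- simulate_observers(g, 0)
    expect_identical(obs, rep(as.integer(g), 3))
    lab <- consensus_grade(obs)
    expect_identical(lab$grade, as.integer(g))
    expect_identical(lab$n_agree, 3L)
  }
  # empirical per-observer error frequency at epsilon = 0.15
  n <- 1e5
  reps <- replicate(n, simulate_observers(1, 0.15)[1])
  expect_equal(mean(reps == 2), 0.15, tolerance = 0.005)
  expect_true(all(reps %in% c(1, 2)))  # grade-1 errors go to grade 2 only
  # grade-2 errors split evenly between 1 and 3
  reps2 <- replicate(n / 4, simulate_observers(2, 0.2)[1])
  expect_lt(abs(mean(reps2 == 1) - 0.1), 0.01)
  expect_lt(abs(mean(reps2 == 3) - 0.1), 0.01)
})

test_that("consensus recovers the true grade at the enumerated rate", {
  # for edge grades (errors to one neighbour only), P(consensus = g) =
  # (1-e)^3 + 3(1-e)^2 e = (1-e)^2 (1+2e); grade 2 does at least as well
  # because its errors split across two neighbours
  eps <- 0.15
  closed <- (1 - eps)^2 * (1 + 2 * eps)
  set.seed(35)
  n <- 2e4
  for (g in c(1, 3)) {
    hits <- mean(replicate(n, consensus_grade(simulate_observers(g, eps))$grade == g))
    expect_equal(hits, closed, tolerance = 0.01)
  }
  hits2 <- mean(replicate(n, consensus_grade(simulate_observers(2, eps))$grade == 2))
  expect_gte(hits2, closed - 0.01)
})

test_that("the hierarchical grade mixture reproduces both cohort margins", {
  pi_ <- c(7, 24, 19) / 50
  m <- c(152, 645, 204) / 1001
  mix <- dcisgrade:::solve_lesion_mixture(pi_, m)
  expect_equal(rowSums(mix), rep(1, 3))
  expect_true(all(mix >= 0))
  # lesion-level marginal implied by the mixture equals the target exactly
  expect_equal(as.numeric(pi_ %*% mix), m, tolerance = 1e-12)
  # grade-1 patients carry only grade-1 lesions
  expect_equal(mix[1, ], c(1, 0, 0))
  expect_error(dcisgrade:::solve_lesion_mixture(c(0.8, 0.1, 0.1),
                                                c(0.05, 0.15, 0.8)),
               "infeasible")
})

test_that("cohort generation is reproducible and consistent on disk", {
  spec <- tiny_cohort_spec(n_patients = 4, seed = 11)
  d1 <- tempfile("coh1"); d2 <- tempfile("coh2")
  m1 <- generate_cohort(spec, d1)
  m2 <- generate_cohort(spec, d2)
  # identical spec -> byte-identical dataset
  for (f in list.files(d1, recursive = TRUE)) {
    expect_same_file_bytes(file.path(d1, f), file.path(d2, f))
  }
  # manifest bookkeeping matches the files on disk
  expect_identical(nrow(m1$truth),
                   length(list.files(file.path(d1, "images"))))
  expect_identical(length(list.files(file.path(d1, "annotations"))), 4L)
  expect_identical(nrow(m1$patients), 4L)
  expect_identical(sum(m1$patients$n_lesions), nrow(m1$truth))
  expect_true(all(m1$patients$true_grade >= 1 & m1$patients$true_grade <= 3))
  # patient-level truth is the max lesion truth
  for (p in m1$patients$patient_id) {
    expect_identical(m1$patients$true_grade[m1$patients$patient_id == p],
                     max(m1$truth$true_grade[m1$truth$patient_id == p]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("lesion grade frequencies match the configured priors", {
  # grade draws only: many patients with small, fast images would still be
  # slow, so check the sampling layer against the priors at n ~ 2000 using
  # a cohort without image rendering cost (tiny images)
  spec <- synthetic_spec(n_patients = 120, lesions_per_patient = c(10L, 24L),
                         image_params = tiny_image_params(), seed = 9)
  d <- tempfile("prio")
  m <- generate_cohort(spec, d, write_images = FALSE)
  n <- nrow(m$truth)
  expect_gte(n, 1200)
  freq <- tabulate(m$truth$true_grade, 3) / n
  expect_true(all(abs(freq - spec$grade_priors) <= 0.03))
  # patient-level margin close to its prior as well
  pfreq <- tabulate(m$patients$true_grade, 3) / nrow(m$patients)
  expect_true(all(abs(pfreq - c(7, 24, 19) / 50) <= 0.12))
  unlink(d, recursive = TRUE)
})

test_that("a generated cohort feeds the split and loads back end-to-end", {
  spec <- tiny_cohort_spec(n_patients = 6, seed = 13)
  d <- tempfile("e2e")
  generate_cohort(spec, d)
  back <- load_cohort(d, load_images = TRUE)
  expect_identical(nrow(back$truth), nrow(back$grades))
  expect_s3_class(back$images[[1]], "lesion_image")
  expect_equal(back$images[[1]]$resolution, 0.88)
  sp <- suppressWarnings(
    split_patients(data.frame(patient_id = back$patients$patient_id,
                              grade = back$patients$consensus_grade),
                   c(0.5, 0.25, 0.25), seed = 2))
  expect_setequal(sp$patient_id, back$patients$patient_id)
  # annotations parse and correspond to slides
  expect_identical(length(back$annotations), 6L)
  unlink(d, recursive = TRUE)
})
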