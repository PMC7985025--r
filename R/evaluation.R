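#' Patient-level grade by nearest-rank percentile
#'
#' The automated patient-level grade is the lesion grade at the Pth
#' percentile under the nearest-rank definition: sort ascending and take the
#' element at 1-based index `ceiling(P/100 * n)` (clamped to `[1, n]`).
#' `P = 100` coincides exactly with the observers' highest-lesion-grade rule
#' ([observer_patient_grade()]); the default `P = 80` damps the max rule so
#' a single outlier lesion does not determine the patient grade.
#'
#' @param lesion_grades Non-empty integer vector of lesion grades in
#'   \{1, 2, 3\}.
#' @param p Percentile in (0, 100\].
#' @return Patient-level grade in \{1, 2, 3\}.
#' @export
model_patient_grade <- function(lesion_grades, p = 80) {
  if (!length(lesion_grades)) stop("empty lesion grade list")
  if (!is.numeric(p) || p <= 0 || p > 100) stop("p must be in (0, 100]")
  g <- sort(as.integer(lesion_grades))
  n <- length(g)
  g[min(max(ceiling(p / 100 * n), 1L), n)]
}

#' 3x3 confusion matrix of two graders
#'
#' Counts of jointly graded items: rows are grader A's grade, columns
#' grader B's.
#'
#' @param a,b Equal-length integer vectors of grades in \{1, 2, 3\}.
#' @return 3x3 integer matrix with dimnames `1:3` x `1:3`.
#' @export
confusion_matrix3 <- function(a, b) {
  if (length(a) != length(b)) stop("grade vectors have different lengths")
  if (!all(a %in% 1:3) || !all(b %in% 1:3))
    stop("grades must be in {1, 2, 3}")
  matrix(tabulate((b - 1L) * 3L + a, nbins = 9L), 3L, 3L,
         dimnames = list(a = 1:3, b = 1:3))
}

qwk_weights <- function(k = 3L) outer(1:k, 1:k, "-")^2 / (k - 1)^2

#' Quadratic weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal grades where disagreement by one
#' grade point is weighted less than disagreement by two: with disagreement
#' weights `w_ij = (i - j)^2 / (k - 1)^2`,
#' `kappa = 1 - sum(w * O) / sum(w * E)` with `O` the observed proportion
#' matrix and `E` the outer product of its marginals.
#'
#' @param a,b Equal-length (n >= 2) integer vectors of grades in \{1, 2, 3\}.
#' @return Kappa in \[-1, 1\] (up to floating error). When both raters are
#'   constant and identical the expected disagreement is zero and an error
#'   of class `dcis_degenerate_agreement` is thrown.
#' @export
quadratic_weighted_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("grade vectors have different lengths")
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired grades")
  if (!all(a %in% 1:3) || !all(b %in% 1:3))
    stop("grades must be in {1, 2, 3}")
  O <- confusion_matrix3(a, b) / n
  E <- outer(rowSums(O), colSums(O))
  w <- qwk_weights(3L)
  den <- sum(w * E)
  if (den == 0)
    stop(structure(class = c("dcis_degenerate_agreement", "error", "condition"),
                   list(message = "degenerate agreement: both raters constant and identical",
                        call = sys.call())))
  1 - sum(w * O) / den
}

#' Analytic confidence interval for quadratic weighted kappa
#'
#' Large-sample standard error of weighted kappa from the
#' Fleiss-Cohen-Everitt asymptotic variance (agreement-weight form), with a
#' normal-approximation interval `kappa +/- z * SE`. Bounds are deliberately
#' not clamped to \[-1, 1\]: with small n the normal-approximation upper
#' bound can exceed 1 (an interval like 0.49-1.05 is meaningful under this
#' convention and signals the small-sample regime).
#'
#' @param a,b Equal-length integer grade vectors (n >= 2).
#' @param alpha Two-sided error level (default 0.05 for a 95% CI).
#' @return Object of class `agreement_result`: list with `kappa`, `ci_low`,
#'   `ci_high`, `se`, `n`.
#' @export
kappa_ci <- function(a, b, alpha = 0.05) {
  kap <- quadratic_weighted_kappa(a, b)
  n <- length(a)
  O <- confusion_matrix3(a, b) / n
  pr <- rowSums(O); pc <- colSums(O)
  wd <- qwk_weights(3L)
  wa <- 1 - wd                        # agreement weights
  po <- sum(wa * O)
  pe <- sum(wa * outer(pr, pc))
  wbar_row <- as.numeric(wa %*% pc)   # row-wise expected agreement weight
  wbar_col <- as.numeric(pr %*% wa)   # column-wise
  # Fleiss, Cohen & Everitt large-sample variance of weighted kappa
  v <- (sum(O * (wa - (outer(wbar_row, rep(1, 3)) +
                       outer(rep(1, 3), wbar_col)) * (1 - kap))^2) -
          (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(kappa = kap, ci_low = kap - z * se, ci_high = kap + z * se,
                 se = se, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("quadratic weighted kappa %.3f (%.0f%% CI %.3f-%.3f), n = %d\n",
              x$kappa, 95, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Pairwise agreement report
#'
#' Quadratic weighted kappa with analytic 95% CI for every unordered pair of
#' graders, plus per-pair confusion matrices — the standard shape of
#' lesion-level and patient-level inter-observer agreement tables.
#'
#' @param graders Named list (>= 2 elements) of equal-length integer grade
#'   vectors for the same items, e.g.
#'   `list(observer1 = ..., observer2 = ..., observer3 = ..., model = ...)`.
#' @param alpha Two-sided error level for the CIs.
#' @return Data frame with columns `rater_a`, `rater_b`, `kappa`, `ci_low`,
#'   `ci_high`, `n`; the per-pair confusion matrices are attached as the
#'   `"confusions"` attribute (named `"a_vs_b"`). A pair with degenerate
#'   agreement (both raters constant and identical) is reported as `NA`
#'   with a warning rather than aborting the whole report.
#' @export
agreement_report <- function(graders, alpha = 0.05) {
  if (!is.list(graders) || length(graders) < 2L || is.null(names(graders)))
    stop("graders must be a named list of at least two grade vectors")
  lens <- lengths(graders)
  if (length(unique(lens)) != 1L)
    stop("all graders must grade the same items (unequal lengths)")
  nm <- names(graders)
  rows <- list()
  confs <- list()
  for (i in seq_len(length(nm) - 1L)) {
    for (j in (i + 1L):length(nm)) {
      res <- tryCatch(kappa_ci(graders[[i]], graders[[j]], alpha),
                      dcis_degenerate_agreement = function(e) {
                        warning(sprintf("pair %s/%s: %s", nm[i], nm[j],
                                        conditionMessage(e)), call. = FALSE)
                        list(kappa = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, n = length(graders[[i]]))
                      })
      rows[[length(rows) + 1L]] <- data.frame(
        rater_a = nm[i], rater_b = nm[j], kappa = res$kappa,
        ci_low = res$ci_low, ci_high = res$ci_high, n = res$n,
        stringsAsFactors = FALSE)
      confs[[paste0(nm[i], "_vs_", nm[j])]] <-
        confusion_matrix3(graders[[i]], graders[[j]])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "confusions") <- confs
  out
}

#' Write an agreement report to CSV files
#'
#' Writes the pairwise kappa table as `kappa_pairs.csv` and each confusion
#' matrix as `confusion_<a>_vs_<b>.csv` under `dir`.
#'
#' @param report Result of [agreement_report()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_agreement_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- report
  df$kappa <- sprintf("%.6f", df$kappa)
  df$ci_low <- sprintf("%.6f", df$ci_low)
  df$ci_high <- sprintf("%.6f", df$ci_high)
  utils::write.csv(df, file.path(dir, "kappa_pairs.csv"), row.names = FALSE,
                   quote = FALSE)
  for (nm in names(attr(report, "confusions"))) {
    utils::write.csv(attr(report, "confusions")[[nm]],
                     file.path(dir, paste0("confusion_", nm, ".csv")))
  }
  invisible(dir)
}
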