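# Independent oracles, coded from first principles and kept free of any
# package internals so they can arbitrate the implementation.

# Textbook quadratic weighted kappa: explicit loops over the 3x3 table.
qwk_oracle <- function(a, b) {
  n <- length(a)
  O <- matrix(0, 3, 3)
  for (i in seq_len(n)) O[a[i], b[i]] <- O[a[i], b[i]] + 1
  O <- O / n
  pr <- rowSums(O); pc <- colSums(O)
  num <- 0; den <- 0
  for (i in 1:3) for (j in 1:3) {
    w <- (i - j)^2 / 4
    num <- num + w * O[i, j]
    den <- den + w * pr[i] * pc[j]
  }
  1 - num / den
}

# Brute-force majority vote with the three-way-split rule.
consensus_oracle <- function(g) {
  counts <- c(sum(g == 1), sum(g == 2), sum(g == 3))
  if (max(counts) >= 2) list(grade = which.max(counts), n_agree = max(counts))
  else list(grade = 2L, n_agree = 1L)
}

# Median with the round-half-up tie rule, from the definition.
median_oracle <- function(g) {
  s <- sort(g)
  n <- length(s)
  if (n %% 2 == 1) return(s[(n + 1) / 2])
  lo <- s[n / 2]; hi <- s[n / 2 + 1]
  if (lo == hi) lo else ceiling((lo + hi) / 2)
}

# Nearest-rank percentile from the definition.
percentile_oracle <- function(g, p) {
  s <- sort(g)
  s[min(max(ceiling(p / 100 * length(s)), 1), length(s))]
}

# All multisets of size n from {1,2,3}, as count triples (n1, n2, n3).
grade_multisets <- function(n) {
  out <- list()
  for (n1 in 0:n) for (n2 in 0:(n - n1))
    out[[length(out) + 1]] <- c(n1, n2, n - n1 - n2)
  out
}

# Ray-casting point-in-polygon test (polygon as an n x 2 matrix).
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > y) != (poly[j, 2] > y) &&
        x < (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# Small image parameters so synthetic rendering stays fast in unit tests.
tiny_image_params <- function() {
  ip <- default_image_params()
  ip$duct_box_px <- c(90L, 130L)
  ip$small_box_px <- c(60L, 80L)
  ip
}

# A fast, tiny synthetic cohort for pipeline tests.
tiny_cohort_spec <- function(n_patients = 4, seed = 1) {
  synthetic_spec(n_patients = n_patients, lesions_per_patient = c(3L, 6L),
                 image_params = tiny_image_params(), seed = seed)
}

expect_same_file_bytes <- function(f1, f2) {
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
}
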