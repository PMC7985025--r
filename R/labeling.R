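#' Consensus grade and agreement count of three observers
#'
#' Majority vote over three ordinal grades in \{1, 2, 3\}. When at least two
#' observers agree, the consensus is their grade and `n_agree` is its
#' multiplicity (2 or 3). When all three observers disagree (a three-way
#' split, only possible as \{1, 2, 3\}) the consensus is grade 2 and
#' `n_agree` is 1. The pair (consensus grade, agreement count) is the dual
#' training target of the grading model: the agreement count encodes how
#' borderline a lesion is.
#'
#' @param grades Integer vector of length 3, each element in \{1, 2, 3\}.
#' @return List with elements `grade` and `n_agree` (class `consensus_label`).
#' @export
consensus_grade <- function(grades) {
  if (length(grades) != 3L || !all(grades %in% c(1, 2, 3)))
    stop("grades must be three values in {1, 2, 3}")
  grades <- as.integer(grades)
  counts <- tabulate(grades, nbins = 3L)
  m <- max(counts)
  if (m >= 2L) {
    g <- which.max(counts)
  } else {
    g <- 2L  # three-way split rule
  }
  structure(list(grade = as.integer(g), n_agree = as.integer(m)),
            class = "consensus_label")
}

#' Consensus labels for a whole grade table
#'
#' @param grades Data frame with columns `lesion_id`, `observer1..3`
#'   (see [read_grade_table()]).
#' @return Data frame with columns `lesion_id`, `grade`, `n_agree`.
#' @export
consensus_labels <- function(grades) {
  labs <- lapply(seq_len(nrow(grades)), function(i)
    consensus_grade(c(grades$observer1[i], grades$observer2[i],
                      grades$observer3[i])))
  data.frame(lesion_id = grades$lesion_id,
             grade = vapply(labs, `[[`, integer(1), "grade"),
             n_agree = vapply(labs, `[[`, integer(1), "n_agree"),
             stringsAsFactors = FALSE)
}

#' Observer patient-level grade
#'
#' The patient-level grade assigned by an observer is the highest lesion
#' grade present for that patient.
#'
#' @param lesion_grades Non-empty integer vector of lesion grades in \{1,2,3\}.
#' @return The maximum grade.
#' @export
observer_patient_grade <- function(lesion_grades) {
  if (!length(lesion_grades)) stop("empty lesion grade list")
  if (!all(lesion_grades %in% c(1, 2, 3)))
    stop("lesion grades must be in {1, 2, 3}")
  as.integer(max(lesion_grades))
}

#' Stratified patient-level split
#'
#' Partitions patients into training / validation / test subsets, stratified
#' by patient-level consensus grade so the grade distribution is similar in
#' each subset. Within each grade stratum patients are shuffled by a seeded
#' generator and allocated to subsets by largest-remainder rounding of the
#' target fractions. The split is by patient: lesions of one patient never
#' cross subsets.
#'
#' @param patients Data frame with columns `patient_id` and `grade`
#'   (patient-level consensus grade in \{1, 2, 3\}).
#' @param fractions Numeric length-3 vector (train, validation, test);
#'   positive, summing to 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return Data frame with columns `patient_id`, `subset` (one of
#'   `"train"`, `"validation"`, `"test"`).
#' @export
split_patients <- function(patients, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "grade") %in% names(patients)))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive values summing to 1")
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient_id")
  subsets <- c("train", "validation", "test")
  out <- vector("list", 3L)
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  for (g in sort(unique(patients$grade))) {
    ids <- patients$patient_id[patients$grade == g]
    if (length(ids) < sum(fractions > 0))
      warning(sprintf("grade-%s stratum has only %d patient(s); allocating by largest remainder anyway",
                      g, length(ids)), call. = FALSE)
    ids <- ids[sample.int(length(ids))]
    counts <- largest_remainder(length(ids), fractions)
    assign <- rep(subsets, counts)
    out[[length(out) + 1L]] <- data.frame(patient_id = ids, subset = assign,
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Largest-remainder (Hamilton) apportionment of n items to fractions.
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  counts <- floor(quota)
  rem <- quota - counts
  left <- n - sum(counts)
  if (left > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' @export
print.consensus_label <- function(x, ...) {
  cat(sprintf("consensus grade %d (%d of 3 observers agree)\n",
              x$grade, x$n_agree))
  invisible(x)
}
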