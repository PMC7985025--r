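#' End-to-end parameter-recovery experiment on a synthetic cohort
#'
#' Runs the whole pipeline at desk scale as a stand-in for the clinical
#' experiment: generates a seeded synthetic cohort, splits patients
#' 40/10/10 (train/validation/test by default), trains the dual-head
#' smallcnn grader on the simulated observers' consensus labels, predicts
#' the test lesions with the 10-patch median rule, and evaluates quadratic
#' weighted kappa against the synthetic ground truth at the lesion level and
#' (via the 80th-percentile rule) at the patient level. A label-shuffled
#' control kappa quantifies the chance level.
#'
#' @param seed Integer master seed; every random stream (cohort, split,
#'   training, prediction, shuffle) is derived from it.
#' @param dir Directory for the generated cohort (a temporary directory by
#'   default).
#' @param n_patients Cohort size (default 60).
#' @param fractions Train/validation/test patient fractions.
#' @param config Optional [model_config()]; by default a smallcnn
#'   configuration suited to CPU training (learning rate 2e-3, batch 8,
#'   448 balanced-sampled lesions per epoch, at most 8 epochs).
#' @param extraction An [extraction_params()].
#' @param augmentation An [augment_params()].
#' @param percentile Patient-level aggregation percentile (default 80).
#' @param write_images Write the cohort PNGs to `dir` (off by default; the
#'   experiment works from in-memory images).
#' @param verbose Print per-epoch progress.
#' @return List with elements `fit` (the trained [dcis_grader()]),
#'   `lesion_kappa`, `patient_kappa`, `control_kappa`, `report` (pairwise
#'   lesion-level agreement of the three simulated observers and the model
#'   on the test set), `split`, and counts `n`.
#' @export
run_recovery_experiment <- function(seed = 1L, dir = tempfile("cohort"),
                                    n_patients = 60L,
                                    fractions = c(40, 10, 10) / 60,
                                    config = NULL,
                                    extraction = extraction_params(),
                                    augmentation = augment_params(),
                                    percentile = 80,
                                    write_images = FALSE,
                                    verbose = FALSE) {
  spec <- synthetic_spec(n_patients = n_patients,
                         seed = derive_seed(seed, 1))
  cohort <- generate_cohort(spec, dir, keep_images = TRUE,
                            write_images = write_images)
  split <- split_patients(
    data.frame(patient_id = cohort$patients$patient_id,
               grade = cohort$patients$consensus_grade),
    fractions = fractions, seed = derive_seed(seed, 2))
  labels <- consensus_labels(cohort$grades)
  if (is.null(config))
    config <- model_config(backbone = "smallcnn", learning_rate = 2e-3,
                           batch_size = 8L, max_epochs = 8L,
                           early_stopping_patience = 3L,
                           lesions_per_epoch = 448L,
                           seed = derive_seed(seed, 3))
  sets <- lapply(c(train = "train", validation = "validation", test = "test"),
                 function(s) subset_lesion_set(cohort, labels, split, s))
  fit <- dcis_grader(sets$train, sets$validation, config, extraction,
                     augmentation, verbose = verbose)
  preds <- predict(fit, sets$test$images, seed = derive_seed(seed, 4))
  truth_test <- cohort$truth[match(preds$lesion_id, cohort$truth$lesion_id), ]
  lesion_kappa <- quadratic_weighted_kappa(preds$predicted_grade,
                                           truth_test$true_grade)
  # patient-level: percentile aggregation of model grades vs true max grade
  test_patients <- split$patient_id[split$subset == "test"]
  model_pat <- vapply(test_patients, function(pid) {
    ids <- cohort$truth$lesion_id[cohort$truth$patient_id == pid]
    model_patient_grade(preds$predicted_grade[match(ids, preds$lesion_id)],
                        p = percentile)
  }, integer(1))
  true_pat <- cohort$patients$true_grade[match(test_patients,
                                               cohort$patients$patient_id)]
  patient_kappa <- quadratic_weighted_kappa(model_pat, true_pat)
  # label-shuffled control: chance-level agreement
  oldr <- local_rng_seed(derive_seed(seed, 5))
  shuffled <- sample(truth_test$true_grade)
  restore_rng(oldr)
  control_kappa <- quadratic_weighted_kappa(preds$predicted_grade, shuffled)
  gr <- cohort$grades[match(preds$lesion_id, cohort$grades$lesion_id), ]
  report <- agreement_report(list(observer1 = gr$observer1,
                                  observer2 = gr$observer2,
                                  observer3 = gr$observer3,
                                  model = preds$predicted_grade))
  list(fit = fit, lesion_kappa = lesion_kappa, patient_kappa = patient_kappa,
       control_kappa = control_kappa, report = report, split = split,
       predictions = preds,
       n = list(patients = n_patients,
                lesions = nrow(cohort$truth),
                test_lesions = nrow(preds),
                test_patients = length(test_patients)))
}

#' Assemble the lesion set of one split subset
#'
#' Collects the images and labels of every lesion whose patient belongs to
#' the given subset — the container [dcis_grader()] trains and predicts on.
#'
#' @param cohort List with `truth` (data frame with `lesion_id`,
#'   `patient_id`) and `images` (named list of [lesion_image()]), e.g. a
#'   [generate_cohort()] manifest with `keep_images = TRUE`.
#' @param labels Data frame of consensus labels (see [consensus_labels()]).
#' @param split Split assignment from [split_patients()].
#' @param subset One of `"train"`, `"validation"`, `"test"`.
#' @return List with elements `images` and `labels`.
#' @export
subset_lesion_set <- function(cohort, labels, split, subset) {
  pids <- split$patient_id[split$subset == subset]
  ids <- cohort$truth$lesion_id[cohort$truth$patient_id %in% pids]
  list(images = cohort$images[ids],
       labels = labels[labels$lesion_id %in% ids, , drop = FALSE])
}
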