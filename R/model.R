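#' Model configuration
#'
#' Configuration of the dual-head grading network and its training loop.
#' The network has a shared convolutional trunk and two 3-class softmax
#' heads: the grade head (consensus grade 1..3) and the agreement head
#' (number of agreeing observers 1..3). `lambda_agree` weights the agreement
#' loss term; `lambda_agree = 0` recovers the consensus-only baseline.
#'
#' @param backbone `"smallcnn"` (CPU-trainable trunk, the default) or
#'   `"densenet121"` (the full-fidelity architecture).
#' @param lambda_agree Non-negative weight of the agreement loss term.
#' @param learning_rate Adam learning rate.
#' @param batch_size Lesions (one patch each) per optimizer step.
#' @param max_epochs Maximum training epochs.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param min_epochs Epochs to run before early stopping may trigger.
#' @param lesions_per_epoch Lesions sampled per epoch (`NULL` = one pass
#'   over the training set); smaller values shorten an epoch without
#'   changing the sampling distribution.
#' @param balanced_sampling Sample lesions each epoch with inverse
#'   grade-frequency weights (with replacement), so minority grades
#'   contribute equally to the loss despite the skewed grade marginal.
#' @param n_eval_patches Patches per lesion at prediction time (median rule).
#' @param n_monitor_patches Patches per lesion for the per-epoch validation
#'   kappa used for model selection (smaller than `n_eval_patches` to keep
#'   monitoring cheap).
#' @param seed Integer seed controlling initialization, patch sampling and
#'   augmentation.
#' @return Object of class `model_config`.
#' @export
model_config <- function(backbone = c("smallcnn", "densenet121"),
                         lambda_agree = 0.5, learning_rate = 1e-4,
                         batch_size = 16L, max_epochs = 10L,
                         early_stopping_patience = 3L, min_epochs = 4L,
                         balanced_sampling = TRUE, lesions_per_epoch = NULL,
                         n_eval_patches = 10L, n_monitor_patches = 4L,
                         seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(lambda_agree >= 0, learning_rate > 0, batch_size >= 1,
            max_epochs >= 1, early_stopping_patience >= 1, min_epochs >= 1,
            n_eval_patches >= 1, n_monitor_patches >= 1)
  structure(list(backbone = backbone, lambda_agree = lambda_agree,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 min_epochs = as.integer(min_epochs),
                 balanced_sampling = isTRUE(balanced_sampling),
                 lesions_per_epoch = if (is.null(lesions_per_epoch)) NULL
                   else as.integer(lesions_per_epoch),
                 n_eval_patches = as.integer(n_eval_patches),
                 n_monitor_patches = as.integer(n_monitor_patches),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build the dual-head grading network
#'
#' Constructs the convolutional trunk (`smallcnn` or `densenet121`) with two
#' 3-class softmax heads off the shared feature vector. Parameter
#' initialization is seeded from the config, so building twice with the same
#' seed yields identical parameters.
#'
#' @param config A [model_config()].
#' @param patch_size Patch side length the network will be fed (used by the
#'   smallcnn backbone to size its pooling stem).
#' @return Object of class `dcis_model` holding the network.
#' @export
build_model <- function(config = model_config(), patch_size = 512L) {
  arch <- switch(config$backbone,
                 smallcnn = arch_smallcnn(patch_size),
                 densenet121 = arch_densenet121(),
                 stop("unknown backbone: ", config$backbone))
  net <- net_init(arch$nodes, in_channels = 3L, heads = arch$heads,
                  seed = derive_seed(config$seed, 101))
  structure(list(net = net, config = config), class = "dcis_model")
}

# Forward a single patch (numeric array, values in [0, 255]) through the
# network; returns the two softmax distributions and the hard grade.  The
# network's leading norm op centers the input on H&E tissue statistics.
predict_patch <- function(model, pixels, train = FALSE) {
  fw <- net_forward(model$net, pixels, train = train)
  zg <- fw$outs[[model$net$heads[["grade"]]]]
  za <- fw$outs[[model$net$heads[["agree"]]]]
  pg <- softmax(zg)
  pa <- softmax(za)
  structure(list(grade_probs = pg, agree_probs = pa,
                 hard_grade = which.max(pg)),
            class = "grade_prediction")
}

#' Dual-target cross-entropy loss
#'
#' `cross_entropy(grade) + lambda_agree * cross_entropy(agreement)`.
#' Probabilities are clamped at 1e-12 before taking logs. With
#' `lambda_agree = 0` the loss reduces to the consensus-only baseline and is
#' independent of the agreement head.
#'
#' @param pred A `grade_prediction` (or any list with `grade_probs` and
#'   `agree_probs`, each three non-negative numbers summing to 1).
#' @param label A `consensus_label` (or list with `grade` and `n_agree`).
#' @param lambda_agree Non-negative agreement-loss weight.
#' @return Non-negative scalar loss.
#' @export
dual_loss <- function(pred, label, lambda_agree = 0.5) {
  stopifnot(lambda_agree >= 0, label$grade %in% 1:3, label$n_agree %in% 1:3)
  lg <- -log(max(pred$grade_probs[label$grade], 1e-12))
  la <- -log(max(pred$agree_probs[label$n_agree], 1e-12))
  lg + lambda_agree * la
}

#' Median grade with the round-up tie rule
#'
#' Median of integer grades; when the two central values of an even-length
#' list straddle (half-integer median), the result is rounded up to the
#' higher grade, biasing borderline lesions toward the clinically cautious
#' higher grade.
#'
#' @param grades Non-empty integer vector of grades in \{1, 2, 3\}.
#' @return A single grade in \{1, 2, 3\}.
#' @export
grade_median <- function(grades) {
  if (!length(grades)) stop("empty grade list")
  g <- sort(as.integer(grades))
  n <- length(g)
  m <- if (n %% 2L == 1L) g[(n + 1L) %/% 2L] else (g[n %/% 2L] + g[n %/% 2L + 1L]) / 2
  as.integer(ceiling(m))
}

#' Predict the grade of one lesion (10-patch median)
#'
#' Draws `n_eval_patches` patches from the lesion image with
#' [sample_patch()] (no augmentation at test time), takes the hard grade of
#' each, and returns their median under the round-up tie rule.
#'
#' @param model A `dcis_model` or fitted [dcis_grader()].
#' @param img A [lesion_image()].
#' @param n_eval_patches Number of patches (default from the model config).
#' @param extraction An [extraction_params()].
#' @return Predicted grade in \{1, 2, 3\}.
#' @export
predict_lesion <- function(model, img, n_eval_patches = NULL,
                           extraction = extraction_params()) {
  if (inherits(model, "dcis_grader")) {
    extraction <- model$extraction
    if (is.null(n_eval_patches)) n_eval_patches <- model$config$n_eval_patches
    model <- model$model
  }
  if (is.null(n_eval_patches)) n_eval_patches <- model$config$n_eval_patches
  grades <- vapply(seq_len(n_eval_patches), function(i) {
    p <- sample_patch(img, extraction)
    predict_patch(model, p$pixels)$hard_grade
  }, integer(1))
  grade_median(grades)
}

#' Fit the dual-head DCIS grading model
#'
#' Trains the convolutional grader on per-lesion consensus labels. Each
#' optimizer step samples one random augmented patch per lesion in the batch
#' and minimizes the mean [dual_loss()] (Adam). After every epoch the
#' lesion-level quadratic weighted kappa against the validation consensus
#' grades is computed (via [predict_lesion()], without augmentation);
#' parameters from the best validation epoch are retained and training stops
#' after `early_stopping_patience` epochs without improvement. Fully
#' deterministic for a fixed config seed.
#'
#' @param train,validation Lesion sets: lists with elements `images` (list of
#'   [lesion_image()]) and `labels` (data frame with columns `lesion_id`,
#'   `grade`, `n_agree`, e.g. from [consensus_labels()]). Training and
#'   validation must be disjoint by patient.
#' @param config A [model_config()].
#' @param extraction An [extraction_params()] (patch size etc.).
#' @param augmentation An [augment_params()]; training-time only.
#' @param verbose Print one line per epoch.
#' @return Object of class `dcis_grader` with components `model` (the
#'   trained network), `history` (per-epoch data frame), `selected_epoch`,
#'   `config`, `extraction`, `augmentation`.
#' @export
dcis_grader <- function(train, validation, config = model_config(),
                        extraction = extraction_params(),
                        augmentation = augment_params(), verbose = FALSE) {
  tr <- align_lesion_set(train)
  va <- align_lesion_set(validation)
  if (!length(tr$images)) stop("empty training set")
  model <- build_model(config, patch_size = extraction$patch_size)
  old <- local_rng_seed(derive_seed(config$seed, 202))
  on.exit(restore_rng(old))
  st <- adam_state(model$net$params)
  n <- length(tr$images)
  best_kappa <- -Inf
  best_params <- model$net$params
  best_epoch <- 0L
  since_best <- 0L
  hist <- list()
  sample_w <- if (config$balanced_sampling) {
    freq <- tabulate(tr$labels$grade, 3L) / n
    w <- (1 / pmax(freq, 1e-9))[tr$labels$grade]
    w / sum(w)
  } else NULL
  epoch_n <- if (is.null(config$lesions_per_epoch)) n
    else min(config$lesions_per_epoch, n)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- if (is.null(sample_w)) sample.int(n)[seq_len(epoch_n)]
      else sample.int(n, epoch_n, replace = TRUE, prob = sample_w)
    epoch_loss <- 0
    for (start in seq(1L, epoch_n, by = config$batch_size)) {
      chunk <- ord[start:min(start + config$batch_size - 1L, epoch_n)]
      gacc <- NULL
      for (i in chunk) {
        p <- sample_patch(tr$images[[i]], extraction)
        p <- augment(p, augmentation)
        x <- p$pixels
        fw <- net_forward(model$net, x, train = TRUE)
        zg <- fw$outs[[model$net$heads[["grade"]]]]
        za <- fw$outs[[model$net$heads[["agree"]]]]
        pg <- softmax(zg); pa <- softmax(za)
        lab <- list(grade = tr$labels$grade[i], n_agree = tr$labels$n_agree[i])
        epoch_loss <- epoch_loss +
          dual_loss(list(grade_probs = pg, agree_probs = pa), lab,
                    config$lambda_agree)
        dzg <- pg; dzg[lab$grade] <- dzg[lab$grade] - 1
        dza <- config$lambda_agree * pa
        dza[lab$n_agree] <- dza[lab$n_agree] - config$lambda_agree
        g <- net_backward(model$net, fw, list(grade = dzg, agree = dza))
        gacc <- acc_grads(gacc, g)
      }
      gacc <- scale_grads(gacc, 1 / length(chunk))
      upd <- adam_step(model$net$params, gacc, st, config$learning_rate)
      model$net$params <- upd$params
      st <- upd$state
    }
    val_pred <- vapply(va$images, function(img)
      predict_lesion(model, img, config$n_monitor_patches, extraction),
      integer(1))
    val_kappa <- tryCatch(
      quadratic_weighted_kappa(val_pred, va$labels$grade),
      error = function(e) NA_real_)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = epoch_loss / epoch_n,
                                val_kappa = val_kappa)
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f, val kappa %.3f",
                      epoch, epoch_loss / epoch_n, val_kappa))
    score <- if (is.na(val_kappa)) -Inf else val_kappa
    if (score > best_kappa + 1e-9) {
      best_kappa <- score
      best_params <- model$net$params
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (epoch >= config$min_epochs &&
          since_best >= config$early_stopping_patience) break
    }
  }
  model$net$params <- best_params
  history <- do.call(rbind, hist)
  structure(list(model = model, history = history,
                 selected_epoch = best_epoch, config = config,
                 extraction = extraction, augmentation = augmentation,
                 baseline = config$lambda_agree == 0),
            class = "dcis_grader")
}

# Match a lesion set's labels to its images by lesion_id, in image order.
align_lesion_set <- function(x) {
  stopifnot(is.list(x), !is.null(x$images), is.data.frame(x$labels))
  ids <- vapply(x$images, `[[`, character(1), "lesion_id")
  m <- match(ids, x$labels$lesion_id)
  if (anyNA(m)) stop("missing label for lesion(s): ",
                     paste(utils::head(ids[is.na(m)], 3), collapse = ", "))
  list(images = x$images, labels = x$labels[m, , drop = FALSE])
}

acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    if (is.null(acc[[i]])) { acc[[i]] <- g[[i]]; next }
    for (nm in names(g[[i]])) acc[[i]][[nm]] <- acc[[i]][[nm]] + g[[i]][[nm]]
  }
  acc
}

scale_grads <- function(g, s) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    for (nm in names(g[[i]])) g[[i]][[nm]] <- g[[i]][[nm]] * s
  }
  g
}

#' Predict lesion grades for a set of lesion images
#'
#' @param object A fitted [dcis_grader()].
#' @param newdata List of [lesion_image()] objects.
#' @param seed Optional seed for the patch-sampling stream (for reproducible
#'   predictions).
#' @param ... Unused.
#' @return Data frame with columns `lesion_id`, `predicted_grade`.
#' @export
predict.dcis_grader <- function(object, newdata, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- local_rng_seed(seed)
    on.exit(restore_rng(old))
  }
  ids <- vapply(newdata, `[[`, character(1), "lesion_id")
  grades <- vapply(newdata, function(img) predict_lesion(object, img),
                   integer(1))
  data.frame(lesion_id = ids, predicted_grade = grades,
             stringsAsFactors = FALSE)
}

#' @export
print.dcis_grader <- function(x, ...) {
  cat(sprintf("Dual-head DCIS grading model (%s%s)\n", x$config$backbone,
              if (isTRUE(x$baseline)) ", consensus-only baseline" else ""))
  cat(sprintf("  trained %d epoch(s); selected epoch %d (validation kappa %.3f)\n",
              nrow(x$history), x$selected_epoch,
              x$history$val_kappa[x$selected_epoch]))
  invisible(x)
}

#' @export
summary.dcis_grader <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  cat(sprintf("\nlambda_agree = %g, learning rate = %g, batch size = %d\n",
              object$config$lambda_agree, object$config$learning_rate,
              object$config$batch_size))
  invisible(object$history)
}

#' @export
coef.dcis_grader <- function(object, ...) {
  p <- object$model$net$params
  names(p) <- vapply(object$model$net$nodes, function(nd)
    sprintf("%s_%d", nd$op, nd$id), character(1))
  p[!vapply(p, is.null, logical(1))]
}

#' @export
plot.dcis_grader <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "mean training loss", main = "Training loss", ...)
  graphics::plot(h$epoch, h$val_kappa, type = "b", xlab = "epoch",
                 ylab = "validation QWK", main = "Validation agreement", ...)
  graphics::abline(v = x$selected_epoch, lty = 2)
  invisible(x)
}

#' Save / load a fitted grader
#'
#' The fitted model is serialized with `saveRDS()`; a JSON sidecar
#' (`<path>.json`) records the configuration and the selected epoch for
#' inspection without deserializing.
#'
#' @param object A fitted [dcis_grader()].
#' @param path Checkpoint path (`.rds`).
#' @return `path`, invisibly (for `save_dcis_grader`); the fitted grader
#'   (for `load_dcis_grader`).
#' @export
save_dcis_grader <- function(object, path) {
  saveRDS(object, path)
  sidecar <- list(config = unclass(object$config),
                  selected_epoch = object$selected_epoch,
                  baseline = isTRUE(object$baseline),
                  epochs_run = nrow(object$history))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_dcis_grader
#' @export
load_dcis_grader <- function(path) readRDS(path)
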