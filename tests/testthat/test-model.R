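test_that("both backbones satisfy the dual-head contract", {
  set.seed(2)
  x <- array(stats::runif(64 * 64 * 3) * 255, c(64, 64, 3))
  for (bk in c("smallcnn", "densenet121")) {
    m <- build_model(model_config(backbone = bk, seed = 7), patch_size = 64L)
    p <- dcisgrade:::predict_patch(m, x)
    expect_length(p$grade_probs, 3L)
    expect_length(p$agree_probs, 3L)
    expect_equal(sum(p$grade_probs), 1, tolerance = 1e-9)
    expect_equal(sum(p$agree_probs), 1, tolerance = 1e-9)
    expect_true(all(p$grade_probs >= 0) && all(p$agree_probs >= 0))
    expect_true(p$hard_grade %in% 1:3)
  }
  expect_error(build_model(model_config(backbone = "resnet")), "arg")
})

test_that("parameter initialization is seeded and reproducible", {
  m1 <- build_model(model_config(seed = 42), patch_size = 128L)
  m2 <- build_model(model_config(seed = 42), patch_size = 128L)
  expect_identical(m1$net$params, m2$net$params)
  m3 <- build_model(model_config(seed = 43), patch_size = 128L)
  expect_false(identical(m1$net$params, m3$net$params))
})

test_that("dual loss matches closed forms and ignores the agreement head at lambda 0", {
  onehot <- function(i) { v <- numeric(3); v[i] <- 1; v }
  lab <- list(grade = 2L, n_agree = 3L)
  expect_equal(dual_loss(list(grade_probs = onehot(2), agree_probs = onehot(3)),
                         lab, 0.5), 0)
  unif <- rep(1 / 3, 3)
  expect_equal(dual_loss(list(grade_probs = unif, agree_probs = unif), lab, 0.5),
               1.5 * log(3))
  # lambda = 0: loss independent of the agreement head
  l1 <- dual_loss(list(grade_probs = unif, agree_probs = onehot(1)), lab, 0)
  l2 <- dual_loss(list(grade_probs = unif, agree_probs = onehot(3)), lab, 0)
  expect_equal(l1, l2)
  expect_equal(l1, log(3))
  # zero probability at the true class is clamped, not infinite
  expect_lt(dual_loss(list(grade_probs = c(1, 0, 0), agree_probs = unif),
                      list(grade = 2, n_agree = 1), 0), Inf)
})

test_that("raising the true-class probability never increases the loss", {
  set.seed(31)
  lab <- list(grade = 1L, n_agree = 2L)
  for (i in 1:100) {
    p <- as.numeric(stats::runif(3)); p <- p / sum(p)
    q <- as.numeric(stats::runif(3)); q <- q / sum(q)
    l0 <- dual_loss(list(grade_probs = p, agree_probs = q), lab, 0.5)
    # move mass toward the true grade class, renormalizing the rest
    p2 <- p; p2[1] <- p[1] + (1 - p[1]) * stats::runif(1)
    p2[2:3] <- p[2:3] * (1 - p2[1]) / (1 - p[1])
    l1 <- dual_loss(list(grade_probs = p2, agree_probs = q), lab, 0.5)
    expect_lte(l1, l0 + 1e-12)
  }
})

test_that("median grade follows the round-up tie rule on all 66 ten-grade multisets", {
  expect_identical(grade_median(rep(2, 10)), 2L)
  expect_identical(grade_median(c(rep(1, 5), rep(2, 5))), 2L)
  for (ms in grade_multisets(10)) {
    g <- rep(1:3, times = ms)
    expect_identical(grade_median(g), as.integer(median_oracle(g)))
  }
})

test_that("analytic gradients match numerical differentiation on a tiny network", {
  set.seed(9)
  ns <- dcisgrade:::arch_smallcnn(16L)
  net <- dcisgrade:::net_init(ns$nodes, 3L, ns$heads, seed = 5)
  x <- array(stats::runif(16 * 16 * 3) * 255, c(16, 16, 3))
  lab <- list(grade = 2L, n_agree = 3L)
  lossfun <- function(net) {
    fw <- dcisgrade:::net_forward(net, x, train = TRUE)
    pg <- dcisgrade:::softmax(fw$outs[[net$heads[["grade"]]]])
    pa <- dcisgrade:::softmax(fw$outs[[net$heads[["agree"]]]])
    list(loss = -log(pg[lab$grade]) - 0.5 * log(pa[lab$n_agree]),
         fw = fw, pg = pg, pa = pa)
  }
  r <- lossfun(net)
  dzg <- r$pg; dzg[lab$grade] <- dzg[lab$grade] - 1
  dza <- 0.5 * r$pa; dza[lab$n_agree] <- dza[lab$n_agree] - 0.5
  gr <- dcisgrade:::net_backward(net, r$fw, list(grade = dzg, agree = dza))
  eps <- 1e-6
  for (i in seq_along(net$params)) {
    if (is.null(net$params[[i]])) next
    for (nm in names(net$params[[i]])) {
      p <- net$params[[i]][[nm]]
      for (k in sample(length(p), min(4, length(p)))) {
        net2 <- net
        net2$params[[i]][[nm]][k] <- p[k] + eps
        l2 <- lossfun(net2)$loss
        net2$params[[i]][[nm]][k] <- p[k] - eps
        l1 <- lossfun(net2)$loss
        num <- (l2 - l1) / (2 * eps)
        an <- gr[[i]][[nm]][k]
        expect_lt(abs(num - an) / max(1e-6, abs(num) + abs(an)), 1e-4)
      }
    }
  }
})

test_that("gradients are exact through batch norm, max pooling and concatenation", {
  # a miniature DenseNet-style graph exercising the remaining ops
  nodes <- list()
  add <- function(op, .from = length(nodes), ...) {
    nodes[[length(nodes) + 1L]] <<-
      dcisgrade:::nn_node(length(nodes) + 1L, op, .from, list(...))
    length(nodes)
  }
  inp <- add("input", .from = 0L)
  c1 <- add("conv", k = 3L, f = 4L, s = 1L, pad = 1L)
  b1 <- add("bn"); r1 <- add("relu")
  mp <- add("maxpool", k = 3L, s = 2L, pad = 1L)
  c2 <- add("conv", k = 1L, f = 4L, s = 1L, pad = 0L)
  cc <- add("concat", .from = c(mp, c2))
  gp <- add("gap")
  hg <- add("dense", .from = gp, units = 3L)
  ha <- add("dense", .from = gp, units = 3L)
  net <- dcisgrade:::net_init(nodes, 3L, c(grade = hg, agree = ha), seed = 3)
  set.seed(10)
  x <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  lossfun <- function(net) {
    fw <- dcisgrade:::net_forward(net, x, train = TRUE)
    pg <- dcisgrade:::softmax(fw$outs[[net$heads[["grade"]]]])
    pa <- dcisgrade:::softmax(fw$outs[[net$heads[["agree"]]]])
    list(loss = -log(pg[1]) - 0.5 * log(pa[2]), fw = fw, pg = pg, pa = pa)
  }
  r <- lossfun(net)
  dzg <- r$pg; dzg[1] <- dzg[1] - 1
  dza <- 0.5 * r$pa; dza[2] <- dza[2] - 0.5
  gr <- dcisgrade:::net_backward(net, r$fw, list(grade = dzg, agree = dza))
  eps <- 1e-6
  for (i in c(c1, b1, c2, hg, ha)) {
    for (nm in names(net$params[[i]])) {
      p <- net$params[[i]][[nm]]
      for (k in sample(length(p), min(4, length(p)))) {
        net2 <- net
        # batch-norm running stats are updated in the forward pass; reset
        # them so both numerical evaluations see the same state
        net2$state <- as.environment(as.list(net$state))
        net2$params[[i]][[nm]][k] <- p[k] + eps
        l2 <- lossfun(net2)$loss
        net2$params[[i]][[nm]][k] <- p[k] - eps
        l1 <- lossfun(net2)$loss
        num <- (l2 - l1) / (2 * eps)
        an <- gr[[i]][[nm]][k]
        # looser than the smallcnn check: max-pooling argmax can flip under
        # the finite-difference perturbation
        expect_lt(abs(num - an) / max(1e-6, abs(num) + abs(an)), 2e-3)
      }
    }
  }
})

test_that("lesion prediction stays in the grade domain for an untrained model", {
  set.seed(14)
  m <- build_model(model_config(seed = 1), patch_size = 32L)
  par <- extraction_params(patch_size = 32)
  for (i in 1:5) {
    img <- lesion_image(array(stats::runif(48 * 48 * 3) * 255, c(48, 48, 3)),
                        resolution = 0.88)
    g <- predict_lesion(m, img, n_eval_patches = 10, extraction = par)
    expect_true(g %in% 1:3)
  }
})

test_that("training is deterministic and selects the best validation epoch", {
  set.seed(15)
  ip <- tiny_image_params()
  mk_set <- function(n, seed) {
    set.seed(seed)
    images <- list(); labels <- NULL
    for (i in seq_len(n)) {
      g <- sample(1:3, 1)
      id <- sprintf("L%d_%d", seed, i)
      les <- generate_lesion_image(g, ip, size_px = 100, lesion_id = id)
      images[[id]] <- les$image
      lab <- consensus_grade(simulate_observers(g, 0.1))
      labels <- rbind(labels, data.frame(lesion_id = id, grade = lab$grade,
                                         n_agree = lab$n_agree))
    }
    list(images = images, labels = labels)
  }
  train <- mk_set(10, 101)
  val <- mk_set(6, 202)
  cfg <- model_config(max_epochs = 2, batch_size = 4, learning_rate = 1e-3,
                      n_monitor_patches = 2, seed = 77)
  par <- extraction_params(patch_size = 64)
  f1 <- dcis_grader(train, val, cfg, par)
  f2 <- dcis_grader(train, val, cfg, par)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$net$params, f2$model$net$params)
  expect_identical(nrow(f1$history), 2L)
  best <- which.max(ifelse(is.na(f1$history$val_kappa), -Inf,
                           f1$history$val_kappa))
  expect_identical(f1$selected_epoch, as.integer(best))
  expect_error(dcis_grader(list(images = list(), labels = train$labels), val,
                           cfg, par), "empty training set")
})

test_that("a lambda-zero run is tagged as the consensus-only baseline", {
  set.seed(16)
  ip <- tiny_image_params()
  les <- generate_lesion_image(1, ip, size_px = 80, lesion_id = "a")
  les2 <- generate_lesion_image(3, ip, size_px = 80, lesion_id = "b")
  set <- list(images = list(a = les$image, b = les2$image),
              labels = data.frame(lesion_id = c("a", "b"),
                                  grade = c(1L, 3L), n_agree = c(3L, 3L)))
  cfg <- model_config(lambda_agree = 0, max_epochs = 1, batch_size = 2,
                      n_monitor_patches = 1, seed = 3)
  fit <- dcis_grader(set, set, cfg, extraction_params(patch_size = 64))
  expect_true(fit$baseline)
  expect_output(print(fit), "baseline")
})

test_that("checkpoints round-trip through save/load with a JSON sidecar", {
  set.seed(17)
  ip <- tiny_image_params()
  les <- generate_lesion_image(2, ip, size_px = 80, lesion_id = "a")
  set <- list(images = list(a = les$image),
              labels = data.frame(lesion_id = "a", grade = 2L, n_agree = 3L))
  cfg <- model_config(max_epochs = 1, batch_size = 1, n_monitor_patches = 1,
                      seed = 4)
  fit <- dcis_grader(set, set, cfg, extraction_params(patch_size = 64))
  f <- tempfile(fileext = ".rds")
  save_dcis_grader(fit, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(side$selected_epoch, fit$selected_epoch)
  back <- load_dcis_grader(f)
  expect_identical(back$model$net$params, fit$model$net$params)
  unlink(c(f, paste0(f, ".json")))
})
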