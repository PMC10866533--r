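# architectures used at reduced scale where only training dynamics (not
# capacity) are under test would change the contract, so the real configs
# are used throughout; datasets are kept tiny instead.

test_that("architecture summaries match their configurations", {
  m <- build_base_model(base_model_config("stacklstm", output_dim = 6))
  expect_length(m$arch, 3)
  expect_identical(vapply(m$arch, `[[`, 0L, "units"), c(128L, 64L, 32L))
  expect_true(all(vapply(m$arch, `[[`, "", "activation") == "linear"))

  b <- build_base_model(base_model_config("bilstm", output_dim = 6))
  expect_length(b$arch, 1)
  expect_true(b$arch[[1]]$bidirectional)
  expect_identical(b$arch[[1]]$activation, "relu")
  expect_equal(b$config$output_dim, 6L)

  v <- build_base_model(base_model_config("vlstm", output_dim = 9))
  expect_true(v$arch[[1]]$peephole)
  expect_warning(base_model_config("vlstm", output_dim = 6,
                                   peepholes = FALSE),
                 "standard LSTM cells")
  expect_error(base_model_config("bilstm", output_dim = 7),
               class = "gs_config_error")
})

test_that("the reference engine's gradients match finite differences", {
  set.seed(31)
  arch <- list(list(units = 4L, activation = "tanh", peephole = TRUE,
                    bidirectional = FALSE))
  params <- glucostack:::net_init(arch, 1L, 2L)
  X <- matrix(runif(12), 3, 4); Y <- matrix(runif(6), 3, 2)
  lg <- glucostack:::net_loss_grads(params, arch, X, Y)
  eps <- 1e-6
  for (blk in names(lg$grads)) for (g in names(lg$grads[[blk]])) {
    fld <- if (blk == "dense") g else sub("^d", "", g)
    for (i in seq_len(min(4, length(lg$grads[[blk]][[g]])))) {
      p2 <- params
      p2[[blk]][[fld]][i] <- p2[[blk]][[fld]][i] + eps
      l1 <- glucostack:::net_loss_grads(p2, arch, X, Y)$loss
      p2[[blk]][[fld]][i] <- p2[[blk]][[fld]][i] - 2 * eps
      l2 <- glucostack:::net_loss_grads(p2, arch, X, Y)$loss
      expect_equal(lg$grads[[blk]][[g]][i], (l1 - l2) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("compiled engine agrees with the reference engine on loss and gradients", {
  set.seed(32)
  archs <- list(
    list(list(units = 6L, activation = "relu", peephole = FALSE,
              bidirectional = TRUE)),
    list(list(units = 6L, activation = "linear", peephole = FALSE,
              bidirectional = FALSE),
         list(units = 4L, activation = "linear", peephole = FALSE,
              bidirectional = FALSE),
         list(units = 3L, activation = "linear", peephole = FALSE,
              bidirectional = FALSE)),
    list(list(units = 5L, activation = "linear", peephole = TRUE,
              bidirectional = FALSE)))
  X <- matrix(runif(48, 0.1, 0.9), 8, 6)
  Y <- matrix(runif(24, 0.2, 0.8), 8, 3)
  for (arch in archs) {
    params <- glucostack:::net_init(arch, 1L, 3L)
    rr <- glucostack:::net_loss_grads(params, arch, X, Y)
    cx <- glucostack:::lstm_grad_cpp(arch, params, X, Y, 3L)
    expect_equal(cx$loss, rr$loss, tolerance = 1e-5)
    yr <- glucostack:::net_forward(params, arch, X)$yhat
    yc <- glucostack:::lstm_predict_cpp(arch, params, X, 3L)
    expect_equal(max(abs(yr - yc)), 0, tolerance = 1e-5)
    for (blk in names(rr$grads)) for (g in names(rr$grads[[blk]])) {
      gc <- cx$grads[[blk]][[if (blk == "dense") g else sub("^d", "", g)]]
      expect_equal(max(abs(rr$grads[[blk]][[g]] - gc)), 0,
                   tolerance = 1e-5)
    }
  }
})

test_that("every architecture can overfit a 10-sample fixture", {
  ds <- toy_dataset(n = 10, h = 6, p = 6, seed = 7)
  for (a in c("bilstm", "stacklstm", "vlstm")) {
    cfg <- base_model_config(a, output_dim = 6, max_epochs = 300,
                             early_stop_patience = Inf, seed = 2)
    fit <- train_base_model(build_base_model(cfg), ds)
    final_mse <- tail(fit$history$train, 1)
    expect_lt(final_mse, 1e-2)
  }
})

test_that("training is deterministic per seed", {
  ds <- toy_dataset(n = 30, seed = 5)
  cfg <- base_model_config("vlstm", output_dim = 6, max_epochs = 3,
                           early_stop_patience = Inf, seed = 99)
  f1 <- train_base_model(build_base_model(cfg), ds)
  f2 <- train_base_model(build_base_model(cfg), ds)
  expect_identical(f1$history$train[1], f2$history$train[1])
  expect_identical(f1$params, f2$params)
})

test_that("early stopping halts after patience epochs of worsening validation", {
  # adversarial fixture: validation targets sit opposite the training
  # targets, so every step toward the training fit worsens validation loss
  ds <- toy_dataset(n = 24, seed = 3)
  ds$Y[] <- 0.9
  val <- ds
  val$Y[] <- -0.9
  cfg <- base_model_config("vlstm", output_dim = 6, max_epochs = 500,
                           early_stop_patience = 10, seed = 1)
  fit <- train_base_model(build_base_model(cfg), ds, val)
  expect_lte(fit$epochs_run, 11)
  expect_equal(fit$best_epoch, 1L)
})

test_that("restored weights reproduce the best validation loss", {
  ds <- toy_dataset(n = 40, seed = 6)
  sp <- split_train_val(ds)
  cfg <- base_model_config("stacklstm", output_dim = 6, max_epochs = 15,
                           early_stop_patience = 5, seed = 8)
  fit <- train_base_model(build_base_model(cfg), sp$train, sp$val)
  expect_equal(fit$best_val, min(fit$history$val), tolerance = 1e-12)
  pred <- predict(fit, sp$val$X)
  expect_equal(mean((pred - sp$val$Y)^2), fit$best_val, tolerance = 1e-5)
})

test_that("inference is deterministic and shape-correct", {
  ds <- toy_dataset(n = 15, seed = 9)
  cfg <- base_model_config("bilstm", output_dim = 6, max_epochs = 2,
                           early_stop_patience = Inf, seed = 3)
  fit <- train_base_model(build_base_model(cfg), ds)
  X <- ds$X[c(1, 1, 2, 3, 3), ]
  out <- predict(fit, X)
  expect_equal(dim(out), c(5L, 6L))
  expect_identical(out[1, ], out[2, ])
  expect_identical(out[4, ], out[5, ])
  expect_true(all(is.finite(out)))
  expect_error(predict(fit, ds$X[, 1:5]))
})

test_that("a model trained on a constant signal predicts the constant", {
  n <- 40
  s <- series_from_values(rep(150, n + 12))
  s$values <- rep(0.5, n + 12)
  attr(s, "provenance") <- c("gap_fill", "kalman", "smooth", "normalize")
  ds <- make_supervised(s, window_spec(6, 6))
  cfg <- base_model_config("vlstm", output_dim = 6, max_epochs = 200,
                           early_stop_patience = Inf, seed = 4)
  fit <- train_base_model(build_base_model(cfg), ds)
  pred <- predict(fit, ds$X)
  expect_lt(max(abs(pred - 0.5)), 0.05)
})
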