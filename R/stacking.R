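#' Stacking ensemble plan
#'
#' Describes the full adaptive weighted stacking run: the base learner
#' configurations, 5-fold out-of-fold (OOF) prediction scheme, the
#' variance-penalized affinity-propagation weighting, and the linear
#' meta-learner. Folds are contiguous in time (never shuffled) so that the
#' temporal ordering of samples is respected.
#'
#' @param ph_minutes Prediction horizon: 30, 45 or 60 minutes.
#' @param n_folds Number of cross-validation folds; default 5.
#' @param architectures Character vector of base learners; entries from
#'   `"bilstm"`, `"stacklstm"`, `"vlstm"`, plus the audit pseudo-learner
#'   `"oracle"` which "predicts" the true targets wherever they are known.
#'   The oracle deliberately leaks targets and exists only for pipeline
#'   self-checks (identity paths and weight-recovery audits).
#' @param max_epochs,early_stop_patience Training protocol applied to every
#'   base learner; the package default mirrors the base-model protocol
#'   (500 epochs cap, patience 10). The `fast_profile()` helper shrinks
#'   these to 30/5 for desk-scale runs.
#' @param similarity A [similarity_config()] for the AP weighting.
#' @param invert_weights Passed to [normalize_weights()]; default `FALSE`
#'   (raw within-cluster variances normalized as printed), `TRUE`
#'   upweights low-variance models instead.
#' @param include_original_features,include_weighted_combo Which blocks the
#'   meta-feature matrix carries besides the base predictions.
#' @param val_fraction Chronological validation fraction; default 0.2.
#' @param seed Master seed; per-model seeds are derived from it.
#' @return A `stacking_plan`.
#' @export
stacking_plan <- function(ph_minutes = 30, n_folds = 5L,
                          architectures = c("bilstm", "stacklstm", "vlstm"),
                          max_epochs = 500L, early_stop_patience = 10L,
                          similarity = similarity_config(),
                          invert_weights = FALSE,
                          include_original_features = TRUE,
                          include_weighted_combo = TRUE,
                          val_fraction = 0.2, seed = 1L) {
  if (!ph_minutes %in% c(30, 45, 60))
    gs_config_error("'ph_minutes' must be 30, 45 or 60")
  check_scalar(n_folds, "n_folds", lower = 2)
  ok <- architectures %in% c("bilstm", "stacklstm", "vlstm", "oracle")
  if (!all(ok))
    gs_config_error(sprintf("unknown architecture(s): %s",
                            paste(architectures[!ok], collapse = ", ")))
  if (length(architectures) < 2)
    gs_config_error("stacking needs at least 2 base learners")
  structure(list(ph_minutes = ph_minutes, n_folds = as.integer(n_folds),
                 architectures = architectures,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 similarity = similarity,
                 invert_weights = isTRUE(invert_weights),
                 include_original_features = isTRUE(include_original_features),
                 include_weighted_combo = isTRUE(include_weighted_combo),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "stacking_plan")
}

#' Desk-scale training profile
#'
#' Shrinks the training protocol (30-epoch cap, patience 5) for continuous
#' integration and interactive use; a deliberate deviation from the full
#' 500-epoch protocol.
#'
#' @param plan A [stacking_plan()].
#' @return The plan with `max_epochs = 30`, `early_stop_patience = 5`.
#' @export
fast_profile <- function(plan) {
  plan$max_epochs <- 30L
  plan$early_stop_patience <- 5L
  plan
}

# contiguous fold index sets; any remainder goes to the first fold
fold_indices <- function(n, n_folds) {
  base <- n %/% n_folds
  sizes <- rep(base, n_folds)
  sizes[1] <- sizes[1] + n - base * n_folds
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_folds] + 1L)
  lapply(seq_len(n_folds), function(k) starts[k]:ends[k])
}

# deterministic per-(architecture, fold) seed fan-out, kept < 2^31
derive_seed <- function(master, arch_idx, fold) {
  (master * 7919L + arch_idx * 1009L + fold * 101L) %% 2147483629L
}

make_arch_config <- function(arch, plan, output_dim, seed) {
  base_model_config(architecture = arch, output_dim = output_dim,
                    max_epochs = plan$max_epochs,
                    early_stop_patience = plan$early_stop_patience,
                    seed = seed)
}

#' Out-of-fold base predictions
#'
#' Splits the training samples into `n_folds` contiguous folds of
#' near-equal size (remainder in the first fold). For each base
#' architecture and each fold, a model is trained on the other folds (early
#' stopping against `val`) and predicts the held-out fold, so every
#' training sample receives exactly one prediction per architecture from a
#' model that never saw it. All fold models are retained for test-time
#' averaging.
#'
#' @param train A `supervised_dataset` (the training subset).
#' @param plan A [stacking_plan()].
#' @param val Validation `supervised_dataset` for early stopping.
#' @return List with `oof` (named list of n x p OOF prediction matrices,
#'   one per architecture), `fold_models` (per architecture, per fold) and
#'   `folds` (the index sets).
#' @export
kfold_oof <- function(train, plan, val = NULL) {
  n <- nrow(train$X)
  if (n < plan$n_folds)
    gs_data_error(sprintf("%d samples cannot form %d folds", n, plan$n_folds))
  folds <- fold_indices(n, plan$n_folds)
  p <- ncol(train$Y)
  oof <- list(); fold_models <- list()
  for (a in seq_along(plan$architectures)) {
    arch <- plan$architectures[a]
    preds <- matrix(NA_real_, n, p)
    models <- vector("list", plan$n_folds)
    if (arch == "oracle") {
      preds <- train$Y
      models <- replicate(plan$n_folds, structure(list(), class = "oracle_model"),
                          simplify = FALSE)
    } else {
      for (k in seq_len(plan$n_folds)) {
        hold <- folds[[k]]
        cfg <- make_arch_config(arch, plan, p, derive_seed(plan$seed, a, k))
        fit <- train_base_model(build_base_model(cfg),
                                subset_dataset(train, setdiff(seq_len(n), hold)),
                                val)
        preds[hold, ] <- predict(fit, train$X[hold, , drop = FALSE])
        models[[k]] <- fit
      }
    }
    oof[[arch]] <- preds
    fold_models[[arch]] <- models
  }
  list(oof = oof, fold_models = fold_models, folds = folds)
}

#' Fold-averaged test predictions
#'
#' Each architecture's fold models all predict the full test input; their
#' elementwise mean is that architecture's test prediction.
#'
#' @param fold_models The `fold_models` element of a [kfold_oof()] result.
#' @param X Test input matrix (normalized scale).
#' @param Y_true Required only when an `"oracle"` pseudo-learner is
#'   present (it returns these targets verbatim).
#' @return Named list of n x p prediction matrices, one per architecture.
#' @export
test_predictions <- function(fold_models, X, Y_true = NULL) {
  out <- list()
  for (arch in names(fold_models)) {
    models <- fold_models[[arch]]
    if (inherits(models[[1]], "oracle_model")) {
      if (is.null(Y_true))
        gs_data_error("oracle pseudo-learner needs Y_true at prediction time")
      out[[arch]] <- Y_true
    } else {
      acc <- NULL
      for (m in models) {
        pr <- predict(m, X)
        acc <- if (is.null(acc)) pr else acc + pr
      }
      out[[arch]] <- acc / length(models)
    }
  }
  out
}

#' Assemble the meta-feature matrix
#'
#' Fixed block order `[base_1 ... base_m | weighted | original]`, i.e. the
#' per-model predictions (m*p columns), their weighted combination (p
#' columns, optional) and the original history window (h columns,
#' optional): `h + (m+1)*p` columns in the full layout. The column-block
#' map is recorded so named blocks can be extracted back.
#'
#' @param base_preds Named list of n x p base prediction matrices.
#' @param weighted_pred n x p weighted combination, or `NULL` to omit.
#' @param original_X n x h original inputs, or `NULL` to omit.
#' @return A `meta_features` matrix with a `blocks` attribute
#'   (name -> column indices).
#' @export
assemble_meta_features <- function(base_preds, weighted_pred = NULL,
                                   original_X = NULL) {
  n <- nrow(base_preds[[1]])
  pieces <- list(); blocks <- list(); at <- 0L
  add <- function(name, m) {
    if (nrow(m) != n) gs_data_error("meta-feature blocks disagree on row count")
    pieces[[name]] <<- m
    blocks[[name]] <<- at + seq_len(ncol(m))
    at <<- at + ncol(m)
  }
  for (nm in names(base_preds)) add(nm, base_preds[[nm]])
  if (!is.null(weighted_pred)) add("weighted", weighted_pred)
  if (!is.null(original_X)) add("original", original_X)
  out <- do.call(cbind, pieces)
  attr(out, "blocks") <- blocks
  class(out) <- c("meta_features", class(out))
  out
}

#' @param features A `meta_features` matrix.
#' @param block Block name to extract.
#' @rdname assemble_meta_features
#' @export
meta_block <- function(features, block) {
  blocks <- attr(features, "blocks")
  if (is.null(blocks[[block]]))
    gs_data_error(sprintf("no meta-feature block named '%s'", block))
  features[, blocks[[block]], drop = FALSE]
}

#' Linear meta-learner
#'
#' One ordinary-least-squares linear map (with intercept) per horizon
#' output. A rank-deficient design falls back to the Moore-Penrose
#' pseudoinverse with a warning; fewer rows than columns also warns.
#'
#' @param features Meta-feature matrix (n x q).
#' @param Y Target matrix (n x p).
#' @return A `meta_model` with `coef` ((q+1) x p, intercept first).
#' @export
fit_meta <- function(features, Y) {
  X <- cbind(1, unclass(features))
  Y <- as.matrix(Y)
  if (nrow(X) < ncol(X))
    warning("fit_meta: fewer samples than columns; solution is not unique")
  qrx <- qr(X)
  coef <- if (qrx$rank < ncol(X)) {
    warning("fit_meta: rank-deficient design, using least-squares pseudoinverse")
    MASS::ginv(X) %*% Y
  } else qr.coef(qrx, Y)
  structure(list(coef = coef, n_features = ncol(X) - 1L,
                 blocks = attr(features, "blocks")),
            class = "meta_model")
}

#' @param model A `meta_model`.
#' @rdname fit_meta
#' @export
meta_predict <- function(model, features) {
  X <- cbind(1, unclass(features))
  if (ncol(X) - 1L != model$n_features)
    gs_data_error("meta-feature width differs from the fitted design")
  X %*% model$coef
}

#' Run the adaptive weighted stacking pipeline
#'
#' End-to-end run for one prediction horizon over all four history windows
#' (30/45/60/90 minutes of history). Per window:
#' \enumerate{
#'   \item window the preprocessed, normalized series and split off the
#'     chronologically last 20% of training samples as validation;
#'   \item 5-fold out-of-fold base predictions on the training subset;
#'   \item affinity-propagation weighting: validation samples, represented
#'     as m-dimensional points of the base models' fold-averaged
#'     predictions at the final horizon step, are clustered; each model's
#'     weight comes from its cluster-weighted variance, normalized;
#'   \item meta-features `[base preds | weighted combo | original window]`
#'     fit by the linear meta-learner against the training-subset targets;
#'   \item test predictions from fold-averaged base models, combined with
#'     the same weights, passed through the meta-learner, denormalized,
#'     and scored at the final horizon step.
#' }
#' The report carries per-window metrics and their mean across the four
#' history windows. No test value enters base training, normalization
#' fitting, or weight estimation.
#'
#' @param train_series,test_series `glucose_series` with roles
#'   `"train"`/`"test"`. They are preprocessed internally (gap fill ->
#'   Kalman -> smoothing -> normalization fitted on train only) unless
#'   already stamped.
#' @param plan A [stacking_plan()].
#' @param kalman,smoothing Preprocessing configs.
#' @return An `awd_stacking_run`: per-window results (`weights`,
#'   `metrics`, `base_rmse`, predictions) plus `mean_metrics` across
#'   windows.
#' @export
run_awd_stacking <- function(train_series, test_series, plan,
                             kalman = kalman_config(),
                             smoothing = smoothing_config()) {
  if (!inherits(plan, "stacking_plan"))
    gs_config_error("'plan' must be a stacking_plan")
  if (!("smooth" %in% provenance(train_series)))
    train_series <- preprocess_series(train_series, kalman, smoothing)
  if (!("smooth" %in% provenance(test_series)))
    test_series <- preprocess_series(test_series, kalman, smoothing)
  norm <- fit_normalizer(train_series)
  train_n <- normalize_series(train_series, norm, strict = TRUE)
  test_n <- normalize_series(test_series, norm, strict = TRUE)

  specs <- enumerate_window_specs(plan$ph_minutes)
  windows <- list()
  for (spec in specs) {
    wname <- sprintf("hw%d", spec$history_points * 5L)
    windows[[wname]] <- run_one_window(train_n, test_n, spec, plan, norm)
  }
  mean_metrics <- average_metric_list(lapply(windows, `[[`, "metrics"))
  structure(list(windows = windows, mean_metrics = mean_metrics,
                 plan = plan, normalizer = norm,
                 ph_minutes = plan$ph_minutes),
            class = "awd_stacking_run")
}

run_one_window <- function(train_n, test_n, spec, plan, norm) {
  ds <- make_supervised(train_n, spec)
  parts <- split_train_val(ds, plan$val_fraction)
  test_ds <- make_supervised(test_n, spec)
  p <- spec$horizon_points

  cv <- kfold_oof(parts$train, plan, parts$val)

  # fold-averaged predictions for validation and test inputs
  val_preds <- test_predictions(cv$fold_models, parts$val$X,
                                Y_true = parts$val$Y)
  tst_preds <- test_predictions(cv$fold_models, test_ds$X,
                                Y_true = test_ds$Y)

  # AP weights from validation samples in base-model prediction space
  pts <- do.call(cbind, lapply(val_preds, function(m) m[, p]))
  simcfg <- plan$similarity
  if (nrow(pts) > simcfg$sample_cap) {
    old <- .Random.seed_save(); set.seed(simcfg$seed)
    keep <- sort(sample.int(nrow(pts), simcfg$sample_cap))
    .Random.seed_restore(old)
    pts <- pts[keep, , drop = FALSE]
  }
  assign <- affinity_propagation(weighted_similarity(pts, simcfg), simcfg)
  wv <- normalize_weights(cluster_weighted_variance(pts, assign),
                          invert = plan$invert_weights)

  meta_train <- assemble_meta_features(
    cv$oof,
    if (plan$include_weighted_combo) combine_predictions(cv$oof, wv),
    if (plan$include_original_features) parts$train$X)
  # the weighted block is a linear combination of the base blocks, so this
  # design is rank-deficient by construction; the pseudoinverse path is the
  # expected route here, not a surprise worth a warning
  meta <- withCallingHandlers(
    fit_meta(meta_train, parts$train$Y),
    warning = function(w) {
      if (grepl("rank-deficient", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })

  meta_test <- assemble_meta_features(
    tst_preds,
    if (plan$include_weighted_combo) combine_predictions(tst_preds, wv),
    if (plan$include_original_features) test_ds$X)
  pred_n <- meta_predict(meta, meta_test)

  # scoring at the final horizon step, mg/dL scale
  y_true <- denormalize_values(test_ds$Y[, p], norm)
  y_pred <- denormalize_values(pred_n[, p], norm)
  base_rmse <- vapply(tst_preds, function(m)
    rmse(y_true, denormalize_values(m[, p], norm)), 0)

  list(spec = spec,
       weights = wv,
       meta = meta,
       n_clusters = assign$n_clusters,
       metrics = metrics_report(y_true, y_pred),
       base_rmse = base_rmse,
       predictions = data.frame(y_true = y_true, y_pred = y_pred),
       epochs_run = if (is.null(cv$fold_models[[1]][[1]]$epochs_run)) NA_integer_
                    else vapply(cv$fold_models, function(ms)
                      sum(vapply(ms, function(m)
                        if (is.null(m$epochs_run)) 0L else m$epochs_run, 0L)),
                      0L))
}

average_metric_list <- function(reports) {
  nums <- lapply(reports, function(r) unlist(r[metric_numeric_fields()]))
  avg <- Reduce(`+`, nums) / length(nums)
  as.list(avg)
}

#' @export
print.awd_stacking_run <- function(x, ...) {
  cat(sprintf("<awd_stacking_run> PH %d min, %d history windows\n",
              x$ph_minutes, length(x$windows)))
  for (nm in names(x$windows)) {
    w <- x$windows[[nm]]
    cat(sprintf("  %s: rmse %.3f, mae %.3f, mcc %.3f | weights %s\n",
                nm, w$metrics$rmse, w$metrics$mae, w$metrics$mcc,
                paste(sprintf("%s=%.2f", names(w$base_rmse),
                              w$weights$weights), collapse = " ")))
  }
  cat(sprintf("  mean over windows: rmse %.3f, mae %.3f, mcc %.3f\n",
              x$mean_metrics$rmse, x$mean_metrics$mae, x$mean_metrics$mcc))
  invisible(x)
}
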