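#' Base learner configuration
#'
#' The three base forecasters share one training protocol (Adam at learning
#' rate 0.001 on mean squared error, minibatches of 32, up to 500 epochs,
#' early stopping on validation loss with patience 10, best weights
#' restored) and differ in architecture:
#'
#' * `bilstm` — one bidirectional LSTM layer, 128 units per direction,
#'   relu cell activation, forward and backward final hidden states
#'   concatenated;
#' * `stacklstm` — three stacked LSTM layers of 128, 64 and 32 units,
#'   linear cell activation;
#' * `vlstm` — one 128-unit LSTM layer with peephole connections (gates
#'   additionally observe the cell state), linear cell activation.
#'
#' Each ends in a linear dense layer of width `output_dim` emitting the
#' whole multi-step forecast as a vector. The cell activation replaces the
#' usual tanh in the candidate and cell-output nonlinearity; `tanh` is
#' available as a config switch.
#'
#' @param architecture `"bilstm"`, `"stacklstm"` or `"vlstm"`.
#' @param output_dim Forecast width (horizon points): 6, 9 or 12.
#' @param layer_units Integer vector of recurrent layer widths; defaults
#'   per architecture as above.
#' @param cell_activation `"relu"`, `"linear"` or `"tanh"`; default per
#'   architecture.
#' @param peepholes Logical; only honoured for `vlstm` (a `vlstm` built
#'   with `peepholes = FALSE` warns and uses standard cells).
#' @param learning_rate,batch_size,max_epochs,early_stop_patience,shuffle_batches
#'   Training protocol knobs; see above for defaults.
#' @param clip_norm Global gradient-norm clip applied before each Adam
#'   step; guards the relu cells against exploding gradients.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @return A `base_model_config`.
#' @export
base_model_config <- function(architecture = c("bilstm", "stacklstm", "vlstm"),
                              output_dim,
                              layer_units = NULL, cell_activation = NULL,
                              peepholes = NULL, learning_rate = 0.001,
                              batch_size = 32L, max_epochs = 500L,
                              early_stop_patience = 10L,
                              shuffle_batches = TRUE, clip_norm = 1,
                              seed = 1L) {
  architecture <- match.arg(architecture)
  if (!output_dim %in% c(6L, 9L, 12L))
    gs_config_error("'output_dim' must be one of 6, 9, 12")
  defaults <- switch(architecture,
    bilstm    = list(units = 128L, act = "relu",   peep = FALSE),
    stacklstm = list(units = c(128L, 64L, 32L), act = "linear", peep = FALSE),
    vlstm     = list(units = 128L, act = "linear", peep = TRUE))
  if (is.null(layer_units)) layer_units <- defaults$units
  if (is.null(cell_activation)) cell_activation <- defaults$act
  if (is.null(peepholes)) peepholes <- defaults$peep
  if (architecture == "stacklstm" && length(layer_units) != 3L)
    gs_config_error("stacklstm requires exactly 3 layer_units")
  if (architecture != "stacklstm" && length(layer_units) != 1L)
    gs_config_error(sprintf("%s requires exactly 1 layer_units entry",
                            architecture))
  if (peepholes && architecture != "vlstm")
    gs_config_error("peephole cells are only used by the vlstm architecture")
  if (!peepholes && architecture == "vlstm") {
    warning("vlstm built with peepholes = FALSE: using standard LSTM cells")
  }
  check_scalar(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  check_scalar(batch_size, "batch_size", 1)
  check_scalar(max_epochs, "max_epochs", 1)
  check_scalar(clip_norm, "clip_norm", 0, strict_lower = TRUE,
               allow_inf = TRUE)  # Inf disables clipping
  structure(list(architecture = architecture,
                 output_dim = as.integer(output_dim),
                 layer_units = as.integer(layer_units),
                 cell_activation = cell_activation,
                 dense_activation = "linear",
                 peepholes = isTRUE(peepholes),
                 optimizer = "adam", learning_rate = learning_rate,
                 loss = "mse",
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 shuffle_batches = isTRUE(shuffle_batches),
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "base_model_config")
}

config_arch <- function(config) {
  switch(config$architecture,
    bilstm = list(list(units = config$layer_units[1],
                       activation = config$cell_activation,
                       peephole = FALSE, bidirectional = TRUE)),
    stacklstm = lapply(config$layer_units, function(u)
      list(units = u, activation = config$cell_activation,
           peephole = FALSE, bidirectional = FALSE)),
    vlstm = list(list(units = config$layer_units[1],
                      activation = config$cell_activation,
                      peephole = config$peepholes, bidirectional = FALSE)))
}

#' Build an untrained base model
#'
#' @param config A [base_model_config()].
#' @return A `base_model` holding the architecture description; weights are
#'   initialized at training time from the config seed so that training is
#'   reproducible end to end.
#' @export
build_base_model <- function(config) {
  if (!inherits(config, "base_model_config"))
    gs_config_error("'config' must be a base_model_config")
  structure(list(config = config, arch = config_arch(config)),
            class = "base_model")
}

#' @export
print.base_model <- function(x, ...) {
  cat(sprintf("<base_model> %s (untrained)\n", x$config$architecture))
  for (l in seq_along(x$arch)) {
    ly <- x$arch[[l]]
    cat(sprintf("  recurrent layer %d: %d units%s, %s activation%s\n", l,
                ly$units, if (ly$bidirectional) "/direction (bidirectional)" else "",
                ly$activation, if (ly$peephole) ", peephole gates" else ""))
  }
  cat(sprintf("  dense output: %d (linear)\n", x$config$output_dim))
  invisible(x)
}

#' Train a base model
#'
#' Optimizes mean squared error with Adam over shuffled minibatches;
#' training halts when the validation loss has not improved for
#' `early_stop_patience` consecutive epochs (or at `max_epochs`), and the
#' weights from the best validation epoch are restored.
#'
#' @param model A [build_base_model()] result.
#' @param train,val `supervised_dataset`s on the normalized scale with
#'   matching window specs. `val` may be `NULL` to train without early
#'   stopping.
#' @param engine `"cpp"` (single-precision compiled engine, the production
#'   path) or `"r"` (the double-precision reference implementation; same
#'   architectures and protocol, used for cross-checking).
#' @return A `trained_base_model` with fields `config`, `params`,
#'   `history` (per-epoch train/val loss), `epochs_run`, `best_epoch`.
#' @export
train_base_model <- function(model, train, val = NULL,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!inherits(model, "base_model"))
    gs_data_error("'model' must be an untrained base_model")
  cfg <- model$config
  if (!is.null(val)) {
    if (!identical(unclass(train$spec), unclass(val$spec)))
      gs_data_error("train and val window specs differ")
  }
  if (ncol(train$Y) != cfg$output_dim)
    gs_data_error(sprintf("dataset horizon %d does not match output_dim %d",
                          ncol(train$Y), cfg$output_dim))
  patience <- cfg$early_stop_patience
  if (is.null(patience) || !is.finite(patience)) patience <- Inf
  fit <- if (engine == "cpp") {
    set.seed(cfg$seed)
    lstm_fit_cpp(model$arch, train$X, train$Y,
                 if (is.null(val)) NULL else val$X,
                 if (is.null(val)) NULL else val$Y,
                 output_dim = cfg$output_dim, lr = cfg$learning_rate,
                 batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
                 patience = patience, shuffle = cfg$shuffle_batches,
                 clip_norm = cfg$clip_norm)
  } else {
    lstm_fit(model$arch, train$X, train$Y,
             if (is.null(val)) NULL else val$X,
             if (is.null(val)) NULL else val$Y,
             output_dim = cfg$output_dim,
             learning_rate = cfg$learning_rate,
             batch_size = cfg$batch_size,
             max_epochs = cfg$max_epochs,
             patience = patience,
             shuffle = cfg$shuffle_batches,
             clip_norm = cfg$clip_norm,
             seed = cfg$seed)
  }
  structure(list(config = cfg, arch = model$arch, params = fit$params,
                 history_points = ncol(train$X),
                 history = fit$history, epochs_run = fit$epochs_run,
                 best_epoch = fit$best_epoch, best_val = fit$best_val),
            class = "trained_base_model")
}

#' @export
print.trained_base_model <- function(x, ...) {
  cat(sprintf("<trained_base_model> %s: %d epochs (best %d, val mse %.3g)\n",
              x$config$architecture, x$epochs_run, x$best_epoch, x$best_val))
  invisible(x)
}

#' Predict with a trained base model
#'
#' Deterministic inference: identical inputs always yield identical rows.
#'
#' @param object A `trained_base_model`.
#' @param X Matrix with `history_points` columns, normalized scale.
#' @param ... Unused.
#' @return An `n x output_dim` prediction matrix (normalized scale), with a
#'   `"scale"` attribute.
#' @export
predict.trained_base_model <- function(object, X, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != object$history_points)
    gs_data_error(sprintf("input has %d columns but the model was trained on %d history points",
                          ncol(X), object$history_points))
  out <- net_forward(object$params, object$arch, X)$yhat
  if (any(!is.finite(out))) gs_data_error("non-finite prediction")
  attr(out, "scale") <- "normalized"
  out
}
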