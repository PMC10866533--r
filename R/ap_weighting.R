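#' Similarity and affinity-propagation configuration
#'
#' Parameters of the variance-penalized similarity and the affinity
#' propagation (AP) message passing used to weight the base models.
#' `similarity_alpha` scales the variance penalty added to the Euclidean
#' distance; the preference (the diagonal of the similarity matrix) is the
#' median of the off-diagonal similarities unless a fixed value is given.
#'
#' @param similarity_alpha Nonnegative weight on the per-point variance
#'   penalty; default 0.5.
#' @param preference `"median"` or a numeric value for the diagonal.
#' @param damping Message damping factor in `[0.5, 1)`; default 0.5, the
#'   canonical choice. Heavier damping slows oscillation but also blunts
#'   exemplar selection on small or highly symmetric inputs.
#' @param max_iter Maximum message-passing iterations; default 200.
#' @param convergence_iter Iterations of unchanged exemplar set that count
#'   as convergence; default 15.
#' @param polish_max Largest instance size on which the converged exemplar
#'   set is additionally polished by a greedy add/remove/swap local search
#'   on the net similarity (cubic cost, so bounded); default 64.
#' @param sample_cap Largest number of points clustered; bigger inputs are
#'   subsampled deterministically from `seed`. Default 500.
#' @param seed Integer seed (subsampling and symmetry-breaking jitter).
#' @return A `similarity_config`.
#' @export
similarity_config <- function(similarity_alpha = 0.5, preference = "median",
                              damping = 0.5, max_iter = 200L,
                              convergence_iter = 15L, polish_max = 64L,
                              sample_cap = 500L, seed = 1L) {
  check_scalar(similarity_alpha, "similarity_alpha", lower = 0)
  if (is.numeric(preference)) check_scalar(preference, "preference")
  else if (!identical(preference, "median"))
    gs_config_error("'preference' must be \"median\" or a number")
  check_scalar(damping, "damping", 0.5, 1, strict_upper = TRUE)
  check_scalar(max_iter, "max_iter", 1)
  check_scalar(convergence_iter, "convergence_iter", 1)
  check_scalar(polish_max, "polish_max", 0)
  check_scalar(sample_cap, "sample_cap", 2)
  structure(list(similarity_alpha = similarity_alpha,
                 preference = preference, damping = damping,
                 max_iter = as.integer(max_iter),
                 convergence_iter = as.integer(convergence_iter),
                 polish_max = as.integer(polish_max),
                 sample_cap = as.integer(sample_cap),
                 seed = as.integer(seed)),
            class = "similarity_config")
}

#' Variance-penalized similarity matrix
#'
#' `S[i, j] = -dis(i, j) - alpha * (var_i + var_j)` where `dis` is the
#' Euclidean distance between points i and j and `var_i` is the mean
#' squared deviation of point i's features from their own mean. The
#' penalty pulls internally heterogeneous points apart, strengthening
#' within-cluster ties among points with similar feature profiles. The
#' diagonal is left to the preference setting (`NA` here).
#'
#' @param points Numeric `n x d` matrix of feature vectors, `n >= 2`.
#' @param config A [similarity_config()].
#' @return A `weighted_similarity` object: symmetric `n x n` matrix `S`
#'   (diagonal `NA`) plus the `points` used.
#' @export
weighted_similarity <- function(points, config = similarity_config()) {
  points <- as.matrix(points)
  if (!is.numeric(points) || any(!is.finite(points)))
    gs_data_error("'points' must be a finite numeric matrix")
  n <- nrow(points)
  if (n < 2) gs_data_error("need at least 2 points")
  D <- as.matrix(stats::dist(points, method = "euclidean"))
  vi <- apply(points, 1, function(r) mean((r - mean(r))^2))
  S <- -D - config$similarity_alpha * outer(vi, vi, "+")
  diag(S) <- NA_real_
  structure(list(S = S, points = points, config = config),
            class = "weighted_similarity")
}

#' Affinity propagation clustering
#'
#' Canonical responsibility/availability message passing over a similarity
#' matrix, with damping, exemplar-set convergence detection, and a tiny
#' seeded jitter to break exact symmetry deterministically (ties resolve to
#' the lowest index). Points are labeled with the exemplar maximizing
#' similarity; exemplars label themselves.
#'
#' @param sim A [weighted_similarity()] object or a symmetric numeric
#'   similarity matrix (diagonal ignored).
#' @param config A [similarity_config()].
#' @return A `cluster_assignment`: `exemplar_indices`, per-point `labels`
#'   (exemplar index per point), `n_clusters`, `cluster_means`, and a
#'   `converged` flag (a warning is raised when `max_iter` is hit first).
#' @export
affinity_propagation <- function(sim, config = similarity_config()) {
  points <- NULL
  if (inherits(sim, "weighted_similarity")) {
    points <- sim$points
    S <- sim$S
  } else S <- as.matrix(sim)
  n <- nrow(S)
  if (n == 1L) {
    return(structure(list(exemplar_indices = 1L, labels = 1L,
                          n_clusters = 1L,
                          cluster_means = if (!is.null(points)) points[1, , drop = FALSE],
                          converged = TRUE),
                     class = "cluster_assignment"))
  }
  off <- S[upper.tri(S) | lower.tri(S)]
  pref <- if (identical(config$preference, "median")) stats::median(off)
          else config$preference
  diag(S) <- pref
  # deterministic symmetry-breaking jitter, scaled well below the data
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  spread <- max(abs(off), abs(pref), 1e-12)
  S <- S + matrix(stats::rnorm(n * n), n, n) * 1e-10 * spread
  lam <- config$damping
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last_ex <- NULL; stable <- 0L; converged <- FALSE
  for (iter in seq_len(config$max_iter)) {
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- lam * R + (1 - lam) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- lam * A + (1 - lam) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last_ex) && length(ex) > 0) {
      stable <- stable + 1L
      if (stable >= config$convergence_iter) { converged <- TRUE; break }
    } else stable <- 0L
    last_ex <- ex
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  if (!converged)
    warning("affinity_propagation: exemplar set not stable at max_iter; returning current assignment")
  # canonical refinement: assign points to exemplars, then re-select each
  # cluster's exemplar as the member maximizing within-cluster similarity
  assign_to <- function(ex) {
    labels <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
    labels[ex] <- ex
    labels
  }
  labels <- assign_to(ex)
  Ssym <- S
  diag(Ssym) <- 0
  for (k in seq_along(ex)) {
    members <- which(labels == ex[k])
    if (length(members) > 1) {
      within <- colSums(Ssym[members, members, drop = FALSE])
      ex[k] <- members[which.max(within)]
    }
  }
  ex <- sort(unique(ex))
  # on small instances, polish the exemplar set by greedy local search on
  # the net similarity (message passing can stall a few percent short of
  # the optimum; at this size the polish is cheap and deterministic)
  if (n <= config$polish_max) ex <- polish_exemplars(S, ex)
  labels <- assign_to(ex)
  cluster_means <- NULL
  if (!is.null(points)) {
    cluster_means <- do.call(rbind, lapply(ex, function(e)
      colMeans(points[labels == e, , drop = FALSE])))
    rownames(cluster_means) <- as.character(ex)
  }
  structure(list(exemplar_indices = as.integer(ex),
                 labels = as.integer(labels),
                 n_clusters = length(ex),
                 cluster_means = cluster_means, converged = converged),
            class = "cluster_assignment")
}

# greedy add/remove/swap local search on net similarity; deterministic
# (first-improvement in fixed index order), terminates at a local optimum
polish_exemplars <- function(S, ex, max_pass = 50L) {
  n <- nrow(S)
  best <- net_similarity(S, ex)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (j in seq_len(n)) {           # toggle j in/out
      cand <- if (j %in% ex) setdiff(ex, j) else sort(c(ex, j))
      if (length(cand) == 0) next
      val <- net_similarity(S, cand)
      if (val > best + 1e-12) { ex <- cand; best <- val; improved <- TRUE }
    }
    for (k in ex) for (j in setdiff(seq_len(n), ex)) {   # swap k -> j
      cand <- sort(c(setdiff(ex, k), j))
      val <- net_similarity(S, cand)
      if (val > best + 1e-12) { ex <- cand; best <- val; improved <- TRUE }
    }
    if (!improved) break
  }
  ex
}

#' Net similarity of an exemplar set
#'
#' The quantity affinity propagation maximizes: every non-exemplar
#' contributes its similarity to the closest exemplar, every exemplar its
#' preference. Used with exhaustive enumeration as a small-instance oracle.
#'
#' @param S Similarity matrix with the preference on the diagonal.
#' @param exemplars Integer vector of exemplar indices.
#' @return The net similarity (a scalar).
#' @export
net_similarity <- function(S, exemplars) {
  n <- nrow(S)
  others <- setdiff(seq_len(n), exemplars)
  s <- sum(diag(S)[exemplars])
  if (length(others))
    s <- s + sum(apply(S[others, exemplars, drop = FALSE], 1, max))
  s
}

#' Cluster-weighted variance of each base model
#'
#' For each model (column) k of the sample-by-model matrix,
#' `w_k = (1/C) * sum over clusters i of sum_{j in cluster i}
#' (x[j, k] - mu[i, k])^2`, with `C` the number of clusters and `mu[i, k]`
#' the cluster mean of model k's values. Measures how inconsistently a
#' model predicts within groups of similar samples.
#'
#' @param X `samples x models` prediction matrix whose rows were clustered.
#' @param assignment A `cluster_assignment` over the rows of `X`.
#' @return Numeric vector of raw weights, one per model (column).
#' @export
cluster_weighted_variance <- function(X, assignment) {
  X <- as.matrix(X)
  if (length(assignment$labels) != nrow(X))
    gs_data_error("assignment does not match the rows of X")
  if (!all(assignment$labels %in% assignment$exemplar_indices))
    gs_data_error("label references a missing cluster")
  C <- assignment$n_clusters
  w <- numeric(ncol(X))
  for (e in assignment$exemplar_indices) {
    rows <- X[assignment$labels == e, , drop = FALSE]
    mu <- colMeans(rows)
    w <- w + colSums((rows - matrix(mu, nrow(rows), ncol(rows),
                                    byrow = TRUE))^2)
  }
  w / C
}

#' Normalize raw model weights
#'
#' Divides by the total so weights are nonnegative and sum to one. With
#' `invert = TRUE` each raw weight is first mapped to `1 / (w + 1e-8)`, so
#' models with *small* within-cluster variance are upweighted; the default
#' `FALSE` normalizes the raw variances as printed. All-zero input falls
#' back to uniform weights with a warning.
#'
#' @param w Nonnegative raw weights.
#' @param invert Apply the reciprocal before normalizing.
#' @return A `weight_vector`: `raw`, `weights` (sum to 1), `invert_flag`.
#' @export
normalize_weights <- function(w, invert = FALSE) {
  if (any(w < 0)) gs_data_error("raw weights must be nonnegative")
  raw <- w
  if (invert) w <- 1 / (w + 1e-8)
  tot <- sum(w)
  if (tot == 0) {
    warning("all raw weights zero: falling back to uniform weights")
    w <- rep(1 / length(w), length(w))
  } else w <- w / tot
  structure(list(raw = raw, weights = w, invert_flag = isTRUE(invert)),
            class = "weight_vector")
}

#' Convex combination of base-model predictions
#'
#' @param preds List of `m` equally shaped prediction matrices.
#' @param weights A `weight_vector` or numeric vector of `m` nonnegative
#'   weights summing to 1.
#' @return Elementwise weighted sum, same shape as each input.
#' @export
combine_predictions <- function(preds, weights) {
  if (inherits(weights, "weight_vector")) weights <- weights$weights
  if (length(preds) != length(weights))
    gs_data_error("need one weight per prediction matrix")
  dims <- lapply(preds, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    gs_data_error("prediction matrices must share a shape")
  out <- preds[[1]] * weights[1]
  for (k in seq_along(preds)[-1]) out <- out + preds[[k]] * weights[k]
  out
}
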