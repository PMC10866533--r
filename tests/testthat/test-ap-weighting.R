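test_that("variance-penalized similarity evaluates the defining formula", {
  pts <- rbind(c(1, 2), c(3, 4))
  # alpha = 0 reduces to the negated Euclidean distance matrix
  s0 <- weighted_similarity(pts, similarity_config(similarity_alpha = 0))
  expect_equal(s0$S[1, 2], -sqrt(8), tolerance = 1e-12)
  # worked case: dis = sqrt(8), var1 = var2 = 0.25, alpha = 0.5
  s5 <- weighted_similarity(pts, similarity_config(similarity_alpha = 0.5))
  expect_equal(s5$S[1, 2], -sqrt(8) - 0.25, tolerance = 1e-12)
  expect_equal(s5$S[1, 2], s5$S[2, 1])
  # duplicated rows: distance vanishes, only the variance penalty remains
  dup <- rbind(c(2, 4), c(2, 4))
  sd <- weighted_similarity(dup, similarity_config(similarity_alpha = 0.5))
  expect_equal(sd$S[1, 2], -2 * 0.5 * 1, tolerance = 1e-12)  # var = 1
  # off-diagonal entries are never positive for alpha >= 0
  set.seed(8)
  sr <- weighted_similarity(matrix(rnorm(24), 8, 3))
  expect_true(all(sr$S[upper.tri(sr$S)] <= 0))
  expect_error(weighted_similarity(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "gs_data_error")
})

test_that("a single point is its own exemplar", {
  a <- affinity_propagation(weighted_similarity(matrix(c(1, 2), 2, 1),
                                                similarity_config()))
  expect_true(a$n_clusters >= 1)
  one <- structure(list(S = matrix(NA_real_, 1, 1),
                        points = matrix(5, 1, 1),
                        config = similarity_config()),
                   class = "weighted_similarity")
  a1 <- affinity_propagation(one)
  expect_equal(a1$n_clusters, 1L)
  expect_equal(a1$labels, 1L)
})

test_that("two planted tight groups are recovered as two clusters", {
  pts <- rbind(matrix(rep(c(0, 0), 3), 3, 2, byrow = TRUE),
               matrix(rep(c(10, 10), 3), 3, 2, byrow = TRUE))
  cfg <- similarity_config()
  a <- affinity_propagation(weighted_similarity(pts, cfg), cfg)
  expect_equal(a$n_clusters, 2L)
  expect_true(any(a$exemplar_indices %in% 1:3))
  expect_true(any(a$exemplar_indices %in% 4:6))
  expect_equal(length(unique(a$labels[1:3])), 1L)
  expect_equal(length(unique(a$labels[4:6])), 1L)
  # matches the exhaustive optimum on this instance
  S <- weighted_similarity(pts, cfg)$S
  diag(S) <- median(S[upper.tri(S) | lower.tri(S)])
  expect_equal(net_similarity(S, a$exemplar_indices),
               ap_brute_force(S)$value, tolerance = 1e-9)
})

test_that("message passing stays within 1% of the exhaustive optimum (n <= 8)", {
  set.seed(42)
  cfg <- similarity_config()
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    ws <- weighted_similarity(pts, cfg)
    a <- affinity_propagation(ws, cfg)
    S <- ws$S
    diag(S) <- median(S[upper.tri(S) | lower.tri(S)])
    opt <- ap_brute_force(S)$value
    got <- net_similarity(S, a$exemplar_indices)
    expect_gte(got, opt - 0.01 * abs(opt))
  }
})

test_that("affinity propagation is deterministic given config and seed", {
  set.seed(1)
  pts <- matrix(rnorm(40), 20, 2)
  cfg <- similarity_config(seed = 9)
  a1 <- affinity_propagation(weighted_similarity(pts, cfg), cfg)
  a2 <- affinity_propagation(weighted_similarity(pts, cfg), cfg)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$exemplar_indices, a2$exemplar_indices)
})

test_that("cluster-weighted variance evaluates the defining sum", {
  # one model, one cluster {0, 2}: mean 1, C = 1 -> w = 2
  X1 <- matrix(c(0, 2), 2, 1)
  a1 <- structure(list(exemplar_indices = 1L, labels = c(1L, 1L),
                       n_clusters = 1L), class = "cluster_assignment")
  expect_equal(cluster_weighted_variance(X1, a1), 2)
  # two clusters {0,2} and {10,14}: contributions 2 and 8, C = 2 -> w = 5
  X2 <- matrix(c(0, 2, 10, 14), 4, 1)
  a2 <- structure(list(exemplar_indices = c(1L, 3L),
                       labels = c(1L, 1L, 3L, 3L), n_clusters = 2L),
                  class = "cluster_assignment")
  expect_equal(cluster_weighted_variance(X2, a2), 5)
  # a constant model column has zero weighted variance
  X3 <- cbind(X2, 7)
  expect_equal(cluster_weighted_variance(X3, a2)[2], 0)
  bad <- a2; bad$labels <- c(1L, 1L, 3L, 2L)
  expect_error(cluster_weighted_variance(X2, bad), class = "gs_data_error")
})

test_that("weight normalization sums to one and handles degeneracy", {
  expect_equal(normalize_weights(c(2, 2, 2))$weights, rep(1 / 3, 3))
  expect_equal(normalize_weights(c(1, 3))$weights, c(0.25, 0.75))
  expect_warning(w0 <- normalize_weights(c(0, 0, 0)), "uniform")
  expect_equal(w0$weights, rep(1 / 3, 3))
  set.seed(3)
  for (k in 1:20) {
    w <- normalize_weights(runif(3, 0, 10), invert = k %% 2 == 0)
    expect_true(all(w$weights >= 0))
    expect_lt(abs(sum(w$weights) - 1), 1e-9)
  }
  expect_error(normalize_weights(c(-1, 2)), class = "gs_data_error")
})

test_that("weighted combination is convex and respects one-hot weights", {
  set.seed(6)
  preds <- lapply(1:3, function(i) matrix(rnorm(12, i), 4, 3))
  one_hot <- normalize_weights(c(1, 0, 0), invert = FALSE)
  expect_equal(combine_predictions(preds, one_hot), preds[[1]])
  unif <- combine_predictions(preds, rep(1 / 3, 3))
  expect_equal(unif, (preds[[1]] + preds[[2]] + preds[[3]]) / 3)
  expect_equal(combine_predictions(list(matrix(10), matrix(20), matrix(30)),
                                   c(0.5, 0.3, 0.2)),
               matrix(17))
  # convexity: combination lies inside the per-element envelope
  comb <- combine_predictions(preds, c(0.2, 0.5, 0.3))
  lo <- pmin(preds[[1]], preds[[2]], preds[[3]])
  hi <- pmax(preds[[1]], preds[[2]], preds[[3]])
  expect_true(all(comb >= lo - 1e-12 & comb <= hi + 1e-12))
  expect_error(combine_predictions(preds[1:2], c(0.5, 0.3, 0.2)),
               class = "gs_data_error")
})

test_that("identical base predictions yield uniform weights and identity combination", {
  set.seed(11)
  val_targets <- rnorm(30)
  pred <- matrix(val_targets + rnorm(30, 0, 0.1), 30, 1)
  pts <- cbind(pred, pred, pred)
  cfg <- similarity_config()
  a <- affinity_propagation(weighted_similarity(pts, cfg), cfg)
  w <- normalize_weights(cluster_weighted_variance(pts, a))
  expect_equal(w$weights, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(combine_predictions(list(pred, pred, pred), w), pred)
})

test_that("an oracle column earns the largest inverted weight", {
  set.seed(13)
  truth <- c(rnorm(20, 0), rnorm(20, 5))   # two regimes of samples
  pts <- cbind(truth + rnorm(40, 0, 0.8),  # noisy model
               truth,                      # oracle: exact predictions
               truth + rnorm(40, 0, 1.2))  # noisier model
  cfg <- similarity_config()
  a <- affinity_propagation(weighted_similarity(pts, cfg), cfg)
  w <- normalize_weights(cluster_weighted_variance(pts, a), invert = TRUE)
  expect_equal(unname(which.max(w$weights)), 2L)
})
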