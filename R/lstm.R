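# Compact recurrent-network engine: LSTM cells (optionally peephole-
# augmented and bidirectional), backpropagation through time, Adam, and
# early stopping. Sized for short CGM windows (sequence lengths 6-18,
# univariate input); all heavy lifting is BLAS matrix multiplication.
#
# Parameter layout per cell: a single (d+H) x 4H matrix `WU` holding input
# and recurrent weights stacked row-wise, gate column blocks ordered
# [input | forget | candidate | output]; bias `b` (forget block initialized
# to 1); optional peephole vectors pi/pf/po of length H.

act_fun <- function(x, kind) {
  switch(kind,
         relu = pmax(x, 0),
         linear = x,
         tanh = tanh(x),
         gs_config_error(sprintf("unknown activation '%s'", kind)))
}

# derivative expressed through the activation *value* (valid for these three)
act_deriv <- function(a, kind) {
  switch(kind,
         relu = (a > 0) * 1,
         linear = 1,
         tanh = 1 - a * a)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_cell <- function(input_dim, H, peephole) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1          # open forget gate at start of training
  par <- list(WU = rbind(glorot(input_dim, 4 * H), glorot(H, 4 * H)), b = b)
  if (peephole) {
    par$pi <- stats::runif(H, -0.05, 0.05)
    par$pf <- stats::runif(H, -0.05, 0.05)
    par$po <- stats::runif(H, -0.05, 0.05)
  }
  par
}

brow <- function(v, B) matrix(v, B, length(v), byrow = TRUE)

# forward pass of one cell over a sequence.
# xs: list over time of B x d matrices. Returns hidden-state sequence (in
# original time indexing), the final processed state, and caches for BPTT.
cell_forward <- function(par, xs, activation, peephole, reverse = FALSE,
                         keep_cache = FALSE) {
  Tlen <- length(xs); B <- nrow(xs[[1]])
  H <- length(par$b) / 4L
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2L * H + idx_i
  idx_o <- 3L * H + idx_i
  bmat <- brow(par$b, B)
  if (peephole) {
    pim <- brow(par$pi, B); pfm <- brow(par$pf, B); pom <- brow(par$po, B)
  }
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", Tlen)
  caches <- if (keep_cache) vector("list", Tlen) else NULL
  order_t <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  for (step in seq_len(Tlen)) {
    t <- order_t[step]
    z <- cbind(xs[[t]], h) %*% par$WU + bmat
    zi <- z[, idx_i, drop = FALSE]; zf <- z[, idx_f, drop = FALSE]
    zg <- z[, idx_g, drop = FALSE]; zo <- z[, idx_o, drop = FALSE]
    if (peephole) { zi <- zi + cc * pim; zf <- zf + cc * pfm }
    gi <- sigmoid(zi); gf <- sigmoid(zf)
    gg <- act_fun(zg, activation)
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    if (peephole) zo <- zo + cc * pom
    go <- sigmoid(zo)
    ac <- act_fun(cc, activation)
    h_prev <- h
    h <- go * ac
    hs[[t]] <- h
    if (keep_cache)
      caches[[t]] <- list(x = xs[[t]], h_prev = h_prev, c_prev = c_prev,
                          gi = gi, gf = gf, gg = gg, go = go, cc = cc,
                          ac = ac)
  }
  list(hs = hs, h_final = h, caches = caches, order_t = order_t)
}

# BPTT for one cell. dh_seq: list over time of gradients flowing into h_t
# from above (NULL entries allowed). Returns parameter grads and dx_seq.
cell_backward <- function(par, fwd, dh_seq, activation, peephole, input_dim) {
  order_t <- fwd$order_t
  Tlen <- length(order_t)
  B <- nrow(fwd$h_final); H <- ncol(fwd$h_final)
  dWU <- matrix(0, nrow(par$WU), ncol(par$WU)); db <- numeric(4 * H)
  if (peephole) {
    dpi <- numeric(H); dpf <- numeric(H); dpo <- numeric(H)
    pim <- brow(par$pi, B); pfm <- brow(par$pf, B); pom <- brow(par$po, B)
  }
  dx_seq <- vector("list", Tlen)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  Ut <- t(par$WU)
  for (step in rev(seq_len(Tlen))) {
    t <- order_t[step]
    cc <- fwd$caches[[t]]
    dh <- dh_next
    if (!is.null(dh_seq[[t]])) dh <- dh + dh_seq[[t]]
    dc <- dc_next + dh * cc$go * act_deriv(cc$ac, activation)
    do_ <- dh * cc$ac
    dzo <- do_ * cc$go * (1 - cc$go)
    if (peephole) dc <- dc + dzo * pom
    di <- dc * cc$gg; df <- dc * cc$c_prev; dg <- dc * cc$gi
    dzi <- di * cc$gi * (1 - cc$gi)
    dzf <- df * cc$gf * (1 - cc$gf)
    dzg <- dg * act_deriv(cc$gg, activation)
    dc_prev <- dc * cc$gf
    if (peephole) {
      dc_prev <- dc_prev + dzi * pim + dzf * pfm
      dpi <- dpi + colSums(dzi * cc$c_prev)
      dpf <- dpf + colSums(dzf * cc$c_prev)
      dpo <- dpo + colSums(dzo * cc$cc)
    }
    dz <- cbind(dzi, dzf, dzg, dzo)
    dinp <- dz %*% Ut
    dx_seq[[t]] <- dinp[, seq_len(input_dim), drop = FALSE]
    dh_next <- dinp[, input_dim + seq_len(H), drop = FALSE]
    dWU <- dWU + crossprod(cbind(cc$x, cc$h_prev), dz)
    db <- db + colSums(dz)
    dc_next <- dc_prev
  }
  out <- list(dWU = dWU, db = db, dx_seq = dx_seq)
  if (peephole) { out$dpi <- dpi; out$dpf <- dpf; out$dpo <- dpo }
  out
}

# ---- whole-network assembly -------------------------------------------

# arch: list of layer descriptors list(units, activation, peephole,
# bidirectional); only the final recurrent layer feeds the dense head
# (its last hidden state; for bidirectional layers the concatenation of
# both directions' final states).

net_init <- function(arch, input_dim, output_dim) {
  params <- list()
  d <- input_dim
  for (l in seq_along(arch)) {
    ly <- arch[[l]]
    if (ly$bidirectional) {
      params[[paste0("l", l, ".f")]] <- init_cell(d, ly$units, ly$peephole)
      params[[paste0("l", l, ".b")]] <- init_cell(d, ly$units, ly$peephole)
      d <- 2L * ly$units
    } else {
      params[[paste0("l", l)]] <- init_cell(d, ly$units, ly$peephole)
      d <- ly$units
    }
  }
  params$dense <- list(W = glorot(d, output_dim), b = numeric(output_dim))
  params
}

net_forward <- function(params, arch, X, keep_cache = FALSE) {
  B <- nrow(X)
  xs <- lapply(seq_len(ncol(X)), function(t) X[, t, drop = FALSE])
  fwds <- vector("list", length(arch))
  for (l in seq_along(arch)) {
    ly <- arch[[l]]
    last <- l == length(arch)
    if (ly$bidirectional) {
      ff <- cell_forward(params[[paste0("l", l, ".f")]], xs, ly$activation,
                         ly$peephole, reverse = FALSE, keep_cache = keep_cache)
      fb <- cell_forward(params[[paste0("l", l, ".b")]], xs, ly$activation,
                         ly$peephole, reverse = TRUE, keep_cache = keep_cache)
      fwds[[l]] <- list(f = ff, b = fb)
      state <- cbind(ff$h_final, fb$h_final)
      if (!last) xs <- lapply(seq_along(xs),
                              function(t) cbind(ff$hs[[t]], fb$hs[[t]]))
    } else {
      fw <- cell_forward(params[[paste0("l", l)]], xs, ly$activation,
                         ly$peephole, keep_cache = keep_cache)
      fwds[[l]] <- fw
      state <- fw$h_final
      if (!last) xs <- fw$hs
    }
  }
  yhat <- state %*% params$dense$W + brow(params$dense$b, B)
  list(yhat = yhat, state = state, fwds = fwds)
}

# mean-squared-error loss and full gradient set for one minibatch
net_loss_grads <- function(params, arch, X, Y) {
  fwd <- net_forward(params, arch, X, keep_cache = TRUE)
  B <- nrow(X); p <- ncol(Y)
  err <- fwd$yhat - Y
  loss <- mean(err * err)
  dy <- 2 * err / (B * p)
  grads <- list()
  grads$dense <- list(W = crossprod(fwd$state, dy), b = colSums(dy))
  dstate <- dy %*% t(params$dense$W)
  Tlen <- ncol(X)
  dh_above <- NULL  # list over time, for non-final layers
  for (l in rev(seq_along(arch))) {
    ly <- arch[[l]]
    last <- l == length(arch)
    input_dim <- if (l == 1) 1L else {
      below <- arch[[l - 1]]
      if (below$bidirectional) 2L * below$units else below$units
    }
    if (ly$bidirectional) {
      H <- ly$units
      dh_f <- vector("list", Tlen); dh_b <- vector("list", Tlen)
      if (last) {
        dh_f[[Tlen]] <- dstate[, seq_len(H), drop = FALSE]
        dh_b[[1]] <- dstate[, H + seq_len(H), drop = FALSE]
      } else {
        for (t in seq_len(Tlen)) {
          dh_f[[t]] <- dh_above[[t]][, seq_len(H), drop = FALSE]
          dh_b[[t]] <- dh_above[[t]][, H + seq_len(H), drop = FALSE]
        }
      }
      bf <- cell_backward(params[[paste0("l", l, ".f")]], fwd$fwds[[l]]$f,
                          dh_f, ly$activation, ly$peephole, input_dim)
      bb <- cell_backward(params[[paste0("l", l, ".b")]], fwd$fwds[[l]]$b,
                          dh_b, ly$activation, ly$peephole, input_dim)
      grads[[paste0("l", l, ".f")]] <- bf[setdiff(names(bf), "dx_seq")]
      grads[[paste0("l", l, ".b")]] <- bb[setdiff(names(bb), "dx_seq")]
      if (l > 1)
        dh_above <- lapply(seq_len(Tlen),
                           function(t) bf$dx_seq[[t]] + bb$dx_seq[[t]])
    } else {
      dh_seq <- vector("list", Tlen)
      if (last) dh_seq[[Tlen]] <- dstate else dh_seq <- dh_above
      bk <- cell_backward(params[[paste0("l", l)]], fwd$fwds[[l]], dh_seq,
                          ly$activation, ly$peephole, input_dim)
      grads[[paste0("l", l)]] <- bk[setdiff(names(bk), "dx_seq")]
      if (l > 1) dh_above <- bk$dx_seq
    }
  }
  list(loss = loss, grads = grads)
}

# map grad names to param fields (dWU -> WU, db -> b, dpi -> pi, ...)
grad_field <- function(nm) sub("^d", "", nm)

flatten_grads <- function(grads) {
  out <- list()
  for (blk in names(grads))
    for (nm in names(grads[[blk]]))
      out[[paste0(blk, "$", nm)]] <- grads[[blk]][[nm]]
  out
}

global_norm <- function(gl) sqrt(sum(vapply(gl, function(g) sum(g * g), 0)))

adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, clip_norm = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fg <- flatten_grads(grads)
  gn <- global_norm(fg)
  scale <- if (is.finite(clip_norm) && gn > clip_norm) clip_norm / gn else 1
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t; corr2 <- 1 - beta2^state$t
  for (blk in names(grads)) {
    pfieldmap <- names(grads[[blk]])
    for (nm in pfieldmap) {
      pf <- grad_field(nm)
      g <- grads[[blk]][[nm]] * scale
      m <- state$m[[blk]][[pf]] * beta1 + (1 - beta1) * g
      v <- state$v[[blk]][[pf]] * beta2 + (1 - beta2) * g * g
      state$m[[blk]][[pf]] <- m
      state$v[[blk]][[pf]] <- v
      params[[blk]][[pf]] <- params[[blk]][[pf]] -
        lr * (m / corr1) / (sqrt(v / corr2) + eps)
    }
  }
  list(params = params, state = state)
}

mse_of <- function(params, arch, X, Y, chunk = 4096L) {
  n <- nrow(X); s <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    yh <- net_forward(params, arch, X[idx, , drop = FALSE])$yhat
    s <- s + sum((yh - Y[idx, , drop = FALSE])^2)
  }
  s / (n * ncol(Y))
}

# full training loop with shuffled minibatches and early stopping on
# validation loss; best-validation weights restored on exit.
lstm_fit <- function(arch, X, Y, Xval, Yval, output_dim,
                     learning_rate = 0.001, batch_size = 32L,
                     max_epochs = 500L, patience = 10L, shuffle = TRUE,
                     clip_norm = 1, seed = 1L) {
  set.seed(seed)
  params <- net_init(arch, 1L, output_dim)
  ad <- adam_init(params)
  n <- nrow(X)
  best <- list(params = params, val = Inf, epoch = 0L)
  hist_train <- numeric(0); hist_val <- numeric(0)
  stall <- 0L
  have_val <- !is.null(Xval) && nrow(Xval) > 0
  for (epoch in seq_len(max_epochs)) {
    ord <- if (shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(n, start + batch_size - 1L)]
      lg <- net_loss_grads(params, arch, X[idx, , drop = FALSE],
                           Y[idx, , drop = FALSE])
      upd <- adam_step(params, lg$grads, ad, learning_rate, clip_norm)
      params <- upd$params; ad <- upd$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    hist_train <- c(hist_train, ep_loss / nb)
    if (have_val) {
      vl <- mse_of(params, arch, Xval, Yval)
      hist_val <- c(hist_val, vl)
      if (vl < best$val) {
        best <- list(params = params, val = vl, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (is.finite(patience) && stall >= patience) break
      }
    } else {
      best <- list(params = params, val = hist_train[epoch], epoch = epoch)
    }
  }
  list(params = best$params, arch = arch,
       history = list(train = hist_train, val = hist_val),
       epochs_run = length(hist_train), best_epoch = best$epoch,
       best_val = best$val)
}
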