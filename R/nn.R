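# The per-member network and its gradients, written against base R matrix
# algebra. Layout convention: a batch of token sequences (B x T id matrix,
# pad id 0) is embedded into a stacked matrix X of shape (B*T) x d where the
# rows for timestep t are ((t-1)*B + 1):(t*B). This makes the input
# projection of a recurrent layer a single large matrix product, leaving only
# the (small) hidden-to-hidden products inside the time loop.
#
# Architecture per member: embedding -> dropout -> bidirectional RNN layer 1
# (GRU or LSTM, outputs the full sequence) -> bidirectional RNN layer 2
# (final states only) -> layer normalization -> dense(32, relu) -> dropout ->
# dense(16, relu) -> dropout -> two 1-unit heads: linear mu and softplus
# sigma (floored). Backpropagation is implemented by hand and verified
# against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Member network configuration
#'
#' Hyperparameters of one ensemble member. Reference defaults follow the
#' deployed solubility model: 64-dimensional embedding, two bidirectional
#' recurrent layers of 64 units, dense layers of 32 and 16 units, dropout
#' 0.35 after the embedding and after each dense layer.
#'
#' @param vocab_size Number of token ids (including pad and unknown).
#' @param embed_dim Embedding dimension.
#' @param rnn_kind \code{"gru"} or \code{"lstm"}.
#' @param rnn_units Hidden units per direction in each recurrent layer.
#' @param dense_units Two hidden dense layer widths.
#' @param dropout Dropout rate in [0, 1).
#' @param sigma_floor Additive floor on the predicted standard deviation
#'   (log S units); keeps the Gaussian likelihood finite.
#' @param max_len Padded sequence length.
#' @return A list of class \code{soluq_member_config}.
#' @export
member_config <- function(vocab_size, embed_dim = 64L, rnn_kind = c("lstm", "gru"),
                          rnn_units = 64L, dense_units = c(32L, 16L),
                          dropout = 0.35, sigma_floor = 1e-3, max_len = 128L) {
  rnn_kind <- match.arg(rnn_kind)
  stopifnot(vocab_size >= 2L, embed_dim >= 1L, rnn_units >= 1L,
            length(dense_units) == 2L, all(dense_units >= 1L),
            dropout >= 0, dropout < 1, sigma_floor > 0, max_len >= 1L)
  structure(list(vocab_size = as.integer(vocab_size),
                 embed_dim = as.integer(embed_dim), rnn_kind = rnn_kind,
                 rnn_units = as.integer(rnn_units),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 sigma_floor = sigma_floor, max_len = as.integer(max_len)),
            class = "soluq_member_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Initialize one member's parameters. Per-member seeds are the diversity
# source of the deep ensemble.
nn_init <- function(config, seed) {
  u <- config$rnn_units
  d <- config$embed_dim
  ng <- if (config$rnn_kind == "gru") 3L else 4L
  rnn_dir <- function(nin) {
    p <- list(Wx = glorot(nin, ng * u), Wh = glorot(u, ng * u),
              b = rep(0, ng * u))
    if (config$rnn_kind == "lstm") p$b[(u + 1L):(2L * u)] <- 1  # forget gate
    p
  }
  with_seed(seed, {
    params <- list(
      emb = matrix(stats::rnorm(config$vocab_size * d, 0, 0.05),
                   config$vocab_size, d),
      l1f = rnn_dir(d), l1b = rnn_dir(d),
      l2f = rnn_dir(2L * u), l2b = rnn_dir(2L * u),
      ln_g = rep(1, 2L * u), ln_b = rep(0, 2L * u),
      W1 = glorot(2L * u, config$dense_units[1]), b1 = rep(0, config$dense_units[1]),
      W2 = glorot(config$dense_units[1], config$dense_units[2]),
      b2 = rep(0, config$dense_units[2]),
      Wmu = glorot(config$dense_units[2], 1L), bmu = 0,
      Ws = glorot(config$dense_units[2], 1L), bs = 0)
    params
  })
}

# Row indices of timestep t in the stacked layout.
t_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Index vector that reverses each sequence within its own length in the
# stacked layout; an involution (applying it twice is the identity).
reverse_rows <- function(lengths, T) {
  B <- length(lengths)
  idx <- integer(B * T)
  for (b in seq_len(B)) {
    L <- lengths[b]
    tt <- seq_len(T)
    rt <- ifelse(tt <= L, L - tt + 1L, tt)
    idx[(tt - 1L) * B + b] <- (rt - 1L) * B + b
  }
  idx
}

# --- one-direction recurrent layer ----------------------------------------
# The input projection XW = X Wx + b is one large BLAS product here; the
# per-timestep recurrence and backpropagation-through-time run in compiled
# code (src/rnn.cpp). dO is the gradient on the masked per-timestep
# outputs; dHlast on the carried final state.

rnn_forward_dir <- function(X, p, kind, u, B, T, maskv) {
  res <- rnn_fwd_cpp(X %*% p$Wx, p$Wh, p$b, maskv, B, T,
                     if (kind == "gru") 0L else 1L)
  list(O = res$O, Hlast = res$Hlast, cache = res)
}

rnn_backward_dir <- function(X, p, kind, u, B, T, maskv, fwd, dO, dHlast) {
  r <- rnn_bwd_cpp(p$Wh, fwd$cache, maskv, dO, dHlast, B, T,
                   if (kind == "gru") 0L else 1L)
  list(dX = r$dXW %*% t(p$Wx), dWx = crossprod(X, r$dXW), dWh = r$dWh,
       db = colSums(r$dXW))
}

# --- full member forward ---------------------------------------------------
# ids: B x T integer matrix of 0-based ids (0 = pad). lengths: B.
# X_override: optional (B*T) x d embedded input replacing the embedding
# lookup. X_offset: optional additive perturbation applied after the lookup
# (the adversarial step; gradients still reach the embedding rows). Dropout
# masks are sampled from the current RNG when training = TRUE.

nn_forward <- function(params, config, ids, lengths, training = FALSE,
                       X_override = NULL, X_offset = NULL) {
  B <- nrow(ids); T <- ncol(ids)
  u <- config$rnn_units
  if (any(ids >= config$vocab_size)) {
    stop("token id >= vocab_size (", config$vocab_size, ")", call. = FALSE)
  }
  idvec <- as.vector(ids) + 1L
  X0 <- if (is.null(X_override)) params$emb[idvec, , drop = FALSE] else X_override
  if (!is.null(X_offset)) X0 <- X0 + X_offset
  # mask from lengths, not ids: position t of sample b is live iff t <= length
  maskv <- as.numeric(rep(seq_len(T), each = B) <=
                        lengths[rep(seq_len(B), times = T)])
  drop_mask <- function(nr, nc) {
    if (!training || config$dropout == 0) return(NULL)
    matrix(stats::rbinom(nr * nc, 1L, 1 - config$dropout), nr, nc) /
      (1 - config$dropout)
  }
  m0 <- drop_mask(nrow(X0), ncol(X0))
  X <- if (is.null(m0)) X0 else X0 * m0
  rev_idx <- reverse_rows(lengths, T)
  f1 <- rnn_forward_dir(X, params$l1f, config$rnn_kind, u, B, T, maskv)
  b1 <- rnn_forward_dir(X[rev_idx, , drop = FALSE], params$l1b,
                        config$rnn_kind, u, B, T, maskv)
  O1 <- cbind(f1$O, b1$O[rev_idx, , drop = FALSE])
  f2 <- rnn_forward_dir(O1, params$l2f, config$rnn_kind, u, B, T, maskv)
  b2 <- rnn_forward_dir(O1[rev_idx, , drop = FALSE], params$l2b,
                        config$rnn_kind, u, B, T, maskv)
  Hcat <- cbind(f2$Hlast, b2$Hlast)
  # layer normalization over features, learned gain/bias
  eps <- 1e-5
  mu_ln <- rowMeans(Hcat)
  xc <- Hcat - mu_ln
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gmat <- matrix(params$ln_g, B, 2 * u, byrow = TRUE)
  Y <- xhat * gmat + matrix(params$ln_b, B, 2 * u, byrow = TRUE)
  Z1 <- Y %*% params$W1 + matrix(params$b1, B, length(params$b1), byrow = TRUE)
  A1 <- pmax(Z1, 0)
  m1 <- drop_mask(nrow(A1), ncol(A1))
  A1d <- if (is.null(m1)) A1 else A1 * m1
  Z2 <- A1d %*% params$W2 + matrix(params$b2, B, length(params$b2), byrow = TRUE)
  A2 <- pmax(Z2, 0)
  m2 <- drop_mask(nrow(A2), ncol(A2))
  A2d <- if (is.null(m2)) A2 else A2 * m2
  mu <- as.vector(A2d %*% params$Wmu + params$bmu)
  sraw <- as.vector(A2d %*% params$Ws + params$bs)
  sigma <- softplus(sraw) + config$sigma_floor
  list(mu = mu, sigma2 = sigma^2,
       cache = list(B = B, T = T, idvec = idvec, maskv = maskv,
                    rev_idx = rev_idx, X0 = X0, X = X, m0 = m0,
                    f1 = f1, b1 = b1, O1 = O1, f2 = f2, b2 = b2,
                    xhat = xhat, istd = istd, Y = Y, Z1 = Z1, A1d = A1d,
                    Z2 = Z2, A2d = A2d, m1 = m1, m2 = m2,
                    sraw = sraw, sigma = sigma))
}

# Backward pass from gradients on (mu, sigma2). Returns the full parameter
# gradient list plus dX (gradient on the pre-dropout embedded input, used
# for the adversarial perturbation) and dEmb scatter.
nn_backward <- function(params, config, fwd, dmu, dsigma2) {
  cc <- fwd$cache
  B <- cc$B; T <- cc$T; u <- config$rnn_units
  dsigma <- dsigma2 * 2 * cc$sigma
  dsraw <- dsigma * sigmoid(cc$sraw)
  dA2d <- outer(dmu, as.vector(params$Wmu)) + outer(dsraw, as.vector(params$Ws))
  g <- list()
  g$Wmu <- t(cc$A2d) %*% matrix(dmu, B, 1); g$bmu <- sum(dmu)
  g$Ws <- t(cc$A2d) %*% matrix(dsraw, B, 1); g$bs <- sum(dsraw)
  dA2 <- if (is.null(cc$m2)) dA2d else dA2d * cc$m2
  dZ2 <- dA2 * (cc$Z2 > 0)
  g$W2 <- t(cc$A1d) %*% dZ2; g$b2 <- colSums(dZ2)
  dA1d <- dZ2 %*% t(params$W2)
  dA1 <- if (is.null(cc$m1)) dA1d else dA1d * cc$m1
  dZ1 <- dA1 * (cc$Z1 > 0)
  g$W1 <- t(cc$Y) %*% dZ1; g$b1 <- colSums(dZ1)
  dY <- dZ1 %*% t(params$W1)
  # layer norm backward
  gmat <- matrix(params$ln_g, B, 2 * u, byrow = TRUE)
  g$ln_g <- colSums(dY * cc$xhat)
  g$ln_b <- colSums(dY)
  dxhat <- dY * gmat
  nf <- 2 * u
  dHcat <- cc$istd * (dxhat - rowMeans(dxhat) -
                        cc$xhat * rowMeans(dxhat * cc$xhat))
  dH2f <- dHcat[, 1:u, drop = FALSE]
  dH2b <- dHcat[, (u + 1):(2 * u), drop = FALSE]
  zeroO <- matrix(0, B * T, u)
  bk2f <- rnn_backward_dir(cc$O1, params$l2f, config$rnn_kind, u, B, T,
                           cc$maskv, cc$f2, zeroO, dH2f)
  O1r <- cc$O1[cc$rev_idx, , drop = FALSE]
  bk2b <- rnn_backward_dir(O1r, params$l2b, config$rnn_kind, u, B, T,
                           cc$maskv, cc$b2, zeroO, dH2b)
  dO1 <- bk2f$dX + bk2b$dX[cc$rev_idx, , drop = FALSE]
  dO1f <- dO1[, 1:u, drop = FALSE]
  dO1b <- dO1[, (u + 1):(2 * u), drop = FALSE]
  zeroH <- matrix(0, B, u)
  bk1f <- rnn_backward_dir(cc$X, params$l1f, config$rnn_kind, u, B, T,
                           cc$maskv, cc$f1, dO1f, zeroH)
  bk1b <- rnn_backward_dir(cc$X[cc$rev_idx, , drop = FALSE], params$l1b,
                           config$rnn_kind, u, B, T, cc$maskv, cc$b1,
                           dO1b[cc$rev_idx, , drop = FALSE], zeroH)
  dXdrop <- bk1f$dX + bk1b$dX[cc$rev_idx, , drop = FALSE]
  dX <- if (is.null(cc$m0)) dXdrop else dXdrop * cc$m0
  dEmb <- matrix(0, config$vocab_size, config$embed_dim)
  agg <- rowsum(dX, cc$idvec)
  dEmb[as.integer(rownames(agg)), ] <- agg
  g$emb <- dEmb
  g$l1f <- list(Wx = bk1f$dWx, Wh = bk1f$dWh, b = bk1f$db)
  g$l1b <- list(Wx = bk1b$dWx, Wh = bk1b$dWh, b = bk1b$db)
  g$l2f <- list(Wx = bk2f$dWx, Wh = bk2f$dWh, b = bk2f$db)
  g$l2b <- list(Wx = bk2b$dWx, Wh = bk2b$dWh, b = bk2b$db)
  g <- g[names(params)]  # align ordering with the parameter list
  g$dX <- dX
  g
}

# --- parameter-list arithmetic and Adam ------------------------------------

param_map <- function(p, f) {
  lapply(p, function(x) if (is.list(x)) lapply(x, f) else f(x))
}

param_map2 <- function(a, b, f) {
  out <- a
  for (nm in names(a)) {
    if (is.list(a[[nm]])) {
      for (nm2 in names(a[[nm]])) out[[nm]][[nm2]] <- f(a[[nm]][[nm2]], b[[nm]][[nm2]])
    } else {
      out[[nm]] <- f(a[[nm]], b[[nm]])
    }
  }
  out
}

# Flatten a parameter list to one numeric vector (and back); used by the
# finite-difference gradient checks and the text serializer.
param_flatten <- function(p) {
  unlist(lapply(p, function(x) if (is.list(x)) unlist(x) else as.vector(x)),
         use.names = FALSE)
}

param_unflatten <- function(template, v) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- v[(i + 1L):(i + n)]
    i <<- i + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  lapply(template, fill)
}

adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  grads$dX <- NULL
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v,
                    function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  params <- param_map2(params, upd, `-`)
  list(params = params, state = state)
}
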