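# The network and its hand-written backpropagation.

tiny_cfg <- function(kind) {
  member_config(vocab_size = 7, embed_dim = 3, rnn_kind = kind, rnn_units = 4,
                dense_units = c(5, 3), dropout = 0, sigma_floor = 1e-3,
                max_len = 6)
}

tiny_batch <- function() {
  list(ids = matrix(c(1, 2, 3, 4, 0, 0,
                      2, 2, 5, 6, 1, 3,
                      6, 0, 0, 0, 0, 0), nrow = 3, byrow = TRUE),
       lengths = c(4, 6, 1), y = c(0.5, -1.2, 2.0))
}

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  for (kind in c("gru", "lstm")) {
    cfg <- tiny_cfg(kind)
    params <- soluq:::nn_init(cfg, 1)
    b <- tiny_batch()
    lossfun <- function(p) {
      fwd <- soluq:::nn_forward(p, cfg, b$ids, b$lengths, training = FALSE)
      nll_loss(fwd$mu, fwd$sigma2, b$y)
    }
    fwd <- soluq:::nn_forward(params, cfg, b$ids, b$lengths, training = FALSE)
    gr <- soluq:::nll_grad(fwd$mu, fwd$sigma2, b$y)
    grads <- soluq:::nn_backward(params, cfg, fwd, gr$dmu, gr$dsigma2)
    dX <- grads$dX
    grads$dX <- NULL
    flat <- soluq:::param_flatten(params)
    gflat <- soluq:::param_flatten(grads)
    expect_length(gflat, length(flat))
    eps <- 1e-6
    idx <- sort(sample(length(flat), 120))
    num <- vapply(idx, function(i) {
      p1 <- flat; p1[i] <- p1[i] + eps
      p2 <- flat; p2[i] <- p2[i] - eps
      (lossfun(soluq:::param_unflatten(params, p1)) -
         lossfun(soluq:::param_unflatten(params, p2))) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - gflat[idx]) / pmax(1, abs(num))), 1e-5)
    # gradient with respect to the embedded input (the adversarial direction)
    X0 <- params$emb[as.vector(b$ids) + 1L, ]
    lossX <- function(X) {
      fwd <- soluq:::nn_forward(params, cfg, b$ids, b$lengths, FALSE,
                                X_override = X)
      nll_loss(fwd$mu, fwd$sigma2, b$y)
    }
    ii <- sample(length(X0), 30)
    numX <- vapply(ii, function(i) {
      a <- X0; a[i] <- a[i] + eps
      d <- X0; d[i] <- d[i] - eps
      (lossX(a) - lossX(d)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(numX - dX[ii])), 1e-6)
  }
})

test_that("inference is deterministic and the variance floor binds", {
  cfg <- tiny_cfg("lstm")
  params <- soluq:::nn_init(cfg, 3)
  b <- tiny_batch()
  f1 <- soluq:::nn_forward(params, cfg, b$ids, b$lengths, training = FALSE)
  f2 <- soluq:::nn_forward(params, cfg, b$ids, b$lengths, training = FALSE)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_true(all(f1$sigma2 >= cfg$sigma_floor^2))
  expect_error(soluq:::nn_forward(params, cfg, matrix(99L, 1, 2), 2L),
               "vocab_size")
})

test_that("padding beyond the sequence length cannot affect the output", {
  for (kind in c("gru", "lstm")) {
    cfg <- tiny_cfg(kind)
    params <- soluq:::nn_init(cfg, 5)
    ids_short <- matrix(c(2L, 5L, 3L), 1, 3)
    ids_padded <- cbind(ids_short, matrix(0L, 1, 3))
    ids_garbage <- cbind(ids_short, matrix(c(4L, 1L, 6L), 1, 3))  # dead ids
    f_short <- soluq:::nn_forward(params, cfg, ids_short, 3L, FALSE)
    f_pad <- soluq:::nn_forward(params, cfg, ids_padded, 3L, FALSE)
    f_garbage <- soluq:::nn_forward(params, cfg, ids_garbage, 3L, FALSE)
    expect_equal(f_pad$mu, f_short$mu, tolerance = 1e-12)
    expect_equal(f_pad$sigma2, f_short$sigma2, tolerance = 1e-12)
    expect_equal(f_garbage$mu, f_short$mu, tolerance = 1e-12)
  }
})

test_that("ensemble aggregation equals Gaussian-mixture moments", {
  # singleton
  one <- ensemble_aggregate(2.0, 0.5)
  expect_equal(one$mu, 2.0)
  expect_equal(one$sigma2_ale, 0.5)
  expect_equal(one$sigma2_epi, 0)
  # two members, hand-computed mixture moments
  two <- ensemble_aggregate(c(0, 2), c(1, 1))
  expect_equal(two$mu, 1)
  expect_equal(two$sigma2_ale, 1)
  expect_equal(two$sigma2_epi, 1)
  expect_equal(two$sigma2_total, 2)
  expect_error(ensemble_aggregate(numeric(0), numeric(0)))
  expect_error(ensemble_aggregate(c(0, 1), c(1, -1)), "positive")
})

test_that("aggregation is permutation-symmetric and epi vanishes iff equal", {
  set.seed(9)
  mu <- matrix(rnorm(5 * 8), 5, 8)
  s2 <- matrix(rexp(5 * 8) + 0.1, 5, 8)
  a <- ensemble_aggregate(mu, s2)
  b <- ensemble_aggregate(mu[, 8:1], s2[, 8:1])
  expect_equal(a, b, tolerance = 1e-14)
  same <- ensemble_aggregate(matrix(1.5, 2, 6), matrix(0.3, 2, 6))
  expect_equal(same$sigma2_epi, c(0, 0))
  expect_true(all(a$sigma2_epi > 0))
})

test_that("model bundles round-trip through the plain-text format", {
  cfg <- tiny_cfg("gru")
  params <- soluq:::nn_init(cfg, 8)
  path <- withr::local_tempfile()
  soluq:::write_params_text(params, path)
  back <- soluq:::read_params_text(path, soluq:::nn_init(cfg, 9))
  expect_equal(back, params, tolerance = 1e-15)
})
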