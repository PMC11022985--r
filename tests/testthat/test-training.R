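test_that("the loss equals the exact negative Gaussian log density", {
  expect_equal(nll_loss(0, 1, 0), 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_identical(nll_loss(2, 1 / (2 * pi), 2), 0)
  set.seed(31)
  mu <- rnorm(10000)
  sigma2 <- rexp(10000) + 0.01
  y <- rnorm(10000)
  closed_form <- -dnorm(y, mean = mu, sd = sqrt(sigma2), log = TRUE)
  expect_lt(max(abs(nll_loss(mu, sigma2, y, reduce = FALSE) - closed_form)),
            1e-10)
  expect_equal(nll_loss(mu, sigma2, y), mean(closed_form), tolerance = 1e-12)
  # strictly increasing in |y - mu| at fixed variance
  ls <- nll_loss(0, 0.7, c(0.1, 0.5, 1, 2), reduce = FALSE)
  expect_true(all(diff(ls) > 0))
  expect_error(nll_loss(0, 0, 0), "positive")
  expect_error(nll_loss(0, -1, 0), "positive")
})

test_that("loss gradients match finite differences", {
  set.seed(5)
  mu <- rnorm(20); s2 <- rexp(20) + 0.1; y <- rnorm(20)
  gr <- soluq:::nll_grad(mu, s2, y)
  eps <- 1e-7
  for (i in c(1, 7, 20)) {
    m1 <- mu; m1[i] <- m1[i] + eps
    m2 <- mu; m2[i] <- m2[i] - eps
    expect_equal(gr$dmu[i], (nll_loss(m1, s2, y) - nll_loss(m2, s2, y)) / (2 * eps),
                 tolerance = 1e-6)
    s1 <- s2; s1[i] <- s1[i] + eps
    s0 <- s2; s0[i] <- s0[i] - eps
    expect_equal(gr$dsigma2[i], (nll_loss(mu, s1, y) - nll_loss(mu, s0, y)) / (2 * eps),
                 tolerance = 1e-6)
  }
})

test_that("the adversarial perturbation is an exact signed epsilon step", {
  set.seed(2)
  X <- matrix(rnorm(20), 4, 5)
  G <- matrix(rnorm(20), 4, 5)
  G[2, 3] <- 0
  out <- adversarial_embed(X, G, 0.05)
  delta <- out - X
  expect_equal(abs(delta[G != 0]), rep(0.05, sum(G != 0)), tolerance = 1e-12)
  expect_identical(delta[2, 3], 0)
  expect_identical(adversarial_embed(X, G, 0), X)
  expect_error(adversarial_embed(X, G[, 1:4], 0.1), "shapes")
  expect_error(adversarial_embed(X, G, -1), "non-negative")
})

test_that("a small FGSM step does not decrease a smooth quadratic loss", {
  # first-order oracle on l(x) = sum((x - c)^2) / 2
  set.seed(8)
  x <- rnorm(30)
  cc <- rnorm(30)
  g <- x - cc
  for (eps in c(1e-4, 1e-3, 1e-2)) {
    xp <- adversarial_embed(matrix(x, 1), matrix(g, 1), eps)
    expect_gte(sum((xp - cc)^2), sum((x - cc)^2))
  }
})

test_that("epsilon = 0 adversarial training equals two clean updates", {
  toy <- fx_toy_tokens()
  cfg <- member_config(vocab_size = toy$vocab_size, embed_dim = 4,
                       rnn_kind = "gru", rnn_units = 4, dense_units = c(5, 3),
                       dropout = 0, max_len = ncol(toy$ids))
  tc0 <- train_config(learning_rate = 1e-2, epsilon_adv = 0,
                      adversarial = TRUE, epochs = 2, batch_size = 10,
                      ensemble_size = 1)
  fit_adv <- train_member(toy$ids, toy$lengths, toy$y, cfg, tc0, seed = 3)
  # oracle: hand-rolled loop doing two plain NLL updates per batch, with the
  # same RNG stream (dropout is off so the streams stay aligned)
  member <- list(params = soluq:::nn_init(cfg, 3), config = cfg)
  member$opt <- soluq:::adam_init(member$params)
  n <- nrow(toy$ids)
  soluq:::with_seed(soluq:::derive_seed(3, 7L), {
    for (epoch in 1:2) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = 10)) {
        sel <- ord[s:min(n, s + 9)]
        Tb <- max(toy$lengths[sel])
        bids <- toy$ids[sel, seq_len(Tb), drop = FALSE]
        for (rep in 1:2) {
          fwd <- soluq:::nn_forward(member$params, cfg, bids,
                                    toy$lengths[sel], training = TRUE)
          gr <- soluq:::nll_grad(fwd$mu, fwd$sigma2, toy$y[sel])
          grads <- soluq:::nn_backward(member$params, cfg, fwd, gr$dmu,
                                       gr$dsigma2)
          up <- soluq:::adam_step(member$params, grads, member$opt, 1e-2)
          member$params <- up$params
          member$opt <- up$state
        }
      }
    }
  })
  expect_identical(soluq:::param_flatten(fit_adv$params),
                   soluq:::param_flatten(member$params))
})

test_that("with adversarial off the trajectory is plain NLL training", {
  toy <- fx_toy_tokens()
  cfg <- member_config(vocab_size = toy$vocab_size, embed_dim = 4,
                       rnn_kind = "gru", rnn_units = 4, dense_units = c(5, 3),
                       dropout = 0, max_len = ncol(toy$ids))
  tc <- train_config(learning_rate = 1e-2, epsilon_adv = 0.5,
                     adversarial = FALSE, epochs = 2, batch_size = 10,
                     ensemble_size = 1)
  a <- train_member(toy$ids, toy$lengths, toy$y, cfg, tc, seed = 3)
  tc$epsilon_adv <- 0  # epsilon must be irrelevant when the flag is off
  b <- train_member(toy$ids, toy$lengths, toy$y, cfg, tc, seed = 3)
  expect_identical(soluq:::param_flatten(a$params),
                   soluq:::param_flatten(b$params))
  expect_true(all(is.na(a$trace$train_nll_adv)))
})

test_that("training is reproducible and reduces the loss", {
  toy <- fx_toy_tokens()
  cfg <- member_config(vocab_size = toy$vocab_size, embed_dim = 8,
                       rnn_kind = "lstm", rnn_units = 8, dense_units = c(8, 4),
                       dropout = 0.2, max_len = ncol(toy$ids))
  tc <- train_config(learning_rate = 5e-3, adversarial = TRUE,
                     epsilon_adv = 0.01, epochs = 10, batch_size = 16,
                     ensemble_size = 1)
  a <- train_member(toy$ids, toy$lengths, toy$y, cfg, tc, seed = 12)
  b <- train_member(toy$ids, toy$lengths, toy$y, cfg, tc, seed = 12)
  expect_identical(soluq:::param_flatten(a$params),
                   soluq:::param_flatten(b$params))
  expect_lt(tail(a$trace$train_nll, 1), a$trace$train_nll[1])
})

test_that("a tiny model can overfit one sample", {
  cfg <- member_config(vocab_size = 6, embed_dim = 4, rnn_kind = "gru",
                       rnn_units = 4, dense_units = c(4, 3), dropout = 0,
                       max_len = 4)
  ids <- matrix(c(2L, 3L, 4L, 5L), 1, 4)
  tc <- train_config(learning_rate = 1e-2, adversarial = FALSE, epochs = 300,
                     batch_size = 1, ensemble_size = 1)
  fit <- train_member(ids, 4L, -1.7, cfg, tc, seed = 4)
  expect_lt(tail(fit$trace$train_nll, 1), fit$trace$train_nll[1])
  fwd <- soluq:::nn_forward(fit$params, cfg, ids, 4L, training = FALSE)
  expect_lt(abs(fwd$mu - (-1.7)), 0.5)
})

test_that("shuffled labels give no generalization beyond a constant model", {
  toy <- fx_toy_tokens(n = 80)
  y_shuffled <- soluq:::with_seed(99, sample(toy$y))
  cfg <- member_config(vocab_size = toy$vocab_size, embed_dim = 8,
                       rnn_kind = "gru", rnn_units = 8, dense_units = c(8, 4),
                       dropout = 0, max_len = ncol(toy$ids))
  tc <- train_config(learning_rate = 5e-3, adversarial = FALSE, epochs = 15,
                     batch_size = 16, ensemble_size = 1)
  tr <- 1:60; te <- 61:80
  fit <- train_member(toy$ids[tr, ], toy$lengths[tr], y_shuffled[tr], cfg, tc,
                      seed = 2)
  held <- soluq:::eval_nll(list(params = fit$params, config = cfg),
                           toy$ids[te, ], toy$lengths[te], y_shuffled[te])
  # best constant Gaussian predictor of the held-out labels
  const_nll <- nll_loss(mean(y_shuffled[te]),
                        mean((y_shuffled[te] - mean(y_shuffled[te]))^2),
                        y_shuffled[te])
  expect_gt(held, const_nll - 0.2)
})
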