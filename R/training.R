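# Training: heteroscedastic Gaussian negative log-likelihood, adversarial
# perturbation of the embedded input, and the per-member loop.

#' Gaussian negative log-likelihood
#'
#' The training loss of each ensemble member: the negative log density of
#' the observed label under the member's predicted Gaussian,
#' \deqn{l = 1/2 log(2 pi sigma^2) + (y - mu)^2 / (2 sigma^2),}
#' including the constant term, so the reported loss is the exact negative
#' log density. Vectorized; the batch loss is the mean.
#'
#' @param mu Predicted mean(s), log S.
#' @param sigma2 Predicted variance(s), log S^2; must be positive.
#' @param y Observed label(s), log S.
#' @param reduce If \code{TRUE} (default) return the mean over samples.
#' @return The mean loss, or the per-sample vector when \code{reduce = FALSE}.
#' @export
#' @examples
#' nll_loss(0, 1, 0)          # 0.5 * log(2 * pi)
#' nll_loss(2, 1 / (2 * pi), 2)  # exactly 0
nll_loss <- function(mu, sigma2, y, reduce = TRUE) {
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("`sigma2` must be strictly positive and finite", call. = FALSE)
  }
  l <- 0.5 * log(2 * pi * sigma2) + (y - mu)^2 / (2 * sigma2)
  if (reduce) mean(l) else l
}

# Gradients of the mean NLL with respect to mu and sigma2.
nll_grad <- function(mu, sigma2, y) {
  n <- length(mu)
  list(dmu = (mu - y) / sigma2 / n,
       dsigma2 = (1 / (2 * sigma2) - (y - mu)^2 / (2 * sigma2^2)) / n)
}

#' Fast-gradient-sign perturbation of an embedded input
#'
#' Because token ids are discrete, adversarial examples are generated in
#' embedding space: \code{x + epsilon * sign(grad)}, where \code{grad} is
#' the gradient of the loss with respect to the embedded input. Every
#' perturbed coordinate moves by exactly \code{epsilon} (0 where the
#' gradient is 0), the direction that locally increases the loss most under
#' an L-infinity budget.
#'
#' @param embedded Numeric matrix/array: the embedded input.
#' @param grad Loss gradient with respect to \code{embedded}; same shape.
#' @param epsilon Perturbation strength (embedding units, >= 0).
#' @return The perturbed embedding, same shape as \code{embedded}.
#' @export
adversarial_embed <- function(embedded, grad, epsilon) {
  if (!identical(dim(embedded), dim(grad)) ||
      length(embedded) != length(grad)) {
    stop("`embedded` and `grad` must have identical shapes", call. = FALSE)
  }
  if (epsilon < 0) stop("`epsilon` must be non-negative", call. = FALSE)
  if (epsilon == 0) return(embedded)
  embedded + epsilon * sign(grad)
}

#' Training configuration
#'
#' Optimization hyperparameters. Reference values: Adam with fixed learning
#' rate 1e-4, beta1 = 0.9, beta2 = 0.999, dropout handled by the member
#' config; the adversarial strength epsilon is not pinned by the reference
#' workflow and defaults to 0.01 embedding units.
#'
#' @param learning_rate Adam step size (> 0).
#' @param beta1,beta2 Adam moment decay rates in [0, 1).
#' @param epsilon_adv Adversarial perturbation strength (>= 0).
#' @param adversarial Whether each iteration adds a second update on the
#'   perturbed batch.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param ensemble_size Number of members N.
#' @param member_seeds Integer vector of length \code{ensemble_size}; the
#'   per-member initialization/shuffling seeds (the ensemble's diversity
#'   source). Defaults to \code{seed + 0:(N-1) * 101}.
#' @param seed Base seed used when \code{member_seeds} is absent.
#' @return A list of class \code{soluq_train_config}.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon_adv = 0.01, adversarial = TRUE,
                         epochs = 50L, batch_size = 32L, ensemble_size = 4L,
                         member_seeds = NULL, seed = 1L) {
  stopifnot(learning_rate > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            epsilon_adv >= 0, epochs >= 1L, batch_size >= 1L,
            ensemble_size >= 1L)
  if (is.null(member_seeds)) {
    member_seeds <- derive_seed(seed, seq_len(ensemble_size) * 101L)
  }
  if (length(member_seeds) != ensemble_size) {
    stop("`member_seeds` must have length `ensemble_size`", call. = FALSE)
  }
  if (anyDuplicated(member_seeds)) {
    warning("duplicate member seeds: ensemble diversity will degrade",
            call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon_adv = epsilon_adv, adversarial = isTRUE(adversarial),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 ensemble_size = as.integer(ensemble_size),
                 member_seeds = as.integer(member_seeds)),
            class = "soluq_train_config")
}

# One training iteration on one batch: an Adam update on the clean-batch
# NLL and, when adversarial training is on, a second Adam update (same
# optimizer state) on the batch perturbed in embedding space using the
# clean pass's input gradient. Dropout is active and re-sampled for the
# perturbed pass. Returns the updated member and the scalar losses.
train_step <- function(member, ids, lengths, y, tconf) {
  fwd <- nn_forward(member$params, member$config, ids, lengths, training = TRUE)
  loss_clean <- nll_loss(fwd$mu, fwd$sigma2, y)
  if (!is.finite(loss_clean)) {
    stop("non-finite training loss (clean pass); mu range [",
         paste(range(fwd$mu), collapse = ", "), "]", call. = FALSE)
  }
  gr <- nll_grad(fwd$mu, fwd$sigma2, y)
  grads <- nn_backward(member$params, member$config, fwd, gr$dmu, gr$dsigma2)
  dX <- grads$dX
  up <- adam_step(member$params, grads, member$opt, tconf$learning_rate,
                  tconf$beta1, tconf$beta2)
  member$params <- up$params
  member$opt <- up$state
  loss_adv <- NA_real_
  if (tconf$adversarial) {
    # the perturbation direction comes from the clean pass's input gradient;
    # it is applied as an offset on the (freshly updated) embedding so that
    # epsilon = 0 reproduces a plain clean update exactly
    offset <- adversarial_embed(dX * 0, dX, tconf$epsilon_adv)
    fwd2 <- nn_forward(member$params, member$config, ids, lengths,
                       training = TRUE, X_offset = offset)
    loss_adv <- nll_loss(fwd2$mu, fwd2$sigma2, y)
    if (!is.finite(loss_adv)) {
      stop("non-finite training loss (adversarial pass)", call. = FALSE)
    }
    gr2 <- nll_grad(fwd2$mu, fwd2$sigma2, y)
    grads2 <- nn_backward(member$params, member$config, fwd2, gr2$dmu,
                          gr2$dsigma2)
    up2 <- adam_step(member$params, grads2, member$opt, tconf$learning_rate,
                     tconf$beta1, tconf$beta2)
    member$params <- up2$params
    member$opt <- up2$state
  }
  list(member = member, loss_clean = loss_clean, loss_adv = loss_adv)
}

# Evaluate mean NLL on a dataset without dropout, in chunks.
eval_nll <- function(member, ids, lengths, y, chunk = 256L) {
  n <- nrow(ids)
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    Tb <- max(lengths[s:e])
    fwd <- nn_forward(member$params, member$config,
                      ids[s:e, seq_len(Tb), drop = FALSE], lengths[s:e],
                      training = FALSE)
    tot <- tot + sum(nll_loss(fwd$mu, fwd$sigma2, y[s:e], reduce = FALSE))
  }
  tot / n
}

#' Train a single ensemble member
#'
#' Runs minibatch Adam on the Gaussian NLL, with the optional adversarial
#' second update per iteration. Deterministic given \code{seed}: the seed
#' drives initialization, epoch shuffling and dropout.
#'
#' @param ids,lengths,y Tokenized training data: id matrix (rows =
#'   molecules), true token lengths, labels.
#' @param mconf A \code{\link{member_config}}.
#' @param tconf A \code{\link{train_config}}.
#' @param seed Member seed.
#' @param val Optional list(ids, lengths, y) evaluated after each epoch.
#' @return A list: \code{params}, \code{config}, \code{trace} (data frame
#'   with per-epoch mean train loss, adversarial loss, validation loss and
#'   wall time), \code{seed}.
#' @export
train_member <- function(ids, lengths, y, mconf, tconf, seed, val = NULL) {
  stopifnot(nrow(ids) >= 1L)
  member <- list(params = nn_init(mconf, seed), config = mconf)
  member$opt <- adam_init(member$params)
  n <- nrow(ids)
  trace <- data.frame(epoch = integer(0), train_nll = numeric(0),
                      train_nll_adv = numeric(0), val_nll = numeric(0),
                      seconds = numeric(0))
  with_seed(derive_seed(seed, 7L), {
    for (epoch in seq_len(tconf$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample.int(n)
      losses <- c()
      losses_adv <- c()
      for (s in seq(1L, n, by = tconf$batch_size)) {
        e <- min(n, s + tconf$batch_size - 1L)
        sel <- ord[s:e]
        Tb <- max(lengths[sel])  # trim the batch to its own longest sequence
        st <- train_step(member, ids[sel, seq_len(Tb), drop = FALSE],
                         lengths[sel], y[sel], tconf)
        member <- st$member
        losses <- c(losses, st$loss_clean)
        losses_adv <- c(losses_adv, st$loss_adv)
      }
      vl <- if (is.null(val)) NA_real_ else
        eval_nll(member, val$ids, val$lengths, val$y)
      trace <- rbind(trace, data.frame(
        epoch = epoch, train_nll = mean(losses),
        train_nll_adv = mean(losses_adv), val_nll = vl,
        seconds = proc.time()[["elapsed"]] - t0))
    }
  })
  list(params = member$params, config = mconf, trace = trace,
       seed = as.integer(seed))
}
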