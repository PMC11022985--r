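# The deep ensemble: fitting interface, aggregation of member Gaussians,
# prediction, S3 methods and the on-disk model bundle.

#' Aggregate member Gaussians into an ensemble prediction
#'
#' Each member m predicts a Gaussian (mu_m, sigma_m^2). The ensemble is
#' their uniform mixture, summarized by its first two moments:
#' \deqn{mu* = (1/N) sum_m mu_m}
#' \deqn{sigma_ale^2 = (1/N) sum_m sigma_m^2}
#' \deqn{sigma_epi^2 = (1/N) sum_m (mu_m - mu*)^2}
#' The aleatoric term is the data noise the members agree on; the epistemic
#' term is their disagreement. Their sum is exactly the mixture variance.
#'
#' @param mu Numeric matrix (rows = samples, columns = members) or vector
#'   (one sample) of member means.
#' @param sigma2 Member variances, same shape as \code{mu}; all positive.
#' @return A data frame with one row per sample: \code{mu}, \code{sigma2_ale},
#'   \code{sigma2_epi}, \code{sigma2_total}, \code{n_members}.
#' @export
#' @examples
#' ensemble_aggregate(c(0, 2), c(1, 1))  # mu* = 1, ale = 1, epi = 1
ensemble_aggregate <- function(mu, sigma2) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
  if (is.null(dim(sigma2))) sigma2 <- matrix(sigma2, nrow = 1L)
  if (!identical(dim(mu), dim(sigma2))) {
    stop("`mu` and `sigma2` must have identical shapes", call. = FALSE)
  }
  if (ncol(mu) < 1L) stop("need at least one ensemble member", call. = FALSE)
  if (any(sigma2 <= 0)) stop("member variances must be positive", call. = FALSE)
  mu_star <- rowMeans(mu)
  sigma2_ale <- rowMeans(sigma2)
  sigma2_epi <- rowMeans((mu - mu_star)^2)
  data.frame(mu = mu_star, sigma2_ale = sigma2_ale, sigma2_epi = sigma2_epi,
             sigma2_total = sigma2_ale + sigma2_epi, n_members = ncol(mu))
}

smiles_to_selfies_corpus <- function(smiles) {
  vapply(smiles, to_selfies, character(1), USE.NAMES = FALSE)
}

#' Fit a deep-ensemble solubility model
#'
#' Trains N independently initialized recurrent networks on SELFIES token
#' sequences; each member predicts a Gaussian (mean and variance) for the
#' label, trained by exact Gaussian negative log-likelihood with optional
#' adversarial perturbation in embedding space. Predictions aggregate the
#' members into an ensemble mean with aleatoric and epistemic variances
#' (see \code{\link{ensemble_aggregate}}).
#'
#' @param formula A two-sided formula naming the label and the SMILES
#'   column, e.g. \code{log_s ~ smiles}.
#' @param data A data frame containing those columns (for example the
#'   records from \code{\link{read_solubility_csv}},
#'   \code{\link{augment_records}} or \code{\link{synth_corpus}}).
#' @param vocab Optional \code{soluq_vocab}; built from the training corpus
#'   when absent.
#' @param max_len Padded token length; longer training sequences are
#'   dropped with a log message.
#' @param embed_dim,rnn_kind,rnn_units,dense_units,dropout,sigma_floor
#'   Member architecture, see \code{\link{member_config}}.
#' @param ensemble_size,epochs,batch_size,learning_rate,adversarial,
#'   epsilon_adv,member_seeds,seed Optimization settings, see
#'   \code{\link{train_config}}.
#' @param val_data Optional data frame like \code{data}; per-epoch held-out
#'   NLL is traced on it.
#' @param verbose Print per-member progress.
#' @return An object of class \code{soluq}; see
#'   \code{\link{predict.soluq}}, \code{summary}, \code{plot},
#'   \code{residuals}, \code{simulate}.
#' @export
soluq <- function(formula, data, vocab = NULL, max_len = 128L,
                  embed_dim = 64L, rnn_kind = c("lstm", "gru"),
                  rnn_units = 64L, dense_units = c(32L, 16L), dropout = 0.35,
                  sigma_floor = 1e-3, ensemble_size = 4L, epochs = 50L,
                  batch_size = 32L, learning_rate = 1e-4, adversarial = TRUE,
                  epsilon_adv = 0.01, member_seeds = NULL, seed = 1L,
                  val_data = NULL, verbose = TRUE) {
  rnn_kind <- match.arg(rnn_kind)
  cl <- match.call()
  vars <- all.vars(formula)
  if (length(vars) != 2L) {
    stop("`formula` must name exactly the label and the SMILES column, ",
         "e.g. log_s ~ smiles", call. = FALSE)
  }
  label_col <- vars[1]; smiles_col <- vars[2]
  if (!all(c(label_col, smiles_col) %in% names(data))) {
    stop("`data` lacks column(s): ",
         paste(setdiff(c(label_col, smiles_col), names(data)), collapse = ", "),
         call. = FALSE)
  }
  smiles <- as.character(data[[smiles_col]])
  y <- as.numeric(data[[label_col]])
  if (any(!is.finite(y))) stop("labels must be finite", call. = FALSE)
  selfies <- smiles_to_selfies_corpus(smiles)
  if (is.null(vocab)) vocab <- build_vocab(selfies)
  enc <- encode_corpus(selfies, vocab, max_len = max_len, on_too_long = "drop")
  y_kept <- y[enc$keep]
  if (nrow(enc$ids) == 0L) stop("no training sequences left after encoding",
                                call. = FALSE)
  mconf <- member_config(vocab_size = vocab_size(vocab), embed_dim = embed_dim,
                         rnn_kind = rnn_kind, rnn_units = rnn_units,
                         dense_units = dense_units, dropout = dropout,
                         sigma_floor = sigma_floor, max_len = max_len)
  tconf <- train_config(learning_rate = learning_rate, epsilon_adv = epsilon_adv,
                        adversarial = adversarial, epochs = epochs,
                        batch_size = batch_size, ensemble_size = ensemble_size,
                        member_seeds = member_seeds, seed = seed)
  val <- NULL
  if (!is.null(val_data)) {
    vs <- smiles_to_selfies_corpus(as.character(val_data[[smiles_col]]))
    ve <- encode_corpus(vs, vocab, max_len = max_len, on_too_long = "drop")
    val <- list(ids = ve$ids, lengths = ve$lengths,
                y = as.numeric(val_data[[label_col]])[ve$keep])
  }
  members <- vector("list", tconf$ensemble_size)
  for (m in seq_len(tconf$ensemble_size)) {
    t0 <- proc.time()[["elapsed"]]
    members[[m]] <- train_member(enc$ids, enc$lengths, y_kept, mconf, tconf,
                                 seed = tconf$member_seeds[m], val = val)
    if (verbose) {
      soluq_log(sprintf("member %d/%d trained in %.1fs (final train NLL %.4f)",
                        m, tconf$ensemble_size,
                        proc.time()[["elapsed"]] - t0,
                        utils::tail(members[[m]]$trace$train_nll, 1)))
    }
  }
  object <- structure(list(members = members, vocab = vocab, mconf = mconf,
                           tconf = tconf, call = cl, label_col = label_col,
                           smiles_col = smiles_col,
                           train_smiles = smiles[enc$keep], y = y_kept),
                      class = "soluq")
  fit <- predict_encoded(object, enc$ids, enc$lengths)
  object$fitted <- fit$mu
  object$fitted_frame <- fit
  object
}

# Forward every member over an encoded id matrix (no dropout) and aggregate.
predict_encoded <- function(object, ids, lengths, chunk = 512L) {
  n <- nrow(ids)
  N <- length(object$members)
  mu <- matrix(0, n, N)
  s2 <- matrix(0, n, N)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    Tb <- max(lengths[s:e])
    sub_ids <- ids[s:e, seq_len(Tb), drop = FALSE]
    for (m in seq_len(N)) {
      fwd <- nn_forward(object$members[[m]]$params, object$mconf, sub_ids,
                        lengths[s:e], training = FALSE)
      mu[s:e, m] <- fwd$mu
      s2[s:e, m] <- fwd$sigma2
    }
  }
  agg <- ensemble_aggregate(mu, s2)
  agg$member_mu <- I(mu)
  agg$member_sigma2 <- I(s2)
  agg
}

#' Predict solubility with uncertainty
#'
#' Encodes the inputs, runs every ensemble member with dropout off and
#' aggregates the member Gaussians. Out-of-vocabulary tokens map to the
#' unknown id (with a warning) and are counted per input; sequences longer
#' than the model's \code{max_len} are truncated with a warning.
#'
#' @param object A fitted \code{soluq} model.
#' @param newdata Character vector of SMILES (or SELFIES, see \code{form}),
#'   or a data frame containing the SMILES column used at fit time.
#' @param form \code{"smiles"} (default) or \code{"selfies"}.
#' @param ... Unused.
#' @return A data frame with one row per input: \code{input}, \code{mu}
#'   (predicted log S), \code{sigma2_ale}, \code{sigma2_epi},
#'   \code{sigma2_total}, \code{sigma_ale}, \code{sigma_epi},
#'   \code{n_members}, \code{n_unknown_tokens}.
#' @export
predict.soluq <- function(object, newdata, form = c("smiles", "selfies"), ...) {
  form <- match.arg(form)
  if (is.data.frame(newdata)) {
    newdata <- as.character(newdata[[object$smiles_col]])
  }
  if (!is.character(newdata) || length(newdata) == 0L) {
    stop("`newdata` must be a non-empty character vector or a data frame ",
         "with column '", object$smiles_col, "'", call. = FALSE)
  }
  selfies <- if (form == "smiles") smiles_to_selfies_corpus(newdata) else newdata
  enc <- encode_corpus(selfies, object$vocab, max_len = object$mconf$max_len,
                       on_too_long = "truncate")
  agg <- predict_encoded(object, enc$ids, enc$lengths)
  if (any(enc$n_unknown > 0L)) {
    warning(sum(enc$n_unknown > 0L),
            " input(s) contained out-of-vocabulary tokens (mapped to <unk>)",
            call. = FALSE)
  }
  data.frame(input = newdata, mu = agg$mu, sigma2_ale = agg$sigma2_ale,
             sigma2_epi = agg$sigma2_epi, sigma2_total = agg$sigma2_total,
             sigma_ale = sqrt(agg$sigma2_ale), sigma_epi = sqrt(agg$sigma2_epi),
             n_members = agg$n_members, n_unknown_tokens = enc$n_unknown,
             stringsAsFactors = FALSE)
}

#' @export
print.soluq <- function(x, ...) {
  cat("Deep-ensemble solubility model (soluq)\n")
  cat(sprintf("  %d members: bi-%s x2 (%d units), embed %d, dense %s, dropout %.2f\n",
              length(x$members), toupper(x$mconf$rnn_kind), x$mconf$rnn_units,
              x$mconf$embed_dim, paste(x$mconf$dense_units, collapse = "/"),
              x$mconf$dropout))
  cat(sprintf("  vocabulary: %d tokens (%d chemical); max_len %d\n",
              vocab_size(x$vocab), attr(x$vocab, "n_chemical"), x$mconf$max_len))
  cat(sprintf("  trained on %d sequences, %d epochs, adversarial %s (eps %.3g)\n",
              length(x$y), x$tconf$epochs,
              if (x$tconf$adversarial) "on" else "off", x$tconf$epsilon_adv))
  invisible(x)
}

#' @export
summary.soluq <- function(object, ...) {
  res <- object$y - object$fitted
  met <- solubility_metrics(object$fitted, object$y)
  out <- list(model = object, train_metrics = met,
              sigma2_ale = stats::quantile(object$fitted_frame$sigma2_ale,
                                           c(0.5, 0.95)),
              sigma2_epi = stats::quantile(object$fitted_frame$sigma2_epi,
                                           c(0.5, 0.95)),
              final_train_nll = vapply(object$members, function(m)
                utils::tail(m$trace$train_nll, 1), numeric(1)),
              residual_sd = stats::sd(res))
  class(out) <- "summary.soluq"
  out
}

#' @export
print.summary.soluq <- function(x, ...) {
  print(x$model)
  cat("\nTraining-set fit (in-sample, optimistic):\n")
  print(x$train_metrics)
  cat(sprintf("\nsigma2_ale median %.4f, 95%% %.4f; sigma2_epi median %.4f, 95%% %.4f\n",
              x$sigma2_ale[1], x$sigma2_ale[2], x$sigma2_epi[1], x$sigma2_epi[2]))
  cat("final member train NLL:",
      paste(sprintf("%.3f", x$final_train_nll), collapse = ", "), "\n")
  invisible(x)
}

#' @export
fitted.soluq <- function(object, ...) object$fitted

#' @export
residuals.soluq <- function(object, ...) object$y - object$fitted

#' Parity plot of a fitted model
#'
#' Observed versus predicted log S on the training data (or on supplied
#' data), with the identity line and the +-0.5 log S band that defines a
#' correct prediction in the solubility-challenge metric.
#'
#' @param x A \code{soluq} model.
#' @param newdata,observed Optional SMILES vector/data frame and labels;
#'   training data are used when absent.
#' @param ... Passed to \code{plot}.
#' @export
plot.soluq <- function(x, newdata = NULL, observed = NULL, ...) {
  if (is.null(newdata)) {
    pred <- x$fitted
    obs <- x$y
  } else {
    pred <- predict(x, newdata)$mu
    obs <- as.numeric(observed)
  }
  rng <- range(c(pred, obs))
  graphics::plot(obs, pred, xlab = "observed log S", ylab = "predicted log S",
                 xlim = rng, ylim = rng, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(0, 1)
  graphics::abline(0.5, 1, lty = 2, col = "red")
  graphics::abline(-0.5, 1, lty = 2, col = "red")
  invisible(x)
}

#' Simulate labels from the predictive mixture
#'
#' Draws from the ensemble's uniform Gaussian mixture: a member is chosen
#' uniformly per draw, then a normal deviate from its (mu_m, sigma_m^2).
#'
#' @param object A fitted \code{soluq} model.
#' @param nsim Number of simulated label sets.
#' @param seed Integer seed.
#' @param newdata Optional inputs (defaults to the training SMILES).
#' @param ... Unused.
#' @return A data frame of \code{nsim} columns of simulated log S values.
#' @export
simulate.soluq <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  smiles <- if (is.null(newdata)) object$train_smiles else newdata
  selfies <- smiles_to_selfies_corpus(if (is.data.frame(smiles))
    as.character(smiles[[object$smiles_col]]) else smiles)
  enc <- encode_corpus(selfies, object$vocab, max_len = object$mconf$max_len,
                       on_too_long = "truncate")
  agg <- predict_encoded(object, enc$ids, enc$lengths)
  mu <- agg$member_mu
  s2 <- agg$member_sigma2
  n <- nrow(mu); N <- ncol(mu)
  draw <- function() {
    pick <- sample.int(N, n, replace = TRUE)
    idx <- cbind(seq_len(n), pick)
    stats::rnorm(n, mu[idx], sqrt(s2[idx]))
  }
  sims <- if (is.null(seed)) replicate(nsim, draw()) else
    with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# ---------------------------------------------------------------------------
# Model bundle: vocabulary manifest + JSON config + one plain-text weights
# file per member (member_000.txt, ...). Loading validates consistency.

write_params_text <- function(params, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  wr <- function(name, x) {
    if (is.list(x)) {
      for (nm in names(x)) wr(paste(name, nm, sep = "."), x[[nm]])
      return(invisible())
    }
    d <- if (is.matrix(x)) dim(x) else c(length(x), 1L)
    writeLines(paste("##", name, d[1], d[2]), con)
    writeLines(sprintf("%.17g", as.vector(x)), con)
  }
  for (nm in names(params)) wr(nm, params[[nm]])
  invisible(path)
}

read_params_text <- function(path, template) {
  lines <- readLines(path)
  heads <- grep("^## ", lines)
  stash <- new.env(parent = emptyenv())
  for (k in seq_along(heads)) {
    h <- strsplit(lines[heads[k]], " ", fixed = TRUE)[[1]]
    n <- as.integer(h[3]) * as.integer(h[4])
    vals <- as.numeric(lines[(heads[k] + 1L):(heads[k] + n)])
    x <- if (h[4] == "1") vals else matrix(vals, as.integer(h[3]), as.integer(h[4]))
    assign(h[2], x, envir = stash)
  }
  build <- function(tmpl, prefix) {
    out <- tmpl
    for (nm in names(tmpl)) {
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.list(tmpl[[nm]])) {
        out[[nm]] <- build(tmpl[[nm]], key)
      } else {
        if (!exists(key, envir = stash)) {
          stop("weights file ", path, " lacks parameter ", key, call. = FALSE)
        }
        v <- get(key, envir = stash)
        if (length(v) != length(tmpl[[nm]])) {
          stop("parameter ", key, " has wrong size in ", path, call. = FALSE)
        }
        if (is.matrix(tmpl[[nm]])) {
          dim(v) <- dim(tmpl[[nm]])
        } else {
          v <- as.vector(v)
        }
        out[[nm]] <- v
      }
    }
    out
  }
  build(template, "")
}

# Order-independent FNV-1a style fingerprint of training data, recorded in
# the bundle manifest for provenance.
data_fingerprint <- function(smiles, y) {
  s <- paste(smiles, sprintf("%.10g", y), sep = "|", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Save a fitted model bundle
#'
#' Writes a directory containing the vocabulary manifest
#' (\code{vocab.tsv}), a JSON manifest of every architecture and training
#' setting plus seeds and a training-data fingerprint (\code{config.json}),
#' and one plain-text weights file per member
#' (\code{member_000.txt}, ...).
#'
#' @param object A fitted \code{soluq} model.
#' @param dir Directory to create/overwrite.
#' @return \code{dir}, invisibly.
#' @export
save_soluq <- function(object, dir) {
  stopifnot(inherits(object, "soluq"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vocab(object$vocab, file.path(dir, "vocab.tsv"))
  manifest <- list(
    package = "soluq", version = as.character(utils::packageVersion("soluq")),
    member_config = unclass(object$mconf),
    train_config = unclass(object$tconf),
    n_members = length(object$members),
    member_seeds = object$tconf$member_seeds,
    label_col = object$label_col, smiles_col = object$smiles_col,
    data_fingerprint = data_fingerprint(object$train_smiles, object$y),
    n_train = length(object$y))
  jsonlite::write_json(manifest, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in seq_along(object$members)) {
    write_params_text(object$members[[m]]$params,
                      file.path(dir, sprintf("member_%03d.txt", m - 1L)))
  }
  invisible(dir)
}

#' Load a model bundle
#'
#' Restores a model saved by \code{\link{save_soluq}}, validating that the
#' vocabulary manifest matches the declared vocabulary size and that every
#' member weights file is present and complete.
#'
#' @param dir Bundle directory.
#' @return A \code{soluq} object (without training traces or fitted values).
#' @export
load_soluq <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  vocab <- read_vocab(file.path(dir, "vocab.tsv"))
  mc <- manifest$member_config
  if (vocab_size(vocab) != mc$vocab_size) {
    stop("bundle mismatch: vocabulary manifest has ", vocab_size(vocab),
         " tokens but config declares ", mc$vocab_size, call. = FALSE)
  }
  mconf <- member_config(vocab_size = mc$vocab_size, embed_dim = mc$embed_dim,
                         rnn_kind = mc$rnn_kind, rnn_units = mc$rnn_units,
                         dense_units = mc$dense_units, dropout = mc$dropout,
                         sigma_floor = mc$sigma_floor, max_len = mc$max_len)
  tc <- manifest$train_config
  tconf <- train_config(learning_rate = tc$learning_rate, beta1 = tc$beta1,
                        beta2 = tc$beta2, epsilon_adv = tc$epsilon_adv,
                        adversarial = tc$adversarial, epochs = tc$epochs,
                        batch_size = tc$batch_size,
                        ensemble_size = tc$ensemble_size,
                        member_seeds = tc$member_seeds)
  template <- nn_init(mconf, 1L)
  members <- lapply(seq_len(manifest$n_members), function(m) {
    f <- file.path(dir, sprintf("member_%03d.txt", m - 1L))
    if (!file.exists(f)) stop("bundle lacks weights file ", f, call. = FALSE)
    list(params = read_params_text(f, template), config = mconf,
         seed = tconf$member_seeds[m])
  })
  structure(list(members = members, vocab = vocab, mconf = mconf,
                 tconf = tconf, call = NULL,
                 label_col = manifest$label_col %||% "log_s",
                 smiles_col = manifest$smiles_col %||% "smiles",
                 train_smiles = character(0), y = numeric(0)),
            class = "soluq")
}
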