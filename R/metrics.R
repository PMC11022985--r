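# Evaluation metrics and uncertainty summaries.

#' Regression metrics for solubility prediction
#'
#' RMSE, MAE, Pearson correlation and the percentage of predictions within
#' 0.5 log S of the label (the solubility challenges' headline metric; the
#' boundary is inclusive). Pearson r is reported as \code{NA} with a
#' warning when either vector is constant.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 2).
#' @return A list of class \code{soluq_metrics}: \code{rmse}, \code{mae},
#'   \code{pearson_r}, \code{acc_half_log} (percent, 0-100), \code{n}.
#' @export
#' @examples
#' solubility_metrics(c(0, 0, 0), c(1, -1, 0.3))
solubility_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  }
  if (length(predicted) < 2L) {
    stop("need at least 2 samples", call. = FALSE)
  }
  err <- predicted - observed
  r <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("constant vector: Pearson r undefined, reported as NA",
            call. = FALSE)
    NA_real_
  } else {
    stats::cor(predicted, observed)
  }
  structure(list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 pearson_r = r, acc_half_log = 100 * mean(abs(err) <= 0.5),
                 n = length(err)),
            class = "soluq_metrics")
}

#' @export
print.soluq_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4f | MAE %.4f | r %s | within +-0.5 log S: %.1f%% (n = %d)\n",
              x$rmse, x$mae,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r),
              x$acc_half_log, x$n))
  invisible(x)
}

#' @export
as.data.frame.soluq_metrics <- function(x, ...) {
  data.frame(rmse = x$rmse, mae = x$mae, pearson_r = x$pearson_r,
             acc_half_log = x$acc_half_log, n = x$n)
}

#' Summarize predictive uncertainty over a set of predictions
#'
#' Collects the per-sample aleatoric and epistemic variances and their
#' distribution summaries (mean, median, 95th percentile, maximum) — the
#' quantities whose densities shrink in the tail as the ensemble grows.
#'
#' @param predictions A data frame from \code{\link{predict.soluq}} (or any
#'   frame with \code{sigma2_ale} and \code{sigma2_epi} columns).
#' @return A list of class \code{soluq_uncertainty}: \code{sigma2_ale},
#'   \code{sigma2_epi} (vectors) and \code{summary} (data frame with one
#'   row per statistic).
#' @export
summarize_uncertainty <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("sigma2_ale", "sigma2_epi") %in% names(predictions)),
            nrow(predictions) >= 1L)
  a <- predictions$sigma2_ale
  e <- predictions$sigma2_epi
  stat <- function(v) c(mean = mean(v), median = stats::median(v),
                        p95 = unname(stats::quantile(v, 0.95)), max = max(v))
  s <- data.frame(statistic = c("mean", "median", "p95", "max"),
                  sigma2_ale = unname(stat(a)), sigma2_epi = unname(stat(e)))
  structure(list(sigma2_ale = a, sigma2_epi = e, summary = s),
            class = "soluq_uncertainty")
}

#' @export
print.soluq_uncertainty <- function(x, ...) {
  cat("Uncertainty over", length(x$sigma2_ale), "predictions (log S^2):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export parity-plot data
#'
#' Writes a two-column CSV (\code{observed}, \code{predicted}) preceded by
#' comment lines embedding the \code{\link{solubility_metrics}} of the
#' pair, ready for external plotting. Re-reading the file (comment char
#' \code{#}) reproduces the inputs exactly.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @param path Output CSV path.
#' @return The \code{soluq_metrics} of the pair, invisibly.
#' @export
parity_export <- function(predicted, observed, path) {
  met <- solubility_metrics(predicted, observed)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rmse=%.17g", met$rmse),
    sprintf("# mae=%.17g", met$mae),
    sprintf("# pearson_r=%.17g", met$pearson_r),
    sprintf("# acc_half_log=%.17g", met$acc_half_log),
    sprintf("# n=%d", met$n),
    "observed,predicted",
    sprintf("%.17g,%.17g", observed, predicted)), con)
  invisible(met)
}
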