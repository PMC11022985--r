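# Scaled-down ablation runner: one metrics row per grid cell per
# evaluation set, with shared splits and member seeds across cells so the
# comparisons isolate the ablated factor.

#' Run an ablation grid
#'
#' Trains one ensemble per cell of the grid \{recurrent cell kind\} x
#' \{augmented training set?\} x \{adversarial training?\} x \{ensemble
#' size\} and evaluates every cell on every evaluation set. All cells share
#' the same train/test split and the same member seed sequence (cell N uses
#' the first N seeds), so differences between rows reflect the ablated
#' factor rather than sampling. A failed cell is recorded with NA metrics
#' and the grid continues.
#'
#' @param data A record data frame (training pool; split internally).
#' @param eval_sets Named list of record data frames used as withheld
#'   evaluation sets; the internal test split is always evaluated as
#'   \code{"test"}.
#' @param rnn_kinds,augmented,adversarial,ensemble_sizes Vectors defining
#'   the grid.
#' @param train_fraction,seed Split settings (shared by all cells).
#' @param max_new Augmentation cap per molecule for augmented cells.
#' @param model_args Named list of extra arguments passed to
#'   \code{\link{soluq}} (architecture, epochs, ...).
#' @param verbose Log per-cell progress.
#' @return A data frame: one row per cell per evaluation set with the grid
#'   coordinates, the evaluation-set name and the metrics columns.
#' @export
run_ablation <- function(data, eval_sets = list(),
                         rnn_kinds = c("gru", "lstm"),
                         augmented = c(FALSE, TRUE),
                         adversarial = c(FALSE, TRUE),
                         ensemble_sizes = c(1L, 4L),
                         train_fraction = 0.8, seed = 1L, max_new = 10L,
                         model_args = list(), verbose = TRUE) {
  grid <- expand.grid(rnn_kind = rnn_kinds, augmented = augmented,
                      adversarial = adversarial, n_members = ensemble_sizes,
                      stringsAsFactors = FALSE)
  sp <- split_records(data, train_fraction = train_fraction, seed = seed)
  sets <- c(list(test = sp$test), eval_sets)
  all_seeds <- derive_seed(seed, seq_len(max(ensemble_sizes)) * 101L)
  aug_train <- NULL
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    if (cell$augmented && is.null(aug_train)) {
      aug_train <- augment_records(sp$train, max_new = max_new, seed = seed)
    }
    train <- if (cell$augmented) aug_train else sp$train
    if (verbose) {
      soluq_log(sprintf("ablation cell %d/%d: %s%s%s N=%d (%d records)",
                        i, nrow(grid), cell$rnn_kind,
                        if (cell$augmented) " +aug" else "",
                        if (cell$adversarial) " +adv" else " -adv",
                        cell$n_members, nrow(train)))
    }
    fit <- tryCatch({
      args <- c(list(formula = log_s ~ smiles, data = train,
                     rnn_kind = cell$rnn_kind,
                     adversarial = cell$adversarial,
                     ensemble_size = cell$n_members,
                     member_seeds = all_seeds[seq_len(cell$n_members)],
                     seed = seed, verbose = FALSE),
                model_args)
      do.call(soluq, args)
    }, error = function(e) {
      soluq_log("cell ", i, " failed: ", conditionMessage(e))
      NULL
    })
    for (set_name in names(sets)) {
      set <- sets[[set_name]]
      met <- if (is.null(fit)) {
        list(rmse = NA_real_, mae = NA_real_, pearson_r = NA_real_,
             acc_half_log = NA_real_, n = nrow(set))
      } else {
        pred <- predict(fit, set$smiles)
        unclass(solubility_metrics(pred$mu, set$log_s))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rnn_kind = cell$rnn_kind, augmented = cell$augmented,
        adversarial = cell$adversarial, n_members = cell$n_members,
        eval_set = set_name, rmse = met$rmse, mae = met$mae,
        pearson_r = met$pearson_r, acc_half_log = met$acc_half_log,
        n = met$n, failed = is.null(fit), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
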