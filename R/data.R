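# Dataset handling: CSV loading, randomized-SMILES augmentation and
# shuffled splitting. Records are plain data frames with columns
# smiles, log_s, source_id, parent_canonical.

record_frame <- function(smiles, log_s, source_id, parent_canonical) {
  data.frame(smiles = smiles, log_s = log_s, source_id = source_id,
             parent_canonical = parent_canonical, stringsAsFactors = FALSE)
}

#' Load a solubility CSV
#'
#' Reads a CSV with a SMILES column and a numeric log S (log10 mol/L)
#' label column, in the layout used by AqSolDB and the solubility-challenge
#' files (column names configurable). Rows whose SMILES cannot be parsed,
#' or whose label is missing or non-finite, are dropped with a logged count.
#'
#' @param path Path to the CSV file (header row required).
#' @param smiles_col,label_col Column names for the SMILES string and label.
#' @param id_col Optional column with a compound identifier; row numbers are
#'   used when absent.
#' @return A record data frame with columns \code{smiles}, \code{log_s},
#'   \code{source_id}, \code{parent_canonical}. The attribute
#'   \code{n_unique_molecules} carries the unique canonical-SMILES count.
#' @export
read_solubility_csv <- function(path, smiles_col = "smiles",
                                label_col = "log_s", id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  missing_cols <- setdiff(c(smiles_col, label_col, id_col), names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  smiles <- as.character(df[[smiles_col]])
  log_s <- suppressWarnings(as.numeric(df[[label_col]]))
  ids <- if (is.null(id_col)) paste0("row", seq_len(nrow(df))) else
    as.character(df[[id_col]])
  ok <- !is.na(smiles) & nzchar(smiles) & is.finite(log_s)
  ok[ok] <- is_valid_smiles(smiles[ok])
  if (any(!ok)) {
    soluq_log(sum(!ok), " row(s) dropped (unparsable SMILES or non-finite label)")
  }
  rec <- record_frame(smiles[ok], log_s[ok], ids[ok],
                      canonical_smiles(smiles[ok]))
  attr(rec, "n_unique_molecules") <- length(unique(rec$parent_canonical))
  rec
}

#' Augment records with randomized SMILES
#'
#' For each input record, generates at most \code{max_new} new unique
#' randomized SMILES strings carrying the parent's label and canonical
#' SMILES, then removes exact string duplicates globally (first occurrence
#' kept). With \code{dedup = "canonical"}, duplicates are instead removed at
#' the canonical-SMILES level across parents.
#'
#' @param records A record data frame (see \code{\link{read_solubility_csv}}).
#' @param max_new Cap on new strings per record (default 10).
#' @param seed Integer seed; augmentation is deterministic given it.
#' @param dedup \code{"string"} (default) or \code{"canonical"}.
#' @return An augmented record data frame containing the input records plus
#'   the new ones.
#' @export
augment_records <- function(records, max_new = 10L, seed = 1L,
                            dedup = c("string", "canonical")) {
  dedup <- match.arg(dedup)
  stopifnot(is.data.frame(records), max_new >= 0)
  if (max_new == 0L) return(records)
  new_list <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    alt <- randomize_smiles(records$smiles[[i]], max_new = max_new,
                            seed = derive_seed(seed, i))
    if (length(alt) > 0L) {
      new_list[[i]] <- record_frame(alt, records$log_s[[i]],
                                    paste0(records$source_id[[i]], "_aug"),
                                    records$parent_canonical[[i]])
    }
  }
  out <- rbind(records, do.call(rbind, new_list[!vapply(new_list, is.null, logical(1))]))
  key <- if (dedup == "string") out$smiles else canonical_smiles(out$smiles)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shuffle and split records into train and test sets
#'
#' Shuffles the records and partitions them by a train fraction. The default
#' splits at the record (string) level, which mirrors the reference
#' workflow of splitting *after* augmentation: different strings for one
#' molecule can then land on both sides. Because that leakage materially
#' flatters test metrics, a leakage report (parent molecules present in both
#' halves) is always attached, and \code{by_parent = TRUE} splits whole
#' molecules instead.
#'
#' @param records A record data frame with at least 2 rows.
#' @param train_fraction Fraction of records assigned to training (0.8 in
#'   the reference workflow).
#' @param seed Integer seed; the split is deterministic given it.
#' @param by_parent If \code{TRUE}, all records of one parent molecule go to
#'   the same side.
#' @return A list of class \code{soluq_split} with \code{train},
#'   \code{test}, \code{leakage} (character vector of parent canonical
#'   SMILES on both sides), \code{seed} and \code{train_fraction}.
#' @export
split_records <- function(records, train_fraction = 0.8, seed = 1L,
                          by_parent = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("`train_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  if (by_parent) {
    parents <- unique(records$parent_canonical)
    shuffled <- with_seed(seed, sample(parents))
    n_train <- round(train_fraction * length(shuffled))
    train_parents <- shuffled[seq_len(n_train)]
    take <- records$parent_canonical %in% train_parents
  } else {
    idx <- with_seed(seed, sample.int(nrow(records)))
    n_train <- round(train_fraction * nrow(records))
    take <- seq_len(nrow(records)) %in% idx[seq_len(n_train)]
  }
  train <- records[take, , drop = FALSE]
  test <- records[!take, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  leakage <- intersect(unique(train$parent_canonical),
                       unique(test$parent_canonical))
  structure(list(train = train, test = test, leakage = leakage,
                 seed = as.integer(seed), train_fraction = train_fraction),
            class = "soluq_split")
}

#' @export
print.soluq_split <- function(x, ...) {
  cat("soluq split:", nrow(x$train), "train /", nrow(x$test), "test records",
      sprintf("(fraction %.3f, seed %d)\n",
              nrow(x$train) / (nrow(x$train) + nrow(x$test)), x$seed))
  cat("parent molecules present on both sides:", length(x$leakage), "\n")
  invisible(x)
}
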