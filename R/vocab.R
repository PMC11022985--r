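# Token vocabulary: bijection between SELFIES tokens and integer ids.
# Ids are 0-based to match the embedding matrix convention (pad row first):
# pad = 0, unknown = 1, chemical tokens from 2 upward in lexicographic order
# so that vocabulary construction is reproducible across runs and platforms.

PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"

#' Build a token vocabulary from a SELFIES corpus
#'
#' Collects every distinct token occurring in the corpus and assigns integer
#' ids: \code{<pad>} = 0, \code{<unk>} = 1, then chemical tokens in
#' lexicographic (C-locale) order. The build is invariant to corpus order
#' and duplication.
#'
#' @param corpus Character vector of SELFIES strings (non-empty).
#' @return An object of class \code{soluq_vocab}: a named integer vector
#'   mapping token text to id, with attribute \code{n_chemical} (the count
#'   of distinct chemical tokens, excluding the two special tokens).
#' @export
#' @examples
#' build_vocab(c("[C][C][O]", "[C][O]"))
build_vocab <- function(corpus) {
  if (!is.character(corpus) || length(corpus) == 0L) {
    stop("`corpus` must be a non-empty character vector of SELFIES strings",
         call. = FALSE)
  }
  toks <- unique(unlist(lapply(corpus, selfies_tokens), use.names = FALSE))
  toks <- sort(toks[!(toks %in% c(PAD_TOKEN, UNK_TOKEN))], method = "radix")
  ids <- seq_along(toks) + 1L
  vocab <- c(stats::setNames(0L, PAD_TOKEN), stats::setNames(1L, UNK_TOKEN),
             stats::setNames(ids, toks))
  attr(vocab, "n_chemical") <- length(toks)
  class(vocab) <- "soluq_vocab"
  vocab
}

#' @export
print.soluq_vocab <- function(x, ...) {
  cat("SELFIES token vocabulary:", attr(x, "n_chemical"),
      "chemical tokens + 2 special tokens (<pad>=0, <unk>=1)\n")
  invisible(x)
}

vocab_size <- function(vocab) length(vocab)

#' Write a vocabulary manifest
#'
#' Plain-text manifest, one \code{token<TAB>id} line per entry, UTF-8, in id
#' order. \code{read_vocab} restores an identical mapping.
#'
#' @param vocab A \code{soluq_vocab} object.
#' @param path File path to write.
#' @return \code{path}, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "soluq_vocab"))
  ord <- order(unclass(vocab))
  lines <- paste(names(vocab)[ord], unclass(vocab)[ord], sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a vocabulary manifest
#'
#' @param path Path to a manifest written by \code{\link{write_vocab}}.
#' @return A \code{soluq_vocab} object identical to the one written.
#' @export
read_vocab <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed vocabulary manifest at line ", which(bad)[1], call. = FALSE)
  }
  tok <- vapply(parts, `[[`, character(1), 1L)
  id <- as.integer(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(id) || any(duplicated(tok)) || any(duplicated(id))) {
    stop("vocabulary manifest is not a bijection", call. = FALSE)
  }
  vocab <- stats::setNames(id, tok)
  vocab <- vocab[order(vocab)]
  if (!identical(unname(vocab[1:2]), 0:1) ||
      !identical(names(vocab)[1:2], c(PAD_TOKEN, UNK_TOKEN))) {
    stop("vocabulary manifest must assign <pad>=0 and <unk>=1", call. = FALSE)
  }
  attr(vocab, "n_chemical") <- length(vocab) - 2L
  class(vocab) <- "soluq_vocab"
  vocab
}

#' Encode a SELFIES string as padded integer ids
#'
#' Tokens are looked up in the vocabulary and the id sequence is padded with
#' the pad id (0) to \code{max_len}. Tokens absent from the vocabulary map
#' to the unknown id with a warning (or an error in strict mode), so novel
#' molecules remain predictable. Sequences longer than \code{max_len} are
#' truncated with a warning.
#'
#' @param selfies A single SELFIES string.
#' @param vocab A \code{soluq_vocab}.
#' @param max_len Padded sequence length (default 128 tokens).
#' @param strict If \code{TRUE}, out-of-vocabulary tokens raise an error.
#' @return A list with \code{ids} (integer vector of length \code{max_len}),
#'   \code{length} (token count before padding/truncation, capped at
#'   \code{max_len}) and \code{n_unknown}.
#' @export
#' @examples
#' v <- build_vocab("[C][C][O]")
#' encode_selfies_ids("[C][O]", v, max_len = 5)
encode_selfies_ids <- function(selfies, vocab, max_len = 128L, strict = FALSE) {
  stopifnot(inherits(vocab, "soluq_vocab"), max_len >= 1L)
  toks <- selfies_tokens(selfies)
  if (length(toks) > max_len) {
    warning("sequence of ", length(toks), " tokens truncated to max_len = ",
            max_len, call. = FALSE)
    toks <- toks[seq_len(max_len)]
  }
  ids <- unclass(vocab)[toks]
  unknown <- is.na(ids)
  if (any(unknown)) {
    if (strict) {
      stop("out-of-vocabulary tokens: ",
           paste(unique(toks[unknown]), collapse = " "), call. = FALSE)
    }
    warning(sum(unknown), " out-of-vocabulary token(s) mapped to <unk>: ",
            paste(unique(toks[unknown]), collapse = " "), call. = FALSE)
    ids[unknown] <- 1L
  }
  list(ids = as.integer(c(ids, rep(0L, max_len - length(ids)))),
       length = length(toks), n_unknown = sum(unknown))
}

#' Decode padded ids back to tokens
#'
#' Inverse of \code{\link{encode_selfies_ids}} over non-pad positions;
#' exact whenever every token was in the vocabulary.
#'
#' @param ids Integer id vector (padded or not).
#' @param vocab A \code{soluq_vocab}.
#' @return Character vector of tokens (pad entries dropped).
#' @export
decode_ids <- function(ids, vocab) {
  stopifnot(inherits(vocab, "soluq_vocab"))
  ids <- ids[ids != 0L]
  rev_map <- stats::setNames(names(vocab), unclass(vocab))
  out <- rev_map[as.character(ids)]
  if (anyNA(out)) stop("id outside vocabulary range", call. = FALSE)
  unname(out)
}

# Encode a character vector of SELFIES strings into an id matrix
# (n x max_len) plus lengths; used by the training and prediction paths.
encode_corpus <- function(selfies, vocab, max_len = 128L, strict = FALSE,
                          on_too_long = c("drop", "truncate")) {
  on_too_long <- match.arg(on_too_long)
  n <- length(selfies)
  ids <- matrix(0L, n, max_len)
  len <- integer(n)
  nunk <- integer(n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    toks <- selfies_tokens(selfies[[i]])
    if (length(toks) > max_len) {
      if (on_too_long == "drop") {
        keep[i] <- FALSE
        next
      }
      warning("sequence truncated to max_len = ", max_len, call. = FALSE)
      toks <- toks[seq_len(max_len)]
    }
    v <- unclass(vocab)[toks]
    unk <- is.na(v)
    if (any(unk) && strict) {
      stop("out-of-vocabulary tokens: ", paste(unique(toks[unk]), collapse = " "),
           call. = FALSE)
    }
    v[unk] <- 1L
    ids[i, seq_along(v)] <- as.integer(v)
    len[i] <- length(v)
    nunk[i] <- sum(unk)
  }
  dropped <- sum(!keep)
  if (dropped > 0L) {
    soluq_log(dropped, " sequence(s) longer than max_len = ", max_len, " dropped")
  }
  list(ids = ids[keep, , drop = FALSE], lengths = len[keep],
       n_unknown = nunk[keep], keep = keep)
}
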