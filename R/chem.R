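# SMILES handling: validation, canonicalization and randomized enumeration.
# Structure perception (parsing, kekulization, canonical ordering) is
# delegated to OpenBabel through ChemmineR/ChemmineOB; this file only
# orchestrates it.

ob_convert <- function(source, from = "SMI", to = "CAN") {
  out <- ChemmineOB::convertFormat(from, to, source)
  out <- strsplit(out, "\n", fixed = TRUE)[[1]]
  out <- sub("[ \t].*$", "", out)
  out[nzchar(out)]
}

#' Test whether strings are valid SMILES
#'
#' A string is considered valid when OpenBabel can parse it into a molecule.
#'
#' @param smiles Character vector of candidate SMILES strings.
#' @return Logical vector, one element per input.
#' @export
#' @examples
#' is_valid_smiles(c("CCO", "not-a-molecule"))
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (!is.character(s) || is.na(s) || !nzchar(s)) return(FALSE)
    length(suppressWarnings(ob_convert(s))) == 1L
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Maps every SMILES representation of a molecule to the unique canonical
#' SMILES chosen by OpenBabel. Canonical SMILES defines molecule identity
#' throughout the package (deduplication, augmentation parentage,
#' round-trip checks). The ensemble model itself is *not* invariant to the
#' representation; canonicalization is what lets us say two strings denote
#' the same molecule.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @export
#' @examples
#' canonical_smiles("OCC") == canonical_smiles("CCO")
canonical_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0L) {
    stop("`smiles` must be a non-empty character vector", call. = FALSE)
  }
  out <- character(length(smiles))
  # batch conversion first; fall back per element to identify offenders
  batch <- suppressWarnings(ob_convert(paste(smiles, collapse = "\n")))
  if (length(batch) == length(smiles)) return(batch)
  for (i in seq_along(smiles)) {
    s <- smiles[[i]]
    res <- if (is.na(s) || !nzchar(s)) character(0) else suppressWarnings(ob_convert(s))
    if (length(res) != 1L) {
      stop("invalid SMILES string: '", s, "'", call. = FALSE)
    }
    out[[i]] <- res
  }
  out
}

# Molecular graph of a SMILES string, kekulized: elements, formal charges and
# integer bond orders. Atom order follows the input string's atom order.
smiles_graph <- function(smiles) {
  if (!is_valid_smiles(smiles)) {
    stop("invalid SMILES string: '", smiles, "'", call. = FALSE)
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_[0-9]+$", "", rownames(ab))
  # V2000 charge codes: 1 -> +3, 2 -> +2, 3 -> +1, 4 -> radical, 5..7 -> -1..-3
  code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- integer(length(code))
  charge[code %in% 1:3] <- 4L - as.integer(code[code %in% 1:3])
  charge[code %in% 5:7] <- -(as.integer(code[code %in% 5:7]) - 4L)
  bonds <- if (nrow(bb) > 0L) {
    data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(a = integer(0), b = integer(0), order = integer(0))
  }
  if (any(bonds$order > 3L)) {
    stop("cannot kekulize '", smiles, "': aromatic bond order in structure table",
         call. = FALSE)
  }
  list(element = element, charge = charge, bonds = bonds)
}

# Write one SMILES string for a permuted atom order of an SDF structure.
permuted_smiles <- function(sdf, perm) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  inv <- order(perm)
  ab2 <- ab[perm, , drop = FALSE]
  el <- sub("_[0-9]+$", "", rownames(ab2))
  rownames(ab2) <- paste(el, seq_len(nrow(ab2)), sep = "_")
  bb2 <- bb
  if (nrow(bb2) > 0L) {
    bb2[, 1] <- inv[bb[, 1]]
    bb2[, 2] <- inv[bb[, 2]]
  }
  sdf2 <- methods::new("SDF", header = ChemmineR::header(sdf), atomblock = ab2,
                       bondblock = bb2, datablock = ChemmineR::datablock(sdf))
  out <- ChemmineR::sdf2smiles(methods::new("SDFset", SDF = list(sdf2), ID = "m"))
  unname(sub("[ \t].*$", "", as.character(out)))
}

#' Enumerate randomized SMILES for one molecule
#'
#' Generates alternative, non-canonical SMILES strings for a molecule by
#' renumbering its atoms at random and writing the SMILES in the permuted
#' order. This is the augmentation primitive: training on several strings
#' for the same molecule teaches the model that the property belongs to the
#' molecule, not to one particular string.
#'
#' At most \code{10 * max_new} random permutations are attempted, so small
#' molecules with few distinct strings terminate quickly (methane has none).
#'
#' @param smiles A single valid SMILES string.
#' @param max_new Maximum number of new unique strings to return (the
#'   augmentation cap; 10 in the reference workflow).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Character vector of at most \code{max_new} unique SMILES strings,
#'   none equal to the input, each denoting the same molecule as the input.
#' @export
#' @examples
#' randomize_smiles("CCO", max_new = 5, seed = 1)
randomize_smiles <- function(smiles, max_new = 10L, seed = 1L) {
  stopifnot(length(smiles) == 1L, is.numeric(max_new), max_new >= 0)
  if (!is_valid_smiles(smiles)) {
    stop("invalid SMILES string: '", smiles, "'", call. = FALSE)
  }
  max_new <- as.integer(max_new)
  if (max_new == 0L) return(character(0))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  n <- nrow(ChemmineR::atomblock(sdf))
  if (n < 2L) return(character(0))
  found <- character(0)
  with_seed(seed, {
    for (attempt in seq_len(10L * max_new)) {
      s <- permuted_smiles(sdf, sample.int(n))
      if (length(s) == 1L && nzchar(s) && !identical(s, smiles) && !(s %in% found)) {
        found <- c(found, s)
      }
      if (length(found) >= max_new) break
    }
  })
  found
}
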