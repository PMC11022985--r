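# SELFIES encoding and decoding.
#
# SELFIES (self-referencing embedded strings) is a molecular string grammar
# in which every symbol is a bracketed group, branches carry their own length
# and rings reference earlier atoms by count, so that token sequences are
# robust to local edits. The model consumes SELFIES tokens; SMILES inputs are
# encoded on the fly. The implementation here covers the core grammar used
# for organic molecules: bond-prefixed atom symbols (e.g. [C], [=O], [#N],
# [NH3+1]), [BranchN]/[RingN] symbols with base-16 index symbols, and the
# "." separator for disconnected components. Kekulization is performed by
# OpenBabel before encoding, so aromatic systems are expressed with
# alternating single/double bonds. Stereochemistry is not encoded: molecule
# identity for round-trips is constitutional.

# Index alphabet: the sixteen symbols that double as base-16 digits 0..15
# when a [BranchN]/[RingN] symbol needs a length or distance operand.
SELFIES_INDEX_ALPHABET <- c(
  "[C]", "[Ring1]", "[Ring2]",
  "[Branch1]", "[=Branch1]", "[#Branch1]",
  "[Branch2]", "[=Branch2]", "[#Branch2]",
  "[Branch3]", "[=Branch3]", "[#Branch3]",
  "[O]", "[N]", "[=N]", "[=C]")

BOND_PREFIX <- c("", "=", "#")  # bond order 1, 2, 3

# Default valence sets used to decide implicit hydrogen counts, following
# SMILES organic-subset semantics (smallest allowed valence >= bond sum).
VALENCE_SETS <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L)

default_valence <- function(element, bondsum) {
  vs <- VALENCE_SETS[[element]]
  if (is.null(vs)) return(NA_integer_)
  ok <- vs[vs >= bondsum]
  if (length(ok) == 0L) return(NA_integer_)
  min(ok)
}

# Implicit hydrogen count for an atom, with common charge adjustments
# (ammonium-like +1 raises the valence of N/O/P/S; anions lower it; charged
# carbon/boron lose a hydrogen for either sign).
implicit_hydrogens <- function(element, charge, bondsum) {
  if (charge == 0L) {
    v <- default_valence(element, bondsum)
    if (is.na(v)) return(NA_integer_)
    return(v - bondsum)
  }
  base <- default_valence(element, 0L)
  if (is.na(base)) return(NA_integer_)
  v <- if (element %in% c("B", "C")) base - abs(charge) else base + charge
  max(0L, as.integer(v) - bondsum)
}

encode_index_tokens <- function(q, n_digits) {
  digits <- integer(n_digits)
  for (i in rev(seq_len(n_digits))) {
    digits[i] <- q %% 16L
    q <- q %/% 16L
  }
  SELFIES_INDEX_ALPHABET[digits + 1L]
}

decode_index_tokens <- function(tokens) {
  vals <- match(tokens, SELFIES_INDEX_ALPHABET) - 1L
  if (anyNA(vals)) {
    stop("malformed SELFIES: '", paste(tokens, collapse = ""),
         "' is not a valid index operand", call. = FALSE)
  }
  sum(vals * 16L^(rev(seq_along(vals)) - 1L))
}

index_digit_count <- function(q) {
  if (q < 16L) 1L else if (q < 256L) 2L else 3L
}

#' Split a SELFIES string into tokens
#'
#' Tokens are bracketed groups such as \code{[C]}, \code{[=O]} or
#' \code{[Branch1]}; the component separator \code{.} is returned as its own
#' token. The concatenation of the returned tokens always equals the input.
#'
#' @param selfies A single SELFIES string (may be empty).
#' @return Character vector of tokens; \code{character(0)} for the empty
#'   string.
#' @export
#' @examples
#' selfies_tokens("[C][C][O]")
selfies_tokens <- function(selfies) {
  stopifnot(is.character(selfies), length(selfies) == 1L, !is.na(selfies))
  if (!nzchar(selfies)) return(character(0))
  m <- gregexpr("\\[[^][]*\\]|\\.", selfies)[[1]]
  toks <- if (m[1] == -1L) character(0) else regmatches(selfies, list(m))[[1]]
  if (!identical(paste(toks, collapse = ""), selfies)) {
    stop("malformed SELFIES string (unbalanced brackets or stray text): '",
         selfies, "'", call. = FALSE)
  }
  toks
}

atom_token <- function(element, charge, h, prefix, explicit) {
  if (!explicit) return(paste0("[", prefix, element, "]"))
  paste0("[", prefix, element, "H", h, sprintf("%+d", charge), "]")
}

# Parse an atom token into its parts; returns NULL if the token is not an
# atom symbol (i.e. it is a Branch/Ring symbol).
parse_atom_token <- function(token) {
  body <- sub("^\\[(.*)\\]$", "\\1", token)
  m <- regexec("^([=#]?)([A-Z][a-z]?)(H([0-9]+))?(([+-])([0-9]+))?$", body)[[1]]
  if (m[1] == -1L) return(NULL)
  parts <- regmatches(body, list(regexec(
    "^([=#]?)([A-Z][a-z]?)(H([0-9]+))?(([+-])([0-9]+))?$", body)[[1]]))[[1]]
  element <- parts[3]
  if (grepl("Branch|Ring", body)) return(NULL)
  order <- match(parts[2], c("", "=", "#"))
  h <- if (nzchar(parts[5])) as.integer(parts[5 + 0][1]) else NA_integer_
  h <- if (nzchar(parts[4])) as.integer(parts[5]) else NA_integer_
  charge <- if (nzchar(parts[6])) {
    as.integer(parts[8]) * if (parts[7] == "-") -1L else 1L
  } else 0L
  list(element = element, order = order, h = h, charge = charge)
}

parse_branch_token <- function(token) {
  m <- regexec("^\\[([=#]?)Branch([123])\\]$", token)[[1]]
  if (m[1] == -1L) return(NULL)
  p <- regmatches(token, list(regexec("^\\[([=#]?)Branch([123])\\]$", token)[[1]]))[[1]]
  list(order = match(p[2], c("", "=", "#")), n = as.integer(p[3]))
}

parse_ring_token <- function(token) {
  m <- regexec("^\\[([=#]?)Ring([123])\\]$", token)[[1]]
  if (m[1] == -1L) return(NULL)
  p <- regmatches(token, list(regexec("^\\[([=#]?)Ring([123])\\]$", token)[[1]]))[[1]]
  list(order = match(p[2], c("", "=", "#")), n = as.integer(p[3]))
}

# ---------------------------------------------------------------------------
# Encoding: molecular graph -> SELFIES token stream

encode_component <- function(graph, atoms) {
  adj <- lapply(seq_along(graph$element), function(i) integer(0))
  bond_order <- new.env(parent = emptyenv())
  bkey <- function(a, b) paste(min(a, b), max(a, b))
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[k]; b <- graph$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    assign(bkey(a, b), graph$bonds$order[k], envir = bond_order)
  }
  bondsum <- vapply(seq_along(graph$element), function(i) {
    sum(vapply(adj[[i]], function(j) get(bkey(i, j), envir = bond_order),
               numeric(1)))
  }, numeric(1))

  visited <- rep(FALSE, length(graph$element))
  closed <- new.env(parent = emptyenv())
  pos <- rep(NA_integer_, length(graph$element))
  counter <- 0L

  needs_explicit <- function(v) {
    el <- graph$element[v]
    if (graph$charge[v] != 0L) return(TRUE)
    if (is.null(VALENCE_SETS[[el]])) return(TRUE)
    is.na(default_valence(el, bondsum[v]))
  }

  emit <- function(v, order_in) {
    visited[v] <<- TRUE
    counter <<- counter + 1L
    pos[v] <<- counter
    el <- graph$element[v]
    expl <- needs_explicit(v)
    h <- implicit_hydrogens(el, graph$charge[v], as.integer(bondsum[v]))
    if (expl && is.na(h)) h <- 0L
    toks <- atom_token(el, graph$charge[v], h, BOND_PREFIX[order_in], expl)
    # ring closures back to already-emitted atoms
    for (u in sort(adj[[v]])) {
      if (!visited[u]) next
      key <- bkey(v, u)
      if (!is.null(closed[[key]]) || identical(u, parent_of[[v]])) next
      closed[[key]] <- TRUE
      q <- pos[v] - pos[u] - 1L
      n <- index_digit_count(q)
      ord <- get(key, envir = bond_order)
      toks <- c(toks, paste0("[", BOND_PREFIX[ord], "Ring", n, "]"),
                encode_index_tokens(q, n))
    }
    # descend; whether a subtree needs to be wrapped as a branch is decided
    # after the recursion, because a ring inside the subtree may consume the
    # remaining siblings (a plain ring then needs no branch symbol)
    repeat {
      un <- adj[[v]][!visited[adj[[v]]]]
      if (length(un) == 0L) break
      u <- min(un)
      parent_of[[u]] <<- v
      ord <- get(bkey(v, u), envir = bond_order)
      sub <- emit(u, ord)
      still_open <- any(!visited[adj[[v]]])
      if (still_open) {
        n <- index_digit_count(length(sub) - 1L)
        toks <- c(toks, paste0("[", BOND_PREFIX[ord], "Branch", n, "]"),
                  encode_index_tokens(length(sub) - 1L, n), sub)
      } else {
        toks <- c(toks, sub)
      }
    }
    toks
  }
  parent_of <- vector("list", length(graph$element))
  root <- min(atoms)
  emit(root, 1L)  # order_in of the root is ignored (prefix "")
}

#' Encode a SMILES string as SELFIES
#'
#' The molecule is kekulized and traversed depth-first in the input string's
#' atom order, so distinct SMILES representations of one molecule yield
#' distinct SELFIES token sequences (the model is trained to become robust to
#' this through augmentation, it is not intrinsically invariant).
#'
#' @param smiles A single valid SMILES string.
#' @return A SELFIES string; decoding it recovers the same molecule
#'   (constitutionally; stereochemistry is dropped).
#' @export
#' @examples
#' to_selfies("CCO")
to_selfies <- function(smiles) {
  graph <- smiles_graph(smiles)
  n <- length(graph$element)
  if (n == 0L) stop("empty molecule cannot be encoded", call. = FALSE)
  # connected components
  comp <- integer(n)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[k]; b <- graph$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  pieces <- vapply(seq_len(cid), function(ci) {
    atoms <- which(comp == ci)
    sub <- subgraph(graph, atoms)
    paste(encode_component(sub, seq_along(atoms)), collapse = "")
  }, character(1))
  paste(pieces, collapse = ".")
}

subgraph <- function(graph, atoms) {
  idx <- match(seq_along(graph$element), atoms)
  keep <- graph$bonds$a %in% atoms & graph$bonds$b %in% atoms
  list(element = graph$element[atoms],
       charge = graph$charge[atoms],
       bonds = data.frame(a = idx[graph$bonds$a[keep]],
                          b = idx[graph$bonds$b[keep]],
                          order = graph$bonds$order[keep]))
}

# ---------------------------------------------------------------------------
# Decoding: SELFIES token stream -> molecular graph -> SMILES

decode_component <- function(tokens) {
  atoms <- list()   # each: list(element, h, charge, explicit)
  bonds <- list()
  i <- 1L
  derivation <- integer(0)  # atom indices in derivation order

  add_atom <- function(at, prev) {
    atoms[[length(atoms) + 1L]] <<- at
    id <- length(atoms)
    derivation <<- c(derivation, id)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- c(prev, id, at$order)
    }
    id
  }

  walk <- function(tokens, prev) {
    i <- 1L
    first <- TRUE
    while (i <= length(tokens)) {
      tok <- tokens[[i]]
      at <- parse_atom_token(tok)
      if (!is.null(at)) {
        if (is.na(prev)) at$order <- 1L
        prev <- add_atom(list(element = at$element, h = at$h,
                              charge = at$charge,
                              order = if (is.na(prev)) NA_integer_ else at$order),
                         prev)
        i <- i + 1L
        next
      }
      br <- parse_branch_token(tok)
      if (!is.null(br)) {
        if (is.na(prev)) {
          stop("malformed SELFIES: branch symbol with no preceding atom",
               call. = FALSE)
        }
        if (i + br$n > length(tokens)) {
          stop("malformed SELFIES: truncated branch operand", call. = FALSE)
        }
        q <- decode_index_tokens(tokens[(i + 1L):(i + br$n)])
        len <- q + 1L
        i <- i + br$n + 1L
        if (i + len - 1L > length(tokens)) {
          stop("malformed SELFIES: branch longer than remaining string",
               call. = FALSE)
        }
        walk(tokens[i:(i + len - 1L)], prev)
        i <- i + len
        next
      }
      rg <- parse_ring_token(tok)
      if (!is.null(rg)) {
        if (is.na(prev)) {
          stop("malformed SELFIES: ring symbol with no preceding atom",
               call. = FALSE)
        }
        if (i + rg$n > length(tokens)) {
          stop("malformed SELFIES: truncated ring operand", call. = FALSE)
        }
        q <- decode_index_tokens(tokens[(i + 1L):(i + rg$n)])
        p <- match(prev, derivation)
        target_pos <- p - (q + 1L)
        if (target_pos < 1L) {
          stop("malformed SELFIES: ring reference before start of string",
               call. = FALSE)
        }
        bonds[[length(bonds) + 1L]] <<- c(derivation[target_pos], prev, rg$order)
        i <- i + rg$n + 1L
        next
      }
      stop("unrecognized SELFIES token: '", tok, "'", call. = FALSE)
    }
    prev
  }
  walk(tokens, NA_integer_)
  list(atoms = atoms, bonds = bonds)
}

write_smiles_component <- function(decoded) {
  atoms <- decoded$atoms
  n <- length(atoms)
  adj <- lapply(seq_len(n), function(i) list())
  for (b in decoded$bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], list(c(b[2], b[3])))
    adj[[b[2]]] <- c(adj[[b[2]]], list(c(b[1], b[3])))
  }
  visited <- rep(FALSE, n)
  ring_digit <- new.env(parent = emptyenv())
  ring_count <- 0L
  opened <- new.env(parent = emptyenv())
  bkey <- function(a, b) paste(min(a, b), max(a, b))

  # pre-assign ring closure digits (non-tree edges under DFS from atom 1)
  pre_visited <- rep(FALSE, n)
  mark <- function(v, parent) {
    pre_visited[v] <<- TRUE
    for (e in adj[[v]]) {
      u <- e[1]
      if (u == parent && is.null(opened[[bkey(v, u)]])) {
        opened[[bkey(v, u)]] <- "tree"
        next
      }
      key <- bkey(v, u)
      if (pre_visited[u] && is.null(opened[[key]])) {
        ring_count <<- ring_count + 1L
        opened[[key]] <- ring_count
      } else if (!pre_visited[u] && is.null(opened[[key]])) {
        opened[[key]] <- "tree"
        mark(u, v)
      }
    }
  }
  mark(1L, 0L)

  atom_text <- function(v) {
    at <- atoms[[v]]
    bare_ok <- at$element %in% names(VALENCE_SETS) && at$charge == 0L && is.na(at$h)
    if (bare_ok) return(at$element)
    h <- if (is.na(at$h)) 0L else at$h
    htxt <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ctxt <- if (at$charge == 0L) "" else {
      sgn <- if (at$charge > 0L) "+" else "-"
      if (abs(at$charge) == 1L) sgn else paste0(sgn, abs(at$charge))
    }
    paste0("[", at$element, htxt, ctxt, "]")
  }
  digit_text <- function(d) if (d < 10L) as.character(d) else paste0("%", d)
  bond_text <- function(o) c("", "=", "#")[o]

  emit <- function(v, parent, order_in) {
    visited[v] <<- TRUE
    out <- paste0(if (v != 1L) bond_text(order_in) else "", atom_text(v))
    branches <- character(0)
    tails <- list()
    for (e in adj[[v]]) {
      u <- e[1]
      key <- bkey(v, u)
      tag <- opened[[key]]
      if (is.numeric(tag)) {  # ring closure digit at both endpoints
        if (is.null(closed_here[[key]])) {
          closed_here[[key]] <- TRUE
          out <- paste0(out, bond_text(e[2]), digit_text(tag))
        } else {
          out <- paste0(out, digit_text(tag))
        }
      }
    }
    kids <- Filter(function(e) !visited[e[1]] &&
                     identical(opened[[bkey(v, e[1])]], "tree"), adj[[v]])
    if (length(kids) > 0L) {
      for (k in seq_along(kids)) {
        e <- kids[[k]]
        if (visited[e[1]]) next
        txt <- emit(e[1], v, e[2])
        if (k < length(kids)) {
          out <- paste0(out, "(", txt, ")")
        } else {
          out <- paste0(out, txt)
        }
      }
    }
    out
  }
  closed_here <- new.env(parent = emptyenv())
  emit(1L, 0L, 1L)
}

#' Decode a SELFIES string to SMILES
#'
#' Inverse of \code{\link{to_selfies}} up to representation: the returned
#' SMILES denotes the same molecule, and
#' \code{canonical_smiles(from_selfies(to_selfies(s)))} equals
#' \code{canonical_smiles(s)} for molecules without stereocenters.
#'
#' @param selfies A single SELFIES string.
#' @return A SMILES string.
#' @export
#' @examples
#' from_selfies("[C][C][O]")
from_selfies <- function(selfies) {
  toks <- selfies_tokens(selfies)
  if (length(toks) == 0L) stop("empty SELFIES string", call. = FALSE)
  splits <- split(toks, cumsum(toks == "."))
  pieces <- vapply(splits, function(ts) {
    ts <- ts[ts != "."]
    if (length(ts) == 0L) return(NA_character_)
    write_smiles_component(decode_component(as.list(ts)))
  }, character(1))
  paste(pieces[!is.na(pieces)], collapse = ".")
}
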