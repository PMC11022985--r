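# Synthetic benchmark corpus with a known heteroscedastic noise model.
#
# The generator emulates the shape of a solubility training table — small
# valid organic molecules paired with a scalar label — while making the
# ground truth fully known: labels are a linear function of heavy-atom and
# oxygen counts plus Gaussian noise whose standard deviation grows with the
# oxygen fraction. Because the true noise law is known per molecule, tests
# can check that the model's aleatoric variance head actually recovers it.

#' Specification for a synthetic corpus
#'
#' Labels are \code{a * heavy_atoms + b * n_oxygen + N(0, sd^2)} with
#' \code{sd = c0 + c1 * oxygen_fraction}. Molecules are linear carbon/oxygen
#' chains with occasional methyl and hydroxyl branches, all valid SMILES.
#'
#' @param n_molecules Number of records to generate (at least 10).
#' @param a,b Label weights on heavy-atom count and oxygen count
#'   (log S units per atom).
#' @param c0,c1 Noise model: standard deviation intercept (log S, must be
#'   positive) and slope on the oxygen fraction.
#' @param seed Integer seed.
#' @return A list of class \code{soluq_synth_spec}.
#' @export
synth_spec <- function(n_molecules = 2000L, a = -0.3, b = 0.8,
                       c0 = 0.1, c1 = 0.4, seed = 11L) {
  if (n_molecules < 10L) {
    stop("`n_molecules` must be at least 10 for any training use", call. = FALSE)
  }
  if (c0 <= 0) stop("`c0` must be positive (noise sd floor)", call. = FALSE)
  if (c0 + min(0, c1) <= 0) {
    stop("noise sd must stay positive for all oxygen fractions", call. = FALSE)
  }
  structure(list(n_molecules = as.integer(n_molecules), a = a, b = b,
                 c0 = c0, c1 = c1, seed = as.integer(seed)),
            class = "soluq_synth_spec")
}

# One random chain molecule; returns smiles, heavy-atom and oxygen counts.
# Ethers are kept non-adjacent (no O-O) and branches sit only on interior
# chain carbons, so every string is a valid molecule.
random_chain_molecule <- function(min_len = 3L, max_len = 12L) {
  len <- sample(min_len:max_len, 1L)
  atoms <- character(len)
  atoms[1] <- "C"
  for (i in 2:len) {
    atoms[i] <- if (atoms[i - 1] == "O") "C" else
      sample(c("C", "O"), 1L, prob = c(0.72, 0.28))
  }
  if (atoms[len] == "O" && len >= 2L && atoms[len - 1L] == "O") atoms[len] <- "C"
  parts <- atoms
  n_branch <- 0L
  n_branch_o <- 0L
  if (len >= 4L) {
    for (i in 2:(len - 1L)) {
      if (atoms[i] == "C" && stats::runif(1) < 0.22) {
        br <- sample(c("(C)", "(O)"), 1L, prob = c(0.6, 0.4))
        parts[i] <- paste0(parts[i], br)
        n_branch <- n_branch + 1L
        if (br == "(O)") n_branch_o <- n_branch_o + 1L
      }
    }
  }
  smiles <- paste(parts, collapse = "")
  heavy <- len + n_branch
  n_o <- sum(atoms == "O") + n_branch_o
  list(smiles = smiles, heavy = heavy, n_oxygen = n_o)
}

#' Generate a synthetic corpus with known ground truth
#'
#' @param spec A \code{\link{synth_spec}}.
#' @return A list of class \code{soluq_synth}: \code{records} (a record
#'   data frame usable anywhere a loaded CSV is) and \code{truth} (one row
#'   per record: \code{smiles}, \code{heavy}, \code{n_oxygen},
#'   \code{oxygen_fraction}, \code{noiseless}, \code{true_sd},
#'   \code{log_s}). Deterministic given \code{spec$seed}.
#' @export
#' @examples
#' synth_corpus(synth_spec(n_molecules = 20, seed = 1))$truth[1:3, ]
synth_corpus <- function(spec) {
  stopifnot(inherits(spec, "soluq_synth_spec"))
  rows <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_molecules), function(i) {
      m <- random_chain_molecule()
      frac <- m$n_oxygen / m$heavy
      noiseless <- spec$a * m$heavy + spec$b * m$n_oxygen
      true_sd <- spec$c0 + spec$c1 * frac
      data.frame(smiles = m$smiles, heavy = m$heavy, n_oxygen = m$n_oxygen,
                 oxygen_fraction = frac, noiseless = noiseless,
                 true_sd = true_sd,
                 log_s = noiseless + stats::rnorm(1L, 0, true_sd),
                 stringsAsFactors = FALSE)
    })
  })
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  records <- record_frame(truth$smiles, truth$log_s,
                          paste0("synth", seq_len(nrow(truth))),
                          canonical_smiles(truth$smiles))
  structure(list(records = records, truth = truth, spec = spec),
            class = "soluq_synth")
}

#' @export
print.soluq_synth <- function(x, ...) {
  cat("synthetic corpus:", nrow(x$records), "molecules;",
      "label = ", x$spec$a, "* heavy +", x$spec$b, "* nO + N(0, (",
      x$spec$c0, "+", x$spec$c1, "* O-fraction)^2 )\n")
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Writes \code{records} as CSV and \code{truth} as JSON next to it.
#'
#' @param synth A \code{soluq_synth}.
#' @param records_path CSV path for the records.
#' @param truth_path JSON path for the ground-truth table (defaults to the
#'   records path with extension \code{.truth.json}).
#' @return \code{records_path}, invisibly.
#' @export
write_synth_corpus <- function(synth, records_path,
                               truth_path = sub("\\.csv$", ".truth.json",
                                                records_path)) {
  stopifnot(inherits(synth, "soluq_synth"))
  utils::write.csv(synth$records, records_path, row.names = FALSE)
  jsonlite::write_json(synth$truth, truth_path, digits = NA)
  invisible(records_path)
}
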