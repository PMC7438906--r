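# Amino-acid alphabet and physicochemical index tables.
#
# All encoders index residues against the 20-letter alphabet in
# lexicographic order; feature layouts inherit this ordering.

#' The 20-letter amino-acid alphabet
#'
#' Single-letter codes of the 20 natural amino acids in lexicographic
#' order. Every encoder in the package lays its features out against
#' this ordering.
#'
#' @return A character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Raw index tables, keyed by the lexicographic alphabet. The first three
# are the canonical hydrophobicity / hydrophilicity / side-chain mass
# scales used by pseudo amino acid composition; the rest are classical
# AAindex-style scales used by the autocorrelation encoders.
.raw_indices <- local({
  tab <- function(...) {
    v <- c(...)
    stopifnot(length(v) == 20L)
    names(v) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    v[.AA]
  }
  list(
    # Tanford/Chou consensus hydrophobicity
    hydrophobicity = tab(0.62, -2.53, -0.78, -0.90, 0.29, -0.85, -0.74,
                         0.48, -0.40, 1.38, 1.06, -1.50, 0.64, 1.19,
                         0.12, -0.18, -0.05, 0.81, 0.26, 1.08),
    # Hopp-Woods hydrophilicity
    hydrophilicity = tab(-0.5, 3.0, 0.2, 3.0, -1.0, 0.2, 3.0, 0.0,
                         -0.5, -1.8, -1.8, 3.0, -1.3, -2.5, 0.0, 0.3,
                         -0.4, -3.4, -2.3, -1.5),
    # side-chain mass (Da)
    side_chain_mass = tab(15.0, 101.0, 58.0, 59.0, 47.0, 72.0, 73.0,
                          1.0, 82.0, 57.0, 57.0, 73.0, 75.0, 91.0,
                          42.0, 31.0, 45.0, 130.0, 107.0, 43.0),
    # Grantham polarity
    polarity = tab(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4,
                   5.2, 4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2,
                   5.9),
    # Charton-Charton polarizability
    polarizability = tab(0.046, 0.291, 0.134, 0.105, 0.128, 0.180,
                         0.151, 0.000, 0.230, 0.186, 0.186, 0.219,
                         0.221, 0.290, 0.131, 0.062, 0.108, 0.409,
                         0.298, 0.140),
    # net charge index of side chains
    net_charge = tab(0.007187, 0.043587, 0.005392, -0.02382, -0.03661,
                     0.049211, 0.006802, 0.179052, -0.01069, 0.021631,
                     0.051672, 0.017708, 0.002683, 0.037552, 0.239531,
                     0.004627, 0.003352, 0.037977, 0.023599, 0.057004),
    # Chothia tripeptide accessible surface area
    solvent_accessibility = tab(115, 225, 160, 150, 135, 180, 190, 75,
                                195, 175, 170, 200, 185, 210, 145, 115,
                                140, 255, 230, 155),
    # Bhaskaran-Ponnuswamy average flexibility
    flexibility = tab(0.357, 0.529, 0.463, 0.511, 0.346, 0.493, 0.497,
                      0.544, 0.323, 0.462, 0.365, 0.466, 0.295, 0.314,
                      0.509, 0.507, 0.444, 0.305, 0.420, 0.386)
  )
})

#' Standardize a physicochemical amino-acid index
#'
#' Centers and scales a 20-value index to mean 0 and unit population
#' standard deviation (divisor 20) over the alphabet, the convention
#' used by pseudo amino acid composition.
#'
#' @param raw_values Named numeric vector of 20 finite values, one per
#'   amino acid (any order; names must cover the alphabet). An unnamed
#'   vector is taken to be in lexicographic alphabet order.
#' @return A numeric vector of 20 standardized values named by
#'   [aa_alphabet()].
#' @export
#' @examples
#' standardize_index(setNames(1:20, aa_alphabet()))
standardize_index <- function(raw_values) {
  if (length(raw_values) != 20L) {
    stop("a physicochemical index must have exactly 20 values", call. = FALSE)
  }
  if (is.null(names(raw_values))) {
    names(raw_values) <- .AA
  }
  if (!all(.AA %in% names(raw_values))) {
    stop("index names must cover the 20-letter amino-acid alphabet",
         call. = FALSE)
  }
  v <- as.numeric(raw_values[.AA])
  if (any(!is.finite(v))) {
    stop("index values must all be finite", call. = FALSE)
  }
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) {
    stop("degenerate index: all 20 values are equal", call. = FALSE)
  }
  out <- (v - mean(v)) / s
  names(out) <- .AA
  out
}

#' Built-in physicochemical index panel
#'
#' Eight classical amino-acid scales (hydrophobicity, hydrophilicity,
#' side-chain mass, polarity, polarizability, net charge index, solvent
#' accessibility, flexibility), standardized with [standardize_index()].
#' This panel drives the autocorrelation encoders by default; the first
#' three scales are the canonical pseudo-amino-acid-composition
#' properties.
#'
#' @param names Optional character vector selecting a subset (in the
#'   given order).
#' @param standardized Return standardized (default) or raw values.
#' @return A named list of numeric vectors of length 20.
#' @export
#' @examples
#' names(aa_index_panel())
#' aa_index_panel("hydrophobicity")
aa_index_panel <- function(names = NULL, standardized = TRUE) {
  idx <- .raw_indices
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(idx))
    if (length(missing) > 0) {
      stop("unknown index name(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    idx <- idx[names]
  }
  if (standardized) idx <- lapply(idx, standardize_index)
  idx
}

#' Read physicochemical indices from an AAindex-style flat file
#'
#' Parses a plain-text table of custom indices: one record per line,
#' an accession/name followed by 20 whitespace-separated values in
#' lexicographic alphabet order. Lines starting with `#` are ignored.
#'
#' @param path Path to the flat file.
#' @param standardized Standardize each index (default `TRUE`).
#' @return A named list of numeric vectors of length 20.
#' @export
read_aaindex <- function(path, standardized = TRUE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:],]+")[[1]]
    if (length(parts) != 21L) {
      stop("expected an accession plus 20 values, got ", length(parts),
           " fields in line: ", substr(ln, 1, 40), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(v))) {
      stop("non-numeric index value in line: ", substr(ln, 1, 40),
           call. = FALSE)
    }
    names(v) <- .AA
    out[[parts[1]]] <- if (standardized) standardize_index(v) else v
  }
  out
}

# Standardized index lookup used internally by the encoders; accepts a
# named list of raw or standardized 20-vectors and returns a matrix with
# one column per index, rows in alphabet order.
.index_matrix <- function(indices) {
  if (is.numeric(indices)) indices <- list(index = indices)
  stopifnot(is.list(indices), length(indices) >= 1)
  if (is.null(names(indices)) || any(!nzchar(names(indices)))) {
    names(indices) <- paste0("I", seq_along(indices))
  }
  vapply(indices, function(v) standardize_index(v), numeric(20))
}
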