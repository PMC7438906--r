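# Pseudo amino acid composition (PseAAC) encoders.
#
# A peptide is represented by its 20 residue frequencies f_u augmented
# with lambda sequence-order correlation factors theta_j built from
# standardized physicochemical properties, combined as
#   x_u = f_u / (sum f + w sum theta)          u = 1..20
#   x_u = w theta_{u-20} / (sum f + w sum theta)   u > 20
# Parallel correlation averages squared property differences at lag j;
# series correlation uses per-property products, two tiers per lag in
# the classical 2-property (hydrophobicity, hydrophilicity) form.

.pseaac_default_parallel <- function() {
  aa_index_panel(c("hydrophobicity", "hydrophilicity", "side_chain_mass"))
}
.pseaac_default_series <- function() {
  aa_index_panel(c("hydrophobicity", "hydrophilicity"))
}

#' Sequence-order correlation factors for PseAAC
#'
#' Computes the lambda (parallel mode) or lambda * n_properties (series
#' mode) correlation tiers of a single peptide.
#'
#' Parallel mode: theta_j is the average over positions i of the
#' correlation function Theta(Ri, Ri+j), the mean squared difference of
#' the standardized properties between the two residues. Series mode:
#' one tier per (lag, property), the average product of the
#' standardized property values of residues lag apart; with the default
#' two properties this is the classical series-correlation layout
#' (theta_1 = hydrophobicity at lag 1, theta_2 = hydrophilicity at lag
#' 1, ...).
#'
#' @param sequence A single peptide sequence.
#' @param lambda Highest correlation tier (>= 1); the sequence must be
#'   longer than `lambda`.
#' @param mode `"parallel"` or `"series"`.
#' @param properties Named list of physicochemical indices
#'   (standardized internally). Defaults: hydrophobicity +
#'   hydrophilicity + side-chain mass (parallel), hydrophobicity +
#'   hydrophilicity (series).
#' @return Numeric vector of correlation factors: length `lambda`
#'   (parallel) or `lambda * length(properties)` (series, lag-major).
#' @export
#' @examples
#' correlation_factors("FLPKKAIDE", lambda = 3)
correlation_factors <- function(sequence, lambda = 4L,
                                mode = c("parallel", "series"),
                                properties = NULL) {
  mode <- match.arg(mode)
  if (is.null(properties)) {
    properties <- if (mode == "parallel") .pseaac_default_parallel()
                  else .pseaac_default_series()
  }
  imat <- .index_matrix(properties)
  x <- .encode_sequences(sequence)[[1]]
  .theta(x, as.integer(lambda), mode, imat)
}

.theta <- function(x, lambda, mode, imat) {
  L <- length(x)
  if (lambda < 1L) stop("lambda must be >= 1", call. = FALSE)
  if (L <= lambda) {
    stop("sequence length ", L, " must exceed lambda = ", lambda,
         call. = FALSE)
  }
  sig <- imat[x, , drop = FALSE]
  n_prop <- ncol(imat)
  if (mode == "parallel") {
    vapply(seq_len(lambda), function(j) {
      d2 <- (sig[seq_len(L - j), , drop = FALSE] -
               sig[(1L + j):L, , drop = FALSE])^2
      mean(rowMeans(d2))
    }, numeric(1))
  } else {
    # lag-major: all properties at lag 1, then lag 2, ...
    as.vector(vapply(seq_len(lambda), function(j) {
      colMeans(sig[seq_len(L - j), , drop = FALSE] *
                 sig[(1L + j):L, , drop = FALSE])
    }, numeric(n_prop)))
  }
}

.pseaac_matrix <- function(codes, lambda, w, imat, mode, tier_prefix) {
  n_prop <- ncol(imat)
  n_theta <- if (mode == "parallel") lambda else lambda * n_prop
  cn <- c(paste0("f_", .AA), paste0(tier_prefix, seq_len(n_theta)))
  mat <- t(vapply(codes, function(x) {
    L <- length(x)
    f <- tabulate(x, nbins = 20L) / L
    theta <- .theta(x, lambda, mode, imat)
    denom <- sum(f) + w * sum(theta)
    if (denom <= 0) {
      stop("degenerate PseAAC encoding: nonpositive normalizer (",
           format(denom), ") for sequence '", paste(.AA[x], collapse = ""),
           "'", call. = FALSE)
    }
    c(f, w * theta) / denom
  }, numeric(20L + n_theta)))
  colnames(mat) <- cn
  mat
}

#' Parallel-correlation pseudo amino acid composition (PC-PseAAC)
#'
#' The classical PseAAC: 20 residue frequencies plus lambda parallel
#' correlation factors built from standardized hydrophobicity,
#' hydrophilicity and side-chain mass, normalized so the vector sums
#' to 1.
#'
#' @inheritParams encode_kmer
#' @param lambda Highest correlation tier (sequences must be longer
#'   than `lambda`). Default 4, the largest value admissible for
#'   5-residue peptides.
#' @param w Weight of the correlation part, in (0, 1]. Default 0.05.
#' @return A tibble: `id` plus 20 + lambda columns.
#' @export
encode_pc_pseaac <- function(data, lambda = 4L, w = 0.05) {
  encode_pseaac_general(data, lambda = lambda, w = w,
                        properties = .pseaac_default_parallel(),
                        mode = "parallel")
}

#' Series-correlation pseudo amino acid composition (SC-PseAAC)
#'
#' The series-correlation variant: 20 residue frequencies plus 2*lambda
#' tiers, odd tiers from products of standardized hydrophobicity
#' values and even tiers from hydrophilicity, at lags 1..lambda.
#'
#' @inheritParams encode_pc_pseaac
#' @return A tibble: `id` plus 20 + 2*lambda columns.
#' @export
encode_sc_pseaac <- function(data, lambda = 4L, w = 0.05) {
  encode_pseaac_general(data, lambda = lambda, w = w,
                        properties = .pseaac_default_series(),
                        mode = "series")
}

#' General pseudo amino acid composition with custom property sets
#'
#' Generalizes PC-/SC-PseAAC to an arbitrary ordered set of
#' physicochemical indices: parallel mode averages squared property
#' differences over the set (dim 20 + lambda); series mode produces one
#' tier per (lag, property) pair (dim 20 + lambda * n_properties).
#'
#' @inheritParams encode_pc_pseaac
#' @param properties Named list of physicochemical indices
#'   (standardized internally); defaults to the classical sets of
#'   [encode_pc_pseaac()] / [encode_sc_pseaac()].
#' @param mode `"parallel"` or `"series"`.
#' @return A tibble of PseAAC features.
#' @export
encode_pseaac_general <- function(data, lambda = 4L, w = 0.05,
                                  properties = NULL,
                                  mode = c("parallel", "series")) {
  mode <- match.arg(mode)
  data <- .as_peptide_tbl(data)
  if (w <= 0 || w > 1) stop("w must lie in (0, 1]", call. = FALSE)
  if (is.null(properties)) {
    properties <- if (mode == "parallel") .pseaac_default_parallel()
                  else .pseaac_default_series()
  }
  imat <- .index_matrix(properties)
  codes <- .encode_sequences(data$sequence)
  prefix <- if (mode == "parallel") "theta" else "tau"
  .feature_tbl(data, .pseaac_matrix(codes, as.integer(lambda), w, imat,
                                    mode, prefix))
}
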