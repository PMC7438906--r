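# Physicochemical autocorrelation encoders: auto covariance (AC),
# cross covariance (CC), auto-cross covariance (ACC), and the
# physicochemical distance transformation (PDT).
#
# A peptide P = R1 R2 ... RL is turned into one numeric signal per
# index u, Iu(Ri); covariances are taken at lags d = 1..dmax with the
# per-sequence mean subtracted:
#   AC(u,d)   = sum_i (Iu(Ri) - mean(Iu)) (Iu(Ri+d) - mean(Iu)) / (L-d)
#   CC(u,v,d) = sum_i (Iu(Ri) - mean(Iu)) (Iv(Ri+d) - mean(Iv)) / (L-d)
# PDT replaces the product by a squared difference:
#   PDT(u,d)  = sum_i (Iu(Ri) - Iu(Ri+d))^2 / (L-d)
# Index values are standardized over the alphabet before use.

# signal matrix: rows = positions, cols = indices
.index_signal <- function(x, imat) imat[x, , drop = FALSE]

.autocov_matrix <- function(codes, imat, dmax, mode) {
  n_idx <- ncol(imat)
  idx_names <- colnames(imat)
  want_ac <- mode %in% c("ac", "acc")
  want_cc <- mode %in% c("cc", "acc")
  ac_names <- if (want_ac) {
    as.vector(t(outer(idx_names, seq_len(dmax),
                      function(u, d) paste0("AC_", u, "_d", d))))
  }
  cc_names <- if (want_cc) {
    unlist(lapply(idx_names, function(u)
      unlist(lapply(setdiff(idx_names, u), function(v)
        paste0("CC_", u, "_", v, "_d", seq_len(dmax))))))
  }
  cn <- c(ac_names, cc_names)
  mat <- t(vapply(codes, function(x) {
    L <- length(x)
    if (L <= dmax) {
      stop("sequence length ", L, " must exceed dmax = ", dmax,
           call. = FALSE)
    }
    sig <- .index_signal(x, imat)
    cent <- sweep(sig, 2L, colMeans(sig))
    out <- numeric(0)
    if (want_ac) {
      for (u in seq_len(n_idx)) {
        for (d in seq_len(dmax)) {
          out <- c(out, sum(cent[seq_len(L - d), u] *
                              cent[(1L + d):L, u]) / (L - d))
        }
      }
    }
    if (want_cc) {
      for (u in seq_len(n_idx)) {
        for (v in setdiff(seq_len(n_idx), u)) {
          for (d in seq_len(dmax)) {
            out <- c(out, sum(cent[seq_len(L - d), u] *
                                cent[(1L + d):L, v]) / (L - d))
          }
        }
      }
    }
    out
  }, numeric(length(cn))))
  colnames(mat) <- cn
  mat
}

#' Auto/cross covariance encoding of physicochemical signals
#'
#' Encodes each peptide as the covariance structure of its
#' physicochemical index signals at lags 1..dmax: mode `"ac"` gives the
#' auto covariance of each index with itself, `"cc"` the cross
#' covariance of every ordered pair of distinct indices, and `"acc"`
#' their concatenation (AC block first).
#'
#' @inheritParams encode_kmer
#' @param indices Named list of 20-value physicochemical indices (raw
#'   or standardized; they are standardized internally). Default: the
#'   built-in 8-index panel of [aa_index_panel()].
#' @param dmax Maximum lag (>= 1); every sequence must be longer than
#'   `dmax`. Default 2.
#' @param mode `"ac"`, `"cc"` or `"acc"`.
#' @return A tibble: `id` plus n_idx*dmax (`ac`),
#'   n_idx*(n_idx-1)*dmax (`cc`) or n_idx^2*dmax (`acc`) columns.
#' @export
#' @examples
#' encode_autocovariance("FLPKKAIDE", dmax = 2, mode = "ac",
#'                       indices = aa_index_panel("hydrophobicity"))
encode_autocovariance <- function(data, indices = aa_index_panel(),
                                  dmax = 2L,
                                  mode = c("acc", "ac", "cc")) {
  data <- .as_peptide_tbl(data)
  mode <- match.arg(mode)
  if (dmax < 1L) stop("dmax must be >= 1", call. = FALSE)
  imat <- .index_matrix(indices)
  if (mode %in% c("cc", "acc") && ncol(imat) < 2L) {
    stop("cross covariance requires at least two indices", call. = FALSE)
  }
  codes <- .encode_sequences(data$sequence)
  .feature_tbl(data, .autocov_matrix(codes, imat, as.integer(dmax), mode))
}

.pdt_matrix <- function(codes, imat, dmax) {
  n_idx <- ncol(imat)
  cn <- as.vector(t(outer(colnames(imat), seq_len(dmax),
                          function(u, d) paste0("PDT_", u, "_d", d))))
  mat <- t(vapply(codes, function(x) {
    L <- length(x)
    if (L <= dmax) {
      stop("sequence length ", L, " must exceed dmax = ", dmax,
           call. = FALSE)
    }
    sig <- .index_signal(x, imat)
    out <- numeric(0)
    for (u in seq_len(n_idx)) {
      for (d in seq_len(dmax)) {
        out <- c(out, sum((sig[seq_len(L - d), u] -
                             sig[(1L + d):L, u])^2) / (L - d))
      }
    }
    out
  }, numeric(n_idx * dmax)))
  colnames(mat) <- cn
  mat
}

#' Physicochemical distance transformation (PDT) encoding
#'
#' Each peptide is encoded as a numeric signal per physicochemical
#' index; the feature for index u and lag d is the mean squared
#' difference of the standardized signal between residues d apart.
#'
#' @inheritParams encode_autocovariance
#' @return A tibble: `id` plus n_idx*dmax columns.
#' @export
encode_pdt <- function(data, indices = aa_index_panel(), dmax = 2L) {
  data <- .as_peptide_tbl(data)
  if (dmax < 1L) stop("dmax must be >= 1", call. = FALSE)
  imat <- .index_matrix(indices)
  codes <- .encode_sequences(data$sequence)
  .feature_tbl(data, .pdt_matrix(codes, imat, as.integer(dmax)))
}
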