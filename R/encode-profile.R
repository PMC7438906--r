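# Profile-based encoders driven by PSSM frequency profiles: Top-n-gram,
# distance-based Top-n-gram (DT), profile PDT, AC/CC/ACC over PSSM
# columns, PSSM distance transformation (PSSM-DT), and PSSM relation
# transformation (PSSM-RT).
#
# On a one-hot profile (each row all mass on the true residue) these
# encoders collapse to their sequence counterparts: Top-1-gram to k=1
# composition, DT and PSSM-DT to the distance-pair blocks of DR.

# Accept a tibble with a `pssm` list-column or a bare list of pssm
# objects.
.as_pssm_list <- function(data) {
  if (inherits(data, "pssm")) return(list(data))
  if (is.data.frame(data)) return(.get_pssms(data))
  stopifnot(is.list(data), all(vapply(data, inherits, logical(1), "pssm")))
  data
}

.pssm_feature_tbl <- function(data, mat) {
  ids <- if (is.data.frame(data)) {
    data$id
  } else {
    vapply(.as_pssm_list(data), `[[`, character(1), "id")
  }
  dplyr::bind_cols(tibble::tibble(id = ids),
                   tibble::as_tibble(mat, .name_repair = "minimal"))
}

# Per-position Top-n-gram indices: at each row take the n highest
# frequencies (ties alphabetical) and map the ordered n-tuple to its
# lexicographic index in 1..20^n.
.top_grams <- function(freq, n) {
  apply(freq, 1L, function(row) {
    top <- order(-row)[seq_len(n)]  # order() breaks ties by column,
    idx <- 0                        # i.e. alphabetically
    for (j in top) idx <- idx * 20 + (j - 1)
    idx + 1
  })
}

.check_profile_len <- function(L, dmax) {
  if (L <= dmax) {
    stop("profile with ", L, " rows must be longer than dmax = ", dmax,
         call. = FALSE)
  }
}

#' Top-n-gram encoding of a frequency profile
#'
#' At each profile position the n amino acids with the highest
#' frequencies (ties broken alphabetically) form that position's
#' Top-n-gram; the peptide is encoded by the counts (or frequencies)
#' of each possible n-tuple.
#'
#' @param data Peptide tibble carrying a `pssm` list-column (see
#'   [attach_pssms()]), a list of [pssm()] objects, or a single `pssm`.
#' @param n Gram size (1 <= n <= 20). Default 1.
#' @param normalize Divide counts by the profile length.
#' @return A tibble: `id` plus 20^n columns.
#' @export
encode_top_ngram <- function(data, n = 1L, normalize = TRUE) {
  pssms <- .as_pssm_list(data)
  n <- as.integer(n)
  if (n < 1L || n > 20L) stop("n must be in 1..20", call. = FALSE)
  dim <- 20L^n
  mat <- t(vapply(pssms, function(p) {
    grams <- .top_grams(p$frequencies, n)
    counts <- tabulate(grams, nbins = dim)
    if (normalize) counts / length(grams) else as.numeric(counts)
  }, numeric(dim)))
  colnames(mat) <- .word_names(.AA, n)
  .pssm_feature_tbl(data, mat)
}

#' Distance-based Top-n-gram (DT) encoding
#'
#' Counts of ordered Top-n-gram pairs at positions (i, i+d) for
#' d = 1..dmax, one block per distance (layout as in [encode_dr()]
#' without the monomer block).
#'
#' @inheritParams encode_top_ngram
#' @param dmax Maximum pair distance (profiles must be longer than
#'   `dmax`). Default 2.
#' @return A tibble: `id` plus 20^(2n) * dmax columns.
#' @export
encode_dt <- function(data, n = 1L, dmax = 2L, normalize = TRUE) {
  pssms <- .as_pssm_list(data)
  n <- as.integer(n)
  dmax <- as.integer(dmax)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (dmax < 1L) stop("dmax must be >= 1", call. = FALSE)
  m <- 20L^n
  gram_names <- .word_names(.AA, n)
  pair_names <- as.vector(t(outer(gram_names, gram_names, paste0)))
  cn <- unlist(lapply(seq_len(dmax),
                      function(d) paste0("d", d, "_", pair_names)))
  mat <- t(vapply(pssms, function(p) {
    L <- nrow(p$frequencies)
    .check_profile_len(L, dmax)
    grams <- .top_grams(p$frequencies, n)
    out <- numeric(0)
    for (d in seq_len(dmax)) {
      idx <- (grams[seq_len(L - d)] - 1) * m + grams[(1L + d):L]
      counts <- tabulate(idx, nbins = m * m)
      out <- c(out, if (normalize) counts / (L - d) else as.numeric(counts))
    }
    out
  }, numeric(m * m * dmax)))
  colnames(mat) <- cn
  .pssm_feature_tbl(data, mat)
}

#' Profile-based physicochemical distance transformation (PDT-profile)
#'
#' For each lag d = 1..dmax, the mean (over positions and the 20
#' residue columns) squared difference between frequency-profile rows
#' d apart:
#' `PDTp(d) = 1/(L-d) * sum_i 1/20 * sum_j (f(i,j) - f(i+d,j))^2`.
#'
#' @inheritParams encode_dt
#' @return A tibble: `id` plus `dmax` columns.
#' @export
encode_pdt_profile <- function(data, dmax = 2L) {
  pssms <- .as_pssm_list(data)
  dmax <- as.integer(dmax)
  if (dmax < 1L) stop("dmax must be >= 1", call. = FALSE)
  mat <- t(vapply(pssms, function(p) {
    f <- p$frequencies
    L <- nrow(f)
    .check_profile_len(L, dmax)
    vapply(seq_len(dmax), function(d) {
      sum((f[seq_len(L - d), , drop = FALSE] -
             f[(1L + d):L, , drop = FALSE])^2) / 20 / (L - d)
    }, numeric(1))
  }, numeric(dmax)))
  colnames(mat) <- paste0("PDTp_d", seq_len(dmax))
  .pssm_feature_tbl(data, mat)
}

#' Auto/cross covariance of PSSM columns (AC-/CC-/ACC-PSSM)
#'
#' Treats the 20 frequency-profile columns as physicochemical signals
#' and computes their mean-centered auto covariance (mode `"ac"`),
#' cross covariance over ordered column pairs (`"cc"`), or both
#' (`"acc"`, AC block first) at lags 1..dmax.
#'
#' @inheritParams encode_dt
#' @param mode `"ac"`, `"cc"` or `"acc"`.
#' @return A tibble: `id` plus 20*dmax, 380*dmax or 400*dmax columns.
#' @export
encode_pssm_covariance <- function(data, dmax = 2L,
                                   mode = c("acc", "ac", "cc")) {
  pssms <- .as_pssm_list(data)
  mode <- match.arg(mode)
  dmax <- as.integer(dmax)
  if (dmax < 1L) stop("dmax must be >= 1", call. = FALSE)
  want_ac <- mode %in% c("ac", "acc")
  want_cc <- mode %in% c("cc", "acc")
  ac_names <- if (want_ac) {
    as.vector(t(outer(.AA, seq_len(dmax),
                      function(a, d) paste0("AC_", a, "_d", d))))
  }
  cc_names <- if (want_cc) {
    unlist(lapply(.AA, function(a)
      unlist(lapply(setdiff(.AA, a), function(b)
        paste0("CC_", a, "_", b, "_d", seq_len(dmax))))))
  }
  cn <- c(ac_names, cc_names)
  mat <- t(vapply(pssms, function(p) {
    f <- p$frequencies
    L <- nrow(f)
    .check_profile_len(L, dmax)
    cent <- sweep(f, 2L, colMeans(f))
    out <- numeric(0)
    if (want_ac) {
      for (j in seq_len(20L)) {
        for (d in seq_len(dmax)) {
          out <- c(out, sum(cent[seq_len(L - d), j] *
                              cent[(1L + d):L, j]) / (L - d))
        }
      }
    }
    if (want_cc) {
      for (j in seq_len(20L)) {
        for (j2 in setdiff(seq_len(20L), j)) {
          for (d in seq_len(dmax)) {
            out <- c(out, sum(cent[seq_len(L - d), j] *
                                cent[(1L + d):L, j2]) / (L - d))
          }
        }
      }
    }
    out
  }, numeric(length(cn))))
  colnames(mat) <- cn
  .pssm_feature_tbl(data, mat)
}

#' PSSM distance transformation (PSSM-DT)
#'
#' Soft co-occurrence of amino-acid pairs at bounded distances: for
#' each ordered residue pair (a, b) and lag d,
#' `sum_i freq(i, a) * freq(i+d, b) / (L-d)`.
#'
#' @inheritParams encode_dt
#' @return A tibble: `id` plus 400*dmax columns.
#' @export
encode_pssm_dt <- function(data, dmax = 2L) {
  pssms <- .as_pssm_list(data)
  dmax <- as.integer(dmax)
  if (dmax < 1L) stop("dmax must be >= 1", call. = FALSE)
  pair_names <- .word_names(.AA, 2L)
  cn <- unlist(lapply(seq_len(dmax),
                      function(d) paste0("d", d, "_", pair_names)))
  mat <- t(vapply(pssms, function(p) {
    f <- p$frequencies
    L <- nrow(f)
    .check_profile_len(L, dmax)
    out <- numeric(0)
    for (d in seq_len(dmax)) {
      cp <- crossprod(f[seq_len(L - d), , drop = FALSE],
                      f[(1L + d):L, , drop = FALSE]) / (L - d)
      out <- c(out, as.vector(t(cp)))  # pair (a, b), a slowest
    }
    out
  }, numeric(400L * dmax)))
  colnames(mat) <- cn
  .pssm_feature_tbl(data, mat)
}

#' PSSM relation transformation (PSSM-RT)
#'
#' Captures relationships of evolutionary information between residues
#' by binarizing the score matrix at a threshold (score > threshold
#' becomes 1) and counting, for each ordered residue pair (a, b) and
#' lag d, the positions where both binarized entries are 1, normalized
#' by (L-d). The binarize-and-co-count rule is this package's explicit
#' construction of the relation transform; see the methods vignette.
#'
#' @inheritParams encode_dt
#' @param threshold Binarization threshold on the score scale.
#'   Default 0 (residues scoring above the background).
#' @return A tibble: `id` plus 400*dmax columns.
#' @export
encode_pssm_rt <- function(data, dmax = 2L, threshold = 0) {
  pssms <- .as_pssm_list(data)
  dmax <- as.integer(dmax)
  if (dmax < 1L) stop("dmax must be >= 1", call. = FALSE)
  pair_names <- .word_names(.AA, 2L)
  cn <- unlist(lapply(seq_len(dmax),
                      function(d) paste0("d", d, "_", pair_names)))
  mat <- t(vapply(pssms, function(p) {
    b <- (p$scores > threshold) * 1
    L <- nrow(b)
    .check_profile_len(L, dmax)
    out <- numeric(0)
    for (d in seq_len(dmax)) {
      cp <- crossprod(b[seq_len(L - d), , drop = FALSE],
                      b[(1L + d):L, , drop = FALSE]) / (L - d)
      out <- c(out, as.vector(t(cp)))
    }
    out
  }, numeric(400L * dmax)))
  colnames(mat) <- cn
  .pssm_feature_tbl(data, mat)
}
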