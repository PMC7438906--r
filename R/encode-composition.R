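# Composition encoders: k-mer, distance-based residue pairs (DR), and
# reduced-alphabet distance pairs.
#
# All layouts are lexicographic over the alphabet with the first
# residue of a word/pair varying slowest.

# All words of length k over `letters_m` in lexicographic order.
.word_names <- function(letters_m, k) {
  if (k == 1L) return(letters_m)
  grid <- expand.grid(rev(replicate(k, letters_m, simplify = FALSE)),
                      stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

# Lexicographic word index (first position slowest) of each window of
# length k in integer codes x over an m-letter alphabet.
.word_index <- function(x, k, m) {
  L <- length(x)
  n <- L - k + 1L
  idx <- rep(0, n)
  for (j in seq_len(k)) {
    idx <- idx * m + (x[j:(j + n - 1L)] - 1L)
  }
  idx + 1L
}

.kmer_matrix <- function(codes, k, normalize, m = 20L,
                         letters_m = .AA) {
  dim <- m^k
  mat <- t(vapply(codes, function(x) {
    L <- length(x)
    if (L < k) {
      stop("sequence of length ", L, " is shorter than k = ", k,
           call. = FALSE)
    }
    counts <- tabulate(.word_index(x, k, m), nbins = dim)
    if (normalize) counts / (L - k + 1L) else as.numeric(counts)
  }, numeric(dim)))
  colnames(mat) <- .word_names(letters_m, k)
  mat
}

#' k-mer composition encoding
#'
#' Counts (or frequencies) of every k-letter word among the L-k+1
#' sliding windows of each peptide; the classical composition
#' descriptor (k = 1 is plain amino-acid composition, k = 2 dipeptide
#' composition).
#'
#' @param data Peptide tibble with a `sequence` column, or a character
#'   vector of sequences.
#' @param k Word length (>= 1). Default 2.
#' @param normalize Divide counts by the number of windows so the
#'   vector sums to 1 (default `TRUE`).
#' @return A tibble: `id` plus 20^k feature columns named by word, in
#'   lexicographic order.
#' @export
#' @examples
#' encode_kmer(c(p1 = "FLPKK"), k = 1)
encode_kmer <- function(data, k = 2L, normalize = TRUE) {
  data <- .as_peptide_tbl(data)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  codes <- .encode_sequences(data$sequence)
  .feature_tbl(data, .kmer_matrix(codes, as.integer(k), normalize))
}

.dr_matrix <- function(codes, dmax, normalize, m = 20L,
                       letters_m = .AA) {
  dim <- m + m * m * dmax
  pair_names <- .word_names(letters_m, 2L)
  cn <- c(paste0("d0_", letters_m),
          if (dmax > 0)
            unlist(lapply(seq_len(dmax),
                          function(d) paste0("d", d, "_", pair_names))))
  mat <- t(vapply(codes, function(x) {
    L <- length(x)
    mono <- tabulate(x, nbins = m)
    out <- if (normalize) mono / sum(mono) else as.numeric(mono)
    for (d in seq_len(dmax)) {
      if (L - d >= 1L) {
        idx <- (x[seq_len(L - d)] - 1L) * m + x[(1L + d):L]
        counts <- tabulate(idx, nbins = m * m)
        block <- if (normalize) counts / (L - d) else as.numeric(counts)
      } else {
        block <- numeric(m * m)
      }
      out <- c(out, block)
    }
    out
  }, numeric(dim)))
  colnames(mat) <- cn
  mat
}

#' Distance-based residue (DR) encoding
#'
#' Counts of ordered residue pairs (Ri, Ri+d) for every distance
#' d = 1..dmax, preceded by the 20 single-residue counts as the d = 0
#' block. With `normalize = TRUE` each distance block is divided by its
#' own pair total; blocks whose distance exceeds the sequence length
#' stay zero.
#'
#' @inheritParams encode_kmer
#' @param dmax Maximum pair distance (>= 0). Default 3.
#' @return A tibble: `id` plus 20 + 400*dmax feature columns
#'   (`d0_A`, ..., `d1_AA`, `d1_AC`, ...).
#' @export
encode_dr <- function(data, dmax = 3L, normalize = TRUE) {
  data <- .as_peptide_tbl(data)
  if (dmax < 0L) stop("dmax must be >= 0", call. = FALSE)
  codes <- .encode_sequences(data$sequence)
  .feature_tbl(data, .dr_matrix(codes, as.integer(dmax), normalize))
}

#' Distance-pair encoding over a reduced amino-acid alphabet
#'
#' The DR counting scheme applied after mapping each residue through a
#' clustered (reduced) alphabet, shrinking the pair space from 400 to
#' m^2 combinations.
#'
#' @inheritParams encode_dr
#' @param alphabet A [reduced_alphabet()] (or the name of a bundled
#'   one). Default `"cp14"`.
#' @return A tibble: `id` plus m + m^2*dmax feature columns; cluster
#'   labels `c1..cm`.
#' @export
encode_distance_pair <- function(data, dmax = 3L, alphabet = "cp14",
                                 normalize = TRUE) {
  data <- .as_peptide_tbl(data)
  if (dmax < 0L) stop("dmax must be >= 0", call. = FALSE)
  if (!inherits(alphabet, "reduced_alphabet")) {
    alphabet <- reduced_alphabet(alphabet)
  }
  if (length(alphabet$mapping) != 20L || anyNA(alphabet$mapping)) {
    stop("reduced alphabet mapping must cover all 20 residues",
         call. = FALSE)
  }
  codes <- lapply(.encode_sequences(data$sequence),
                  function(x) unname(alphabet$mapping[x]))
  letters_m <- paste0("c", seq_len(alphabet$m))
  .feature_tbl(data, .dr_matrix(codes, as.integer(dmax), normalize,
                                m = alphabet$m, letters_m = letters_m))
}
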