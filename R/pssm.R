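# Position-specific scoring matrices (PSSMs) and their frequency
# profiles.
#
# A `pssm` holds an L x 20 score matrix (columns in lexicographic
# alphabet order internally) and the derived row-stochastic frequency
# profile. Scores are mapped to frequencies cell-wise with the bounded
# logistic transform f = 1 / (1 + 2^(-score)) and each row is then
# renormalized to sum to 1; files that already contain frequencies can
# be wrapped directly with `pssm(..., scores_are = "frequencies")`.

# PSI-BLAST writes columns in this residue order.
.PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.score_to_freq <- function(scores) {
  f <- 1 / (1 + 2^(-scores))
  f / rowSums(f)
}

.freq_to_score <- function(freq, floor = 1e-9) {
  p <- pmin(pmax(freq, floor), 1 - floor)
  -log2(1 / p - 1)
}

#' Construct a PSSM object
#'
#' @param scores L x 20 numeric matrix. Columns must be named with the
#'   20 amino acids (any order; they are reordered lexicographically)
#'   or be in lexicographic order if unnamed.
#' @param id Peptide identifier.
#' @param scores_are `"scores"` (log-odds; frequencies derived via the
#'   logistic transform) or `"frequencies"` (rows renormalized, scores
#'   derived by the inverse transform).
#' @return An object of class `pssm` with elements `id`, `scores`,
#'   `frequencies` (both L x 20, alphabet-ordered columns).
#' @export
pssm <- function(scores, id = "peptide",
                 scores_are = c("scores", "frequencies")) {
  scores_are <- match.arg(scores_are)
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    stop("a PSSM must have exactly 20 columns, got ", ncol(scores),
         call. = FALSE)
  }
  if (!is.null(colnames(scores))) {
    if (!setequal(colnames(scores), .AA)) {
      stop("PSSM column names must be the 20 amino acids", call. = FALSE)
    }
    scores <- scores[, .AA, drop = FALSE]
  } else {
    colnames(scores) <- .AA
  }
  if (any(!is.finite(scores))) {
    stop("PSSM contains non-finite entries", call. = FALSE)
  }
  if (scores_are == "frequencies") {
    if (any(scores < 0)) {
      stop("frequency PSSM entries must be nonnegative", call. = FALSE)
    }
    freq <- scores / rowSums(scores)
    scores <- .freq_to_score(freq)
    colnames(scores) <- .AA
  } else {
    freq <- .score_to_freq(scores)
  }
  structure(list(id = id, scores = scores, frequencies = freq),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM '", x$id, "': ", nrow(x$scores), " positions x 20 residues\n",
      sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the layout written by `psiblast -out_ascii_pssm`: header
#' lines, a column-letter line, then one row per position holding the
#' position index, the query residue and 20 (or 40, score + percentage)
#' numeric columns. Only the first 20 numeric columns (the log-odds
#' scores) are used; frequencies are derived with the logistic
#' transform described in [pssm()].
#'
#' @param path Path to the ASCII PSSM file.
#' @param id Peptide identifier; defaults to the file stem.
#' @return A [pssm()] object.
#' @export
read_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  # locate the column-header line: >= 20 single-letter fields
  header_at <- NA_integer_
  col_order <- NULL
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) >= 20L && all(f %in% .AA) &&
        setequal(f[seq_len(20)], .AA)) {
      header_at <- i
      col_order <- f[seq_len(20)]
      break
    }
  }
  if (is.na(header_at)) {
    stop("not a PSI-BLAST ASCII PSSM: no residue column header in '",
         path, "'", call. = FALSE)
  }
  rows <- list()
  for (i in (header_at + 1L):length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    # stop at trailer lines (K, Lambda statistics)
    if (is.na(suppressWarnings(as.integer(f[1])))) break
    if (length(f) < 22L) {
      stop("PSSM row on line ", i, " has ", length(f) - 2L,
           " numeric columns; expected at least 20", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (anyNA(v)) {
      stop("non-numeric PSSM entry on line ", i, " of '", path, "'",
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- v
  }
  if (length(rows) == 0) {
    stop("PSSM '", path, "' contains no data rows", call. = FALSE)
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  pssm(scores, id = id)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Writes scores (real-valued, 6 decimals) in the `-out_ascii_pssm`
#' column order so that [read_pssm()] round-trips the matrix.
#'
#' @param x A [pssm()] object.
#' @param path Output path.
#' @param sequence Optional query sequence for the residue column;
#'   defaults to the per-row score argmax.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path, sequence = NULL) {
  stopifnot(inherits(x, "pssm"))
  L <- nrow(x$scores)
  res <- if (is.null(sequence)) {
    .AA[max.col(x$scores, ties.method = "first")]
  } else {
    strsplit(sequence, "")[[1]]
  }
  stopifnot(length(res) == L)
  sc <- x$scores[, .PSIBLAST_ORDER, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("    ", paste(sprintf(" %11s", .PSIBLAST_ORDER),
                                  collapse = "")), con)
  for (i in seq_len(L)) {
    writeLines(paste0(sprintf("%4d %s", i, res[i]),
                      paste(sprintf(" %11.6f", sc[i, ]), collapse = "")),
               con)
  }
  writeLines("", con)
  invisible(path)
}

#' Attach per-peptide PSSMs to a dataset
#'
#' Adds a `pssm` list-column by matching each record id to a PSSM file.
#' Files are located either by filename stem in a directory (the first
#' whitespace-delimited token of the FASTA id, plus `ext`) or through a
#' manifest TSV with columns `id` and `path`.
#'
#' @param data Peptide tibble.
#' @param dir Directory of ASCII PSSM files named `<id><ext>`.
#' @param manifest Path of a TSV (`id`, `path`) instead of `dir`.
#' @param ext File extension used with `dir`. Default `".pssm"`.
#' @return `data` with a `pssm` list-column; records without a matching
#'   file get `NULL` and a warning.
#' @export
attach_pssms <- function(data, dir = NULL, manifest = NULL,
                         ext = ".pssm") {
  stopifnot(xor(is.null(dir), is.null(manifest)))
  stem <- vapply(strsplit(data$id, "[[:space:]]+"), `[`, character(1), 1)
  paths <- if (!is.null(dir)) {
    file.path(dir, paste0(stem, ext))
  } else {
    man <- utils::read.delim(manifest, header = TRUE,
                             stringsAsFactors = FALSE)
    stopifnot(all(c("id", "path") %in% names(man)))
    man$path[match(stem, man$id)]
  }
  found <- !is.na(paths) & file.exists(paths)
  if (!all(found)) {
    warning(sum(!found), " record(s) have no PSSM file; profile ",
            "encoders will not be applicable to them", call. = FALSE)
  }
  data$pssm <- lapply(seq_along(paths), function(i) {
    if (found[i]) read_pssm(paths[i], id = stem[i]) else NULL
  })
  data
}

# Pull the pssm list-column (or a parallel list) and fail with ids if
# any are missing.
.get_pssms <- function(data) {
  if (!"pssm" %in% names(data)) {
    stop("profile encoders need a 'pssm' list-column; see attach_pssms()",
         call. = FALSE)
  }
  missing <- vapply(data$pssm, is.null, logical(1))
  if (any(missing)) {
    stop("missing PSSM for record(s): ",
         paste(utils::head(data$id[missing], 5), collapse = ", "),
         call. = FALSE)
  }
  data$pssm
}
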