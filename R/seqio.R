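# Reading, validating and summarizing labeled peptide datasets.
#
# A peptide dataset is a tibble with columns `id`, `sequence` and
# (once labeled) `label` (1 = anticancer peptide, 0 = non-ACP).
# Sequences are stored as plain upper-case strings; formula
# transcriptions throughout the package use 1-based positions
# R1..RL while R's string indexing is used internally.

#' Read peptide sequences from a FASTA file
#'
#' Reads plain or multi-line FASTA into a tibble, preserving entry
#' order. Sequences are upper-cased and whitespace-stripped but NOT
#' validated against the amino-acid alphabet: records with non-natural
#' characters survive so that [validate_peptides()] can report them.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (full header line) and
#'   `sequence`. An empty file yields an empty tibble.
#' @seealso [write_fasta()], [validate_peptides()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- names(x)
  if (anyDuplicated(ids)) {
    message("note: duplicate FASTA ids in '", path, "' (",
            sum(duplicated(ids)), " repeats) - kept as-is")
  }
  tibble::tibble(
    id = as.character(ids),
    sequence = unname(toupper(gsub("[[:space:]]", "",
                                   as.character(x))))
  )
}

#' Write peptide sequences to a FASTA file
#'
#' @param data A data frame with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  x <- Biostrings::BStringSet(data$sequence)
  names(x) <- data$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Assemble a labeled peptide dataset from positive/negative FASTA files
#'
#' Reads two FASTA files and stacks them with labels 1 (ACP) and 0
#' (non-ACP). Alternatively use [attach_labels()] to join a label table
#' onto a single FASTA.
#'
#' @param positive,negative Paths to the positive- and negative-class
#'   FASTA files.
#' @return A tibble with `id`, `sequence`, `label`.
#' @export
read_peptide_dataset <- function(positive, negative) {
  pos <- dplyr::mutate(read_fasta(positive), label = 1L)
  neg <- dplyr::mutate(read_fasta(negative), label = 0L)
  dplyr::bind_rows(pos, neg)
}

#' Attach class labels from a two-column table
#'
#' Joins labels onto a peptide tibble by `id`. The label source may be
#' a data frame or the path of a TSV with columns `id` and `label`
#' (0/1).
#'
#' @param data Peptide tibble from [read_fasta()].
#' @param labels Data frame or TSV path with columns `id`, `label`.
#' @return `data` with an integer `label` column.
#' @export
attach_labels <- function(data, labels) {
  if (is.character(labels) && length(labels) == 1) {
    labels <- utils::read.delim(labels, header = TRUE,
                                stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "label") %in% names(labels)))
  labels$label <- as.integer(labels$label)
  if (!all(labels$label %in% c(0L, 1L))) {
    stop("labels must be 0 (non-ACP) or 1 (ACP)", call. = FALSE)
  }
  out <- dplyr::left_join(data, labels[c("id", "label")], by = "id")
  if (anyNA(out$label)) {
    stop(sum(is.na(out$label)), " record(s) have no label", call. = FALSE)
  }
  out
}

#' Remove peptides containing non-natural amino acids
#'
#' Drops every record whose sequence contains any character outside the
#' 20-letter alphabet (ambiguity codes B/J/O/U/X/Z, digits, gaps, ...)
#' together with its label, mirroring the benchmark-curation rule that
#' sequences not made of the 20 natural amino acids are eliminated.
#' Nothing is dropped silently: the removed records are returned as a
#' rejection report in the `"rejected"` attribute.
#'
#' @param data Peptide tibble with `id` and `sequence` (a `label`
#'   column, if present, is filtered in parallel).
#' @param quiet Suppress the rejection message.
#' @return The surviving rows, with attribute `"rejected"`: a tibble of
#'   the removed rows plus an `invalid_chars` column listing each
#'   record's offending characters. See [peptide_rejects()].
#' @export
#' @examples
#' d <- tibble::tibble(id = c("a", "b"), sequence = c("ACDK", "AXDK"),
#'                     label = c(1L, 0L))
#' ok <- validate_peptides(d, quiet = TRUE)
#' peptide_rejects(ok)
validate_peptides <- function(data, quiet = FALSE) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  data$sequence <- toupper(data$sequence)
  bad_chars <- vapply(data$sequence, function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    paste(sort(setdiff(ch, .AA)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ok <- nzchar(data$sequence) & !nzchar(bad_chars)
  rejected <- data[!ok, , drop = FALSE]
  rejected$invalid_chars <- ifelse(nzchar(rejected$sequence),
                                   bad_chars[!ok], "<empty>")
  out <- data[ok, , drop = FALSE]
  if (!quiet && nrow(rejected) > 0) {
    message("removed ", nrow(rejected),
            " sequence(s) with non-natural amino acids: ",
            paste(utils::head(rejected$id, 5), collapse = ", "),
            if (nrow(rejected) > 5) ", ..." else "")
  }
  attr(out, "rejected") <- tibble::as_tibble(rejected)
  out
}

#' Rejection report of the last validation
#'
#' @param data Output of [validate_peptides()].
#' @return Tibble of removed records with their offending characters.
#' @export
peptide_rejects <- function(data) {
  rej <- attr(data, "rejected")
  if (is.null(rej)) {
    tibble::tibble(id = character(), sequence = character(),
                   invalid_chars = character())
  } else {
    rej
  }
}

#' Summarize a labeled peptide dataset
#'
#' Per-class residue composition, length distribution, and the fraction
#' of sequences in the 5-50 length band typical of bioactive peptides.
#'
#' @param data Labeled peptide tibble (`sequence`, `label`).
#' @param band Length band to report coverage of (default `c(5, 50)`).
#' @return An object of class `peptide_summary`: list of tibbles
#'   `composition` (label, residue, count), `lengths` (label, length,
#'   n) and `band` (label, n, fraction_in_band).
#' @export
summarize_peptides <- function(data, band = c(5L, 50L)) {
  stopifnot(all(c("sequence", "label") %in% names(data)))
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  codes <- .encode_sequences(data$sequence)
  comp <- dplyr::bind_rows(lapply(split(codes, data$label), function(cl) {
    counts <- tabulate(unlist(cl), nbins = 20L)
    tibble::tibble(residue = .AA, count = counts)
  }), .id = "label")
  comp$label <- as.integer(comp$label)
  lens <- tibble::tibble(label = data$label,
                         length = nchar(data$sequence))
  len_tab <- dplyr::count(lens, .data$label, .data$length)
  band_tab <- dplyr::summarise(
    dplyr::group_by(lens, .data$label),
    n = dplyr::n(),
    fraction_in_band = mean(.data$length >= band[1] &
                              .data$length <= band[2]),
    .groups = "drop"
  )
  structure(
    list(composition = tibble::as_tibble(comp), lengths = len_tab,
         band = band_tab, band_limits = band),
    class = "peptide_summary"
  )
}

#' @export
print.peptide_summary <- function(x, ...) {
  cat("Peptide dataset summary\n")
  for (i in seq_len(nrow(x$band))) {
    cat(sprintf("  class %d: n = %d, %.1f%% of lengths in [%d, %d]\n",
                x$band$label[i], x$band$n[i],
                100 * x$band$fraction_in_band[i],
                x$band_limits[1], x$band_limits[2]))
  }
  top <- dplyr::slice_max(dplyr::group_by(x$composition, .data$label),
                          .data$count, n = 3, with_ties = FALSE)
  cat("  most frequent residues per class:\n")
  for (lb in unique(top$label)) {
    sub <- top[top$label == lb, ]
    cat(sprintf("    class %d: %s\n", lb,
                paste(sub$residue, collapse = " ")))
  }
  invisible(x)
}

# Map sequences to lists of integer codes 1..20 (lexicographic
# alphabet); errors on the first non-natural character.
.encode_sequences <- function(sequences) {
  lapply(strsplit(toupper(sequences), ""), function(ch) {
    codes <- match(ch, .AA)
    if (anyNA(codes)) {
      stop("sequence contains non-natural amino acid(s): ",
           paste(unique(ch[is.na(codes)]), collapse = ""),
           call. = FALSE)
    }
    codes
  })
}

# Shared front door for the encode_* functions: accept a tibble with a
# `sequence` column or a bare character vector.
.as_peptide_tbl <- function(data) {
  if (is.character(data)) {
    data <- tibble::tibble(
      id = if (is.null(names(data))) paste0("seq", seq_along(data))
           else names(data),
      sequence = unname(data)
    )
  }
  stopifnot(is.data.frame(data), "sequence" %in% names(data))
  if (!"id" %in% names(data)) {
    data <- dplyr::mutate(data, id = paste0("seq", dplyr::row_number()))
  }
  tibble::as_tibble(data)
}

# Bind a feature matrix onto the id column as a wide tibble.
.feature_tbl <- function(data, mat) {
  dplyr::bind_cols(tibble::tibble(id = data$id),
                   tibble::as_tibble(mat, .name_repair = "minimal"))
}
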