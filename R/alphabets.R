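# Reduced amino-acid alphabets for the distance-pair encoder.

# Bundled clusterings. cp13/cp14 follow the hydrophobicity-based
# groupings used with distance-pair descriptors in protein feature
# toolkits; cp19 keeps all residues apart except the near-synonymous
# I/L pair; cp20 is the identity alphabet.
.reduced_groups <- list(
  cp13 = c("MF", "IL", "V", "A", "C", "WYQHP", "G", "T", "S", "N",
           "RK", "D", "E"),
  cp14 = c("IMV", "L", "F", "WY", "G", "P", "C", "A", "S", "T", "N",
           "HRKQ", "E", "D"),
  cp19 = c("IL", "A", "C", "D", "E", "F", "G", "H", "K", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y"),
  cp20 = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
           "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

#' Reduced amino-acid alphabets
#'
#' Returns one of the bundled residue clusterings used by
#' [encode_distance_pair()], or builds one from explicit groups. A
#' reduced alphabet maps each of the 20 amino acids to one of `m`
#' cluster ids (1..m, in the order the groups are given).
#'
#' Bundled alphabets: `"cp13"`, `"cp14"`, `"cp19"` (physicochemical
#' clusterings of decreasing coarseness) and `"cp20"` (identity, no
#' reduction).
#'
#' @param name Name of a bundled alphabet, or a character vector of
#'   residue groups (e.g. `c("ILV", "FWY", ...)`) that together cover
#'   all 20 letters exactly once.
#' @return An object of class `reduced_alphabet`: a list with `name`,
#'   `mapping` (named integer vector over the 20 letters), `m` (number
#'   of clusters) and `groups`.
#' @export
#' @examples
#' reduced_alphabet("cp14")
#' reduced_alphabet(c("ILVMFWYCA", "GTSNQDEHRKP"))  # 2-cluster split
reduced_alphabet <- function(name = "cp14") {
  if (length(name) == 1 && name %in% names(.reduced_groups)) {
    groups <- .reduced_groups[[name]]
    label <- name
  } else {
    groups <- as.character(name)
    label <- "custom"
  }
  letters20 <- unlist(strsplit(groups, ""))
  if (length(letters20) != 20L || !setequal(letters20, .AA) ||
      anyDuplicated(letters20)) {
    stop("reduced alphabet groups must partition the 20 amino acids",
         call. = FALSE)
  }
  mapping <- integer(20)
  names(mapping) <- .AA
  for (g in seq_along(groups)) {
    mapping[strsplit(groups[g], "")[[1]]] <- g
  }
  structure(
    list(name = label, mapping = mapping, m = length(groups),
         groups = groups),
    class = "reduced_alphabet"
  )
}

#' @export
print.reduced_alphabet <- function(x, ...) {
  cat("Reduced amino-acid alphabet '", x$name, "' (", x$m,
      " clusters)\n", sep = "")
  cat(paste0("  ", seq_along(x$groups), ": ", x$groups, collapse = "\n"),
      "\n", sep = "")
  invisible(x)
}
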