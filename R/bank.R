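# The encoder bank: the ordered set of feature encodings whose
# first-layer model outputs form the meta-feature vector.

# registry: encoder id -> (family, needs profile, function of
# (data, params) returning a feature tibble)
.encoder_registry <- function() {
  list(
    kmer = list(family = "composition", profile = FALSE,
                fn = function(data, p) rlang::exec(encode_kmer, data, !!!p)),
    dr = list(family = "composition", profile = FALSE,
              fn = function(data, p) rlang::exec(encode_dr, data, !!!p)),
    distance_pair = list(family = "composition", profile = FALSE,
                         fn = function(data, p)
                           rlang::exec(encode_distance_pair, data, !!!p)),
    ac = list(family = "autocorrelation", profile = FALSE,
              fn = function(data, p)
                rlang::exec(encode_autocovariance, data, mode = "ac", !!!p)),
    cc = list(family = "autocorrelation", profile = FALSE,
              fn = function(data, p)
                rlang::exec(encode_autocovariance, data, mode = "cc", !!!p)),
    acc = list(family = "autocorrelation", profile = FALSE,
               fn = function(data, p)
                 rlang::exec(encode_autocovariance, data, mode = "acc", !!!p)),
    pdt = list(family = "autocorrelation", profile = FALSE,
               fn = function(data, p) rlang::exec(encode_pdt, data, !!!p)),
    pc_pseaac = list(family = "pseaac", profile = FALSE,
                     fn = function(data, p)
                       rlang::exec(encode_pc_pseaac, data, !!!p)),
    sc_pseaac = list(family = "pseaac", profile = FALSE,
                     fn = function(data, p)
                       rlang::exec(encode_sc_pseaac, data, !!!p)),
    pc_pseaac_general = list(family = "pseaac", profile = FALSE,
                             fn = function(data, p)
                               rlang::exec(encode_pseaac_general, data,
                                           mode = "parallel", !!!p)),
    sc_pseaac_general = list(family = "pseaac", profile = FALSE,
                             fn = function(data, p)
                               rlang::exec(encode_pseaac_general, data,
                                           mode = "series", !!!p)),
    top_ngram = list(family = "profile", profile = TRUE,
                     fn = function(data, p)
                       rlang::exec(encode_top_ngram, data, !!!p)),
    pdt_profile = list(family = "profile", profile = TRUE,
                       fn = function(data, p)
                         rlang::exec(encode_pdt_profile, data, !!!p)),
    dt = list(family = "profile", profile = TRUE,
              fn = function(data, p) rlang::exec(encode_dt, data, !!!p)),
    ac_pssm = list(family = "profile", profile = TRUE,
                   fn = function(data, p)
                     rlang::exec(encode_pssm_covariance, data,
                                 mode = "ac", !!!p)),
    cc_pssm = list(family = "profile", profile = TRUE,
                   fn = function(data, p)
                     rlang::exec(encode_pssm_covariance, data,
                                 mode = "cc", !!!p)),
    acc_pssm = list(family = "profile", profile = TRUE,
                    fn = function(data, p)
                      rlang::exec(encode_pssm_covariance, data,
                                  mode = "acc", !!!p)),
    pssm_dt = list(family = "profile", profile = TRUE,
                   fn = function(data, p)
                     rlang::exec(encode_pssm_dt, data, !!!p)),
    pssm_rt = list(family = "profile", profile = TRUE,
                   fn = function(data, p)
                     rlang::exec(encode_pssm_rt, data, !!!p))
  )
}

# default parameters per encoder, sized for 5-50-residue peptides
.default_params <- list(
  kmer = list(k = 2L),
  dr = list(dmax = 3L),
  distance_pair = list(dmax = 3L, alphabet = "cp14"),
  ac = list(dmax = 2L), cc = list(dmax = 2L), acc = list(dmax = 2L),
  pdt = list(dmax = 2L),
  pc_pseaac = list(lambda = 4L, w = 0.05),
  sc_pseaac = list(lambda = 4L, w = 0.05),
  pc_pseaac_general = list(lambda = 4L, w = 0.05),
  sc_pseaac_general = list(lambda = 4L, w = 0.05),
  top_ngram = list(n = 1L), pdt_profile = list(dmax = 2L),
  dt = list(n = 1L, dmax = 2L),
  ac_pssm = list(dmax = 2L), cc_pssm = list(dmax = 2L),
  acc_pssm = list(dmax = 2L), pssm_dt = list(dmax = 2L),
  pssm_rt = list(dmax = 2L, threshold = 0)
)

# The general PseAAC variants default to the full 8-index panel so they
# differ from the classical three/two-property encoders.
.general_pseaac_properties <- function() aa_index_panel()

#' Build an encoder bank
#'
#' An encoder bank is the ordered list of feature encodings feeding the
#' first layer of the stacked model; meta-feature column m corresponds
#' to encoder m. The default bank holds all 19 encoders -- 3
#' composition, 4 autocorrelation, 4 pseudo amino acid composition and
#' 8 profile-based -- or the 11 sequence-only encoders when PSSM
#' profiles are unavailable.
#'
#' @param encoders Character vector of encoder ids (must be unique), or
#'   a named list `id = list(param = value, ...)` overriding defaults.
#'   `NULL` selects the default bank.
#' @param profiles Are PSSM profiles available? When `FALSE` the 8
#'   profile encoders are dropped from the default bank with a warning.
#' @return An object of class `encoder_bank`: tibble with columns
#'   `encoder`, `family`, `params` (list-column); attribute `k`.
#' @export
#' @examples
#' encoder_bank()                      # 19 encoders
#' encoder_bank(profiles = FALSE)      # 11 sequence-only encoders
#' encoder_bank(list(kmer = list(k = 3), dr = list(dmax = 2)))
encoder_bank <- function(encoders = NULL, profiles = TRUE) {
  reg <- .encoder_registry()
  if (is.null(encoders)) {
    ids <- names(reg)
    if (!profiles) {
      ids <- ids[!vapply(reg, `[[`, logical(1), "profile")]
      warning("PSSM profiles unavailable: dropping the 8 profile ",
              "encoders (k = ", length(ids), ")", call. = FALSE)
    }
    overrides <- stats::setNames(vector("list", length(ids)), ids)
  } else if (is.character(encoders)) {
    ids <- encoders
    overrides <- stats::setNames(vector("list", length(ids)), ids)
  } else {
    stopifnot(is.list(encoders), !is.null(names(encoders)))
    ids <- names(encoders)
    overrides <- encoders
  }
  if (anyDuplicated(ids)) {
    stop("duplicate encoder id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(ids, names(reg))
  if (length(unknown) > 0) {
    stop("unknown encoder id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- lapply(ids, function(id) {
    p <- utils::modifyList(.default_params[[id]],
                           overrides[[id]] %||% list())
    if (id %in% c("pc_pseaac_general", "sc_pseaac_general") &&
        is.null(p$properties)) {
      p$properties <- .general_pseaac_properties()
    }
    p
  })
  bank <- tibble::tibble(
    encoder = ids,
    family = vapply(reg[ids], `[[`, character(1), "family"),
    params = params
  )
  structure(bank, k = nrow(bank), class = c("encoder_bank",
                                            class(bank)))
}

#' @export
print.encoder_bank <- function(x, ...) {
  fam <- table(factor(x$family, levels = c("composition",
                                           "autocorrelation", "pseaac",
                                           "profile")))
  cat("Encoder bank: k =", nrow(x), "encoders (",
      paste(fam, collapse = "/"), "by family )\n")
  cat(" ", paste(x$encoder, collapse = ", "), "\n")
  invisible(x)
}

#' Encode a dataset with every encoder in a bank
#'
#' @param data Peptide tibble (with a `pssm` list-column if the bank
#'   contains profile encoders).
#' @param bank An [encoder_bank()].
#' @return Named list of numeric feature matrices, one per encoder, in
#'   bank order.
#' @export
encode_with_bank <- function(data, bank = encoder_bank()) {
  data <- .as_peptide_tbl(data)
  reg <- .encoder_registry()
  out <- lapply(seq_len(nrow(bank)), function(i) {
    id <- bank$encoder[i]
    tbl <- reg[[id]]$fn(data, bank$params[[i]])
    as.matrix(tbl[, -1, drop = FALSE])
  })
  names(out) <- bank$encoder
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
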