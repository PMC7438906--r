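# Independent brute-force transcriptions of every encoder formula,
# written against plain character vectors so they share no code with
# the package internals, plus small fixture generators.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptides <- function(n, lmin = 5, lmax = 50, seed = 1) {
  set.seed(seed)
  lens <- lmin - 1 + sample.int(lmax - lmin + 1, n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1))
}

# population-standardized copy of a raw 20-value index
o_standardize <- function(raw) {
  v <- raw[AA20]
  m <- sum(v) / 20
  s <- sqrt(sum((v - m)^2) / 20)
  (v - m) / s
}

# raw built-in index values straight from the package accessor
raw_panel <- function(names = NULL) {
  pepstack::aa_index_panel(names, standardized = FALSE)
}

# named k-mer counts of a sequence via literal sliding windows
o_kmer <- function(seq, k, normalize = TRUE) {
  L <- nchar(seq)
  counts <- list()
  for (i in seq_len(L - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    counts[[w]] <- (counts[[w]] %||0% 0) + 1
  }
  function(word) {
    v <- counts[[word]] %||0% 0
    if (normalize) v / (L - k + 1) else v
  }
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

# named DR block counts: lookup("d0_A"), lookup("d2_KR"), ...
o_dr_lookup <- function(seq, dmax, normalize = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  counts <- list()
  for (a in ch) {
    key <- paste0("d0_", a)
    counts[[key]] <- (counts[[key]] %||0% 0) + 1
  }
  for (d in seq_len(dmax)) {
    if (L - d < 1) next
    for (i in seq_len(L - d)) {
      key <- paste0("d", d, "_", ch[i], ch[i + d])
      counts[[key]] <- (counts[[key]] %||0% 0) + 1
    }
  }
  totals <- c(d0 = L,
              stats::setNames(pmax(L - seq_len(max(dmax, 1)), 0),
                              paste0("d", seq_len(max(dmax, 1)))))
  function(name) {
    v <- counts[[name]] %||0% 0
    if (!normalize) return(v)
    block <- sub("_.*", "", name)
    tot <- totals[[block]]
    if (tot > 0) v / tot else 0
  }
}

# auto covariance by literal double loop on standardized signal
o_ac <- function(seq, std_index, d) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  v <- std_index[ch]
  vbar <- sum(v) / L
  tot <- 0
  for (i in seq_len(L - d)) {
    tot <- tot + (v[i] - vbar) * (v[i + d] - vbar)
  }
  unname(tot / (L - d))
}

o_cc <- function(seq, std_u, std_v, d) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  u <- std_u[ch]; v <- std_v[ch]
  ubar <- sum(u) / L; vbar <- sum(v) / L
  tot <- 0
  for (i in seq_len(L - d)) {
    tot <- tot + (u[i] - ubar) * (v[i + d] - vbar)
  }
  unname(tot / (L - d))
}

o_pdt <- function(seq, std_index, d) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  v <- std_index[ch]
  tot <- 0
  for (i in seq_len(L - d)) tot <- tot + (v[i] - v[i + d])^2
  unname(tot / (L - d))
}

# parallel correlation tiers over a list of standardized properties
o_theta_parallel <- function(seq, lambda, std_props) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  vapply(seq_len(lambda), function(j) {
    tot <- 0
    for (i in seq_len(L - j)) {
      tot <- tot + mean(vapply(std_props, function(p) {
        unname((p[ch[i]] - p[ch[i + j]])^2)
      }, numeric(1)))
    }
    tot / (L - j)
  }, numeric(1))
}

# series tiers, lag-major over properties
o_theta_series <- function(seq, lambda, std_props) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (j in seq_len(lambda)) {
    for (p in std_props) {
      tot <- 0
      for (i in seq_len(L - j)) tot <- tot + p[ch[i]] * p[ch[i + j]]
      out <- c(out, unname(tot) / (L - j))
    }
  }
  out
}

o_pseaac <- function(seq, lambda, w, theta) {
  ch <- strsplit(seq, "")[[1]]
  f <- vapply(AA20, function(a) sum(ch == a), numeric(1)) / length(ch)
  denom <- sum(f) + w * sum(theta)
  c(f, w * theta) / denom
}

# random row-stochastic profile and helpers for profile-encoder oracles
random_profile <- function(L, seed = 1) {
  set.seed(seed)
  f <- matrix(stats::rexp(L * 20), L, 20)
  f <- f / rowSums(f)
  colnames(f) <- AA20
  f
}

o_top1 <- function(freq) {
  apply(freq, 1, function(row) AA20[which.max(row)])  # which.max is
}                                                     # first-tie = alphabetical

o_pssm_dt <- function(freq, a, b, d) {
  L <- nrow(freq)
  tot <- 0
  for (i in seq_len(L - d)) tot <- tot + freq[i, a] * freq[i + d, b]
  unname(tot / (L - d))
}

o_pssm_cov_ac <- function(freq, j, d) {
  L <- nrow(freq)
  pj <- freq[, j]
  pbar <- mean(pj)
  tot <- 0
  for (i in seq_len(L - d)) tot <- tot + (pj[i] - pbar) * (pj[i + d] - pbar)
  unname(tot / (L - d))
}

o_pssm_cov_cc <- function(freq, j1, j2, d) {
  L <- nrow(freq)
  p1 <- freq[, j1]; p2 <- freq[, j2]
  b1 <- mean(p1); b2 <- mean(p2)
  tot <- 0
  for (i in seq_len(L - d)) tot <- tot + (p1[i] - b1) * (p2[i + d] - b2)
  unname(tot / (L - d))
}

o_pdt_profile <- function(freq, d) {
  L <- nrow(freq)
  tot <- 0
  for (i in seq_len(L - d)) {
    tot <- tot + sum((freq[i, ] - freq[i + d, ])^2) / 20
  }
  unname(tot / (L - d))
}

o_pssm_rt <- function(scores, a, b, d, thr = 0) {
  L <- nrow(scores)
  tot <- 0
  for (i in seq_len(L - d)) {
    tot <- tot + (scores[i, a] > thr) * (scores[i + d, b] > thr)
  }
  unname(tot / (L - d))
}

# exactly one-hot frequency profile of a sequence; the derived scores
# are strongly positive at the true residue only, so binarization at 0
# also recovers the residue indicator
one_hot_pssm <- function(seq, id = "p") {
  ch <- strsplit(seq, "")[[1]]
  f <- matrix(0, length(ch), 20, dimnames = list(NULL, AA20))
  for (i in seq_along(ch)) f[i, ch[i]] <- 1
  pepstack::pssm(f, id = id, scores_are = "frequencies")
}

expect_feature_equal <- function(tbl, expected, tol = 1e-10) {
  vals <- as.numeric(tbl[1, -1])
  names(vals) <- names(tbl)[-1]
  expect_equal(vals[names(expected)], expected, tolerance = tol)
}
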