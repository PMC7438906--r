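std_h1 <- function() o_standardize(raw_panel("hydrophobicity")[[1]])
std_h2 <- function() o_standardize(raw_panel("hydrophilicity")[[1]])
std_m <- function() o_standardize(raw_panel("side_chain_mass")[[1]])

test_that("correlation factors match brute-force pair loops", {
  # homopolymer: parallel tiers all zero
  expect_equal(correlation_factors("KKKKKK", lambda = 3), rep(0, 3))

  # boundary: L = lambda + 1 leaves exactly one pair in the top tier
  s <- "ACDEF"
  th <- correlation_factors(s, lambda = 4)
  props <- list(std_h1(), std_h2(), std_m())
  expect_equal(th, o_theta_parallel(s, 4, props), tolerance = 1e-12)
  expect_equal(th[4],
               mean(vapply(props, function(p) (p["A"] - p["F"])^2,
                           numeric(1))),
               tolerance = 1e-12)

  # series: two-residue sequence gives plain products
  th2 <- correlation_factors("AW", lambda = 1, mode = "series")
  expect_equal(th2, c(std_h1()[["A"]] * std_h1()[["W"]],
                      std_h2()[["A"]] * std_h2()[["W"]]),
               tolerance = 1e-12)

  for (seq in random_peptides(8, 15, 15, seed = 37)) {
    expect_equal(correlation_factors(seq, lambda = 4),
                 o_theta_parallel(seq, 4, props), tolerance = 1e-10)
    expect_equal(correlation_factors(seq, lambda = 4, mode = "series"),
                 o_theta_series(seq, 4, list(std_h1(), std_h2())),
                 tolerance = 1e-10)
  }
  expect_error(correlation_factors("ACD", lambda = 3), "exceed lambda")
})

test_that("PC-PseAAC vectors are normalized compositions plus tiers", {
  # normalization forced by the formula, entries nonnegative
  for (seq in random_peptides(10, 6, 40, seed = 43)) {
    v <- as.numeric(encode_pc_pseaac(seq, lambda = 4, w = 0.05)[1, -1])
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
  }

  # homopolymer reduces to pure composition
  v <- encode_pc_pseaac("KKKKK", lambda = 2, w = 0.05)
  expect_equal(v$f_K, 1)
  expect_equal(sum(as.numeric(v[1, -1])), 1)
  expect_equal(as.numeric(v[1, -1])[-match("K", aa_alphabet())],
               rep(0, 21))

  # independent transcription on random peptides
  props <- list(std_h1(), std_h2(), std_m())
  for (seq in random_peptides(6, 12, 12, seed = 47)) {
    got <- as.numeric(encode_pc_pseaac(seq, lambda = 3, w = 0.05)[1, -1])
    theta <- o_theta_parallel(seq, 3, props)
    expect_equal(got, unname(o_pseaac(seq, 3, 0.05, theta)),
                 tolerance = 1e-10)
  }
})

test_that("SC-PseAAC uses 2*lambda series tiers", {
  expect_equal(ncol(encode_sc_pseaac("ACDEFGHIK", lambda = 4)) - 1, 28)

  sprops <- list(std_h1(), std_h2())
  for (seq in random_peptides(6, 14, 14, seed = 53)) {
    got <- as.numeric(encode_sc_pseaac(seq, lambda = 2, w = 0.05)[1, -1])
    theta <- o_theta_series(seq, 2, sprops)
    expect_equal(got, unname(o_pseaac(seq, 2, 0.05, theta)),
                 tolerance = 1e-10)
  }
})

test_that("general PseAAC reduces to the classical encoders and extends", {
  s <- random_peptides(1, 20, 20, seed = 59)
  # default parallel property set: identical to PC-PseAAC
  expect_equal(encode_pseaac_general(s, lambda = 4, mode = "parallel"),
               encode_pc_pseaac(s, lambda = 4),
               ignore_attr = TRUE)

  # one property, series, lambda 1: dim 21
  g <- encode_pseaac_general(s, lambda = 1, mode = "series",
                             properties = raw_panel("polarity"))
  expect_equal(ncol(g) - 1, 21)

  # five custom properties against the brute-force oracle
  props5 <- raw_panel(c("hydrophobicity", "polarity", "flexibility",
                        "net_charge", "side_chain_mass"))
  std5 <- lapply(props5, o_standardize)
  for (seq in random_peptides(5, 10, 25, seed = 61)) {
    gotp <- as.numeric(
      encode_pseaac_general(seq, lambda = 2, w = 0.05,
                            properties = props5,
                            mode = "parallel")[1, -1])
    expect_equal(gotp,
                 unname(o_pseaac(seq, 2, 0.05,
                                 o_theta_parallel(seq, 2, std5))),
                 tolerance = 1e-10)
    gots <- as.numeric(
      encode_pseaac_general(seq, lambda = 2, w = 0.05,
                            properties = props5, mode = "series")[1, -1])
    expect_equal(gots,
                 unname(o_pseaac(seq, 2, 0.05,
                                 o_theta_series(seq, 2, std5))),
                 tolerance = 1e-10)
    expect_length(gots, 20 + 2 * 5)
  }
})

test_that("dimension contracts hold for lambda 1..4", {
  s <- random_peptides(1, 30, 30, seed = 67)
  for (lam in 1:4) {
    expect_equal(ncol(encode_pc_pseaac(s, lambda = lam)) - 1, 20 + lam)
    expect_equal(ncol(encode_sc_pseaac(s, lambda = lam)) - 1,
                 20 + 2 * lam)
  }
})

test_that("the w -> 0 limit recovers plain composition", {
  s <- random_peptides(1, 25, 25, seed = 71)
  comp <- as.numeric(encode_kmer(s, k = 1, normalize = TRUE)[1, -1])
  for (enc in list(encode_pc_pseaac, encode_sc_pseaac)) {
    v <- as.numeric(enc(s, lambda = 4, w = 1e-9)[1, -1])
    expect_equal(v[1:20], comp, tolerance = 1e-6)
    expect_true(all(abs(v[-(1:20)]) < 1e-6))
  }
})

test_that("short sequences and degenerate normalizers raise errors", {
  expect_error(encode_pc_pseaac("ACDE", lambda = 4), "exceed lambda")
  # strongly negative series products can null the normalizer at w = 1:
  # alternating R/I gives large negative lag-1 hydrophobicity products
  neg <- paste(rep(c("R", "I"), 8), collapse = "")
  expect_error(encode_sc_pseaac(neg, lambda = 1, w = 1),
               "degenerate PseAAC")
})
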