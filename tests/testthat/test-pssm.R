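test_that("PSSM files round-trip through the PSI-BLAST ASCII layout", {
  f <- withr::local_tempfile(fileext = ".pssm")
  seq <- "KLWYR"
  p <- simulate_pssm(seq, sharpness = 5, id = "p1", seed = 3)
  write_pssm(p, f, sequence = seq)
  q <- read_pssm(f)
  expect_equal(q$scores, p$scores, tolerance = 1e-5)
  expect_equal(q$frequencies, p$frequencies, tolerance = 1e-6)

  # frequencies of any parsed file are row-stochastic
  expect_equal(rowSums(q$frequencies), rep(1, 5), tolerance = 1e-9)
  expect_true(all(q$frequencies >= 0 & q$frequencies <= 1))

  # a row with 19 score columns is a format error naming the line
  lines <- readLines(f)
  bad <- grep("^   2 ", lines)
  fields <- strsplit(trimws(lines[bad]), "[[:space:]]+")[[1]]
  lines[bad] <- paste(fields[-length(fields)], collapse = " ")
  writeLines(lines, f)
  expect_error(read_pssm(f), "line 5")

  expect_error(read_pssm(withr::local_tempfile()), "not found")
})

test_that("pssm objects validate shape and derive frequencies", {
  sc <- matrix(stats::rnorm(80), 4, 20, dimnames = list(NULL, AA20))
  p <- pssm(sc, id = "x")
  expect_equal(rowSums(p$frequencies), rep(1, 4), tolerance = 1e-12)
  # logistic transform then renormalization, checked cell-wise
  f_raw <- 1 / (1 + 2^(-sc))
  expect_equal(unname(p$frequencies), unname(f_raw / rowSums(f_raw)))
  expect_error(pssm(sc[, 1:19]), "20 columns")
})

test_that("Top-n-gram encoding tallies per-position dominant residues", {
  # one-hot profile: Top-1-grams reproduce the sequence, counts are
  # plain composition
  seq <- random_peptides(1, 15, 15, seed = 73)
  oh <- one_hot_pssm(seq)
  v <- encode_top_ngram(list(oh), n = 1, normalize = FALSE)
  expect_equal(unname(as.numeric(v[1, -1])),
               unname(as.numeric(encode_kmer(seq, k = 1,
                                             normalize = FALSE)[1, -1])))

  # duplicated argmax counts twice
  f <- random_profile(4, seed = 5)
  f[2, ] <- f[1, ]
  p <- pssm(f, scores_are = "frequencies")
  top <- o_top1(p$frequencies)
  v2 <- encode_top_ngram(list(p), n = 1, normalize = FALSE)
  expect_gte(v2[[top[1]]], 2)

  # random profiles match the per-row sort-and-tally oracle
  for (s in 1:4) {
    p <- pssm(random_profile(12, seed = s), scores_are = "frequencies")
    grams <- o_top1(p$frequencies)
    got <- encode_top_ngram(list(p), n = 1, normalize = FALSE)
    for (a in AA20) {
      expect_equal(got[[a]], sum(grams == a))
    }
  }
})

test_that("distance Top-n-grams reduce to DR pair blocks on one-hot input", {
  seq <- random_peptides(1, 20, 20, seed = 79)
  oh <- one_hot_pssm(seq)
  dt <- encode_dt(list(oh), n = 1, dmax = 2, normalize = FALSE)
  dr <- encode_dr(seq, dmax = 2, normalize = FALSE)
  shared <- setdiff(intersect(names(dt), names(dr)), "id")
  expect_equal(length(shared), 800)  # the two d >= 1 pair blocks
  expect_equal(dt[shared], dr[shared])

  p <- pssm(random_profile(10, seed = 7), scores_are = "frequencies")
  expect_error(encode_dt(list(p), n = 1, dmax = 10), "longer than dmax")

  # random profiles: pair counts match a loop over converted grams
  grams <- o_top1(p$frequencies)
  got <- encode_dt(list(p), n = 1, dmax = 2, normalize = FALSE)
  for (d in 1:2) {
    for (i in seq_len(10 - d)) {
      col <- paste0("d", d, "_", grams[i], grams[i + d])
      cnt <- 0
      for (j in seq_len(10 - d)) {
        cnt <- cnt + (grams[j] == grams[i] && grams[j + d] == grams[i + d])
      }
      expect_equal(got[[col]], cnt)
    }
  }
})

test_that("profile PDT measures squared row differences per lag", {
  # identical rows: all zero
  f <- matrix(1 / 20, 6, 20, dimnames = list(NULL, AA20))
  p <- pssm(f, scores_are = "frequencies")
  expect_equal(unname(as.numeric(
    encode_pdt_profile(list(p), dmax = 2)[1, -1])), c(0, 0))

  # L = 2 one-hot rows on different letters: PDTp(1) = 2/20
  f2 <- matrix(0, 2, 20, dimnames = list(NULL, AA20))
  f2[1, "A"] <- 1; f2[2, "K"] <- 1
  p2 <- pssm(f2, scores_are = "frequencies")
  expect_equal(encode_pdt_profile(list(p2), dmax = 1)$PDTp_d1, 0.1)

  for (s in 1:3) {
    p3 <- pssm(random_profile(14, seed = s), scores_are = "frequencies")
    got <- encode_pdt_profile(list(p3), dmax = 2)
    expect_equal(got$PDTp_d1, o_pdt_profile(p3$frequencies, 1),
                 tolerance = 1e-12)
    expect_equal(got$PDTp_d2, o_pdt_profile(p3$frequencies, 2),
                 tolerance = 1e-12)
  }
})

test_that("profile covariances treat the 20 columns as properties", {
  f <- matrix(1 / 20, 8, 20, dimnames = list(NULL, AA20))
  p <- pssm(f, scores_are = "frequencies")
  expect_true(all(abs(as.numeric(
    encode_pssm_covariance(list(p), dmax = 2, mode = "acc")[1, -1]))
    < 1e-14))

  p2 <- pssm(random_profile(13, seed = 11), scores_are = "frequencies")
  acc <- encode_pssm_covariance(list(p2), dmax = 2, mode = "acc")
  ac <- encode_pssm_covariance(list(p2), dmax = 2, mode = "ac")
  cc <- encode_pssm_covariance(list(p2), dmax = 2, mode = "cc")
  expect_equal(ncol(acc) - 1, 400 * 2)
  expect_equal(ncol(ac) - 1, 20 * 2)
  expect_equal(ncol(cc) - 1, 380 * 2)
  expect_equal(acc[names(ac)], ac)
  expect_equal(acc[names(cc)], cc)

  for (a in c("A", "K", "W")) {
    for (d in 1:2) {
      expect_equal(ac[[paste0("AC_", a, "_d", d)]],
                   o_pssm_cov_ac(p2$frequencies, a, d), tolerance = 1e-12)
    }
  }
  expect_equal(cc$CC_A_K_d1, o_pssm_cov_cc(p2$frequencies, "A", "K", 1),
               tolerance = 1e-12)
  expect_equal(cc$CC_K_A_d2, o_pssm_cov_cc(p2$frequencies, "K", "A", 2),
               tolerance = 1e-12)
})

test_that("PSSM-DT measures soft pair co-occurrence", {
  # one-hot: equals normalized DR pair blocks
  seq <- random_peptides(1, 18, 18, seed = 83)
  oh <- one_hot_pssm(seq)
  got <- encode_pssm_dt(list(oh), dmax = 2)
  dr <- encode_dr(seq, dmax = 2, normalize = TRUE)
  shared <- setdiff(intersect(names(got), names(dr)), "id")
  expect_equal(got[shared], dr[shared], tolerance = 1e-12)

  # uniform rows: every entry 1/400
  f <- matrix(1 / 20, 9, 20, dimnames = list(NULL, AA20))
  pu <- pssm(f, scores_are = "frequencies")
  expect_equal(unname(as.numeric(encode_pssm_dt(list(pu), dmax = 1)[1, -1])),
               rep(1 / 400, 400), tolerance = 1e-12)

  p2 <- pssm(random_profile(11, seed = 13), scores_are = "frequencies")
  got2 <- encode_pssm_dt(list(p2), dmax = 2)
  for (pair in list(c("A", "C"), c("K", "K"), c("W", "R"))) {
    for (d in 1:2) {
      expect_equal(got2[[paste0("d", d, "_", pair[1], pair[2])]],
                   o_pssm_dt(p2$frequencies, pair[1], pair[2], d),
                   tolerance = 1e-12)
    }
  }
})

test_that("PSSM-RT counts co-activated binarized scores", {
  # all scores below threshold: zero vector
  sc <- matrix(-5, 7, 20, dimnames = list(NULL, AA20))
  p <- pssm(sc)
  expect_true(all(as.numeric(encode_pssm_rt(list(p), dmax = 2)[1, -1]) == 0))

  # one-hot-at-threshold profile reduces to normalized DR pair blocks
  seq <- random_peptides(1, 16, 16, seed = 89)
  oh <- one_hot_pssm(seq)
  got <- encode_pssm_rt(list(oh), dmax = 2, threshold = 0)
  dr <- encode_dr(seq, dmax = 2, normalize = TRUE)
  shared <- setdiff(intersect(names(got), names(dr)), "id")
  expect_equal(got[shared], dr[shared], tolerance = 1e-12)

  set.seed(17)
  sc2 <- matrix(stats::rnorm(20 * 12), 12, 20,
                dimnames = list(NULL, AA20))
  p2 <- pssm(sc2)
  got2 <- encode_pssm_rt(list(p2), dmax = 2, threshold = 0)
  for (pair in list(c("A", "D"), c("R", "R"), c("Y", "K"))) {
    for (d in 1:2) {
      expect_equal(got2[[paste0("d", d, "_", pair[1], pair[2])]],
                   o_pssm_rt(p2$scores, pair[1], pair[2], d),
                   tolerance = 1e-12)
    }
  }
})

test_that("profile encoders stay bounded on row-stochastic input", {
  for (s in 1:3) {
    p <- pssm(random_profile(20, seed = s), scores_are = "frequencies")
    dat <- list(p)
    expect_true(all(abs(as.matrix(
      encode_pssm_covariance(dat, dmax = 2, mode = "acc")[, -1])) <= 1))
    expect_true(all(abs(as.matrix(
      encode_pssm_dt(dat, dmax = 2)[, -1])) <= 1))
    expect_true(all(abs(as.matrix(
      encode_pdt_profile(dat, dmax = 2)[, -1])) <= 2))
  }
})

test_that("PSSMs attach to datasets by filename stem or manifest", {
  d <- simulate_peptides(3, 3, length_range = c(8, 12), seed = 5)
  d <- simulate_pssms(d, seed = 6)
  dir <- withr::local_tempdir()
  write_pssm_dir(d, dir)
  d2 <- attach_pssms(d[, c("id", "sequence", "label")], dir = dir)
  for (i in seq_len(nrow(d2))) {
    expect_equal(d2$pssm[[i]]$frequencies, d$pssm[[i]]$frequencies,
                 tolerance = 1e-6)
  }
  man <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(id = d$id, path = file.path(dir, paste0(d$id, ".pssm"))),
    man, sep = "\t", row.names = FALSE, quote = FALSE)
  d3 <- attach_pssms(d[, c("id", "sequence", "label")], manifest = man)
  expect_equal(d3$pssm[[2]]$scores, d2$pssm[[2]]$scores)
})
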