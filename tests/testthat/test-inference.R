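test_that("positional marginals are read off the truncation ladder", {
  # DP4 fraction: parent ratio 1:3.2 (G:M), one-cut readout M only, RE all M
  s4 <- truncation_series(4, list(`0` = nmr_readout(1, 3.2, 0, 1),
                                  `1` = nmr_readout(0, 1, 0, 1)))
  p <- marginals_from_series(s4)
  expect_equal(p, c(1 / 4.2, 0, 0), tolerance = 1e-9)

  # DP2: the single residue letter is both Delta neighbour and reducing end
  s2 <- truncation_series(2, list(`0` = nmr_readout(3.4, 1, 3.4, 1)))
  expect_equal(marginals_from_series(s2), 3.4 / 4.4, tolerance = 1e-9)

  expect_error(marginals_from_series(
    truncation_series(5, list(`0` = nmr_readout(1, 1, 0, 1),
                              `2` = nmr_readout(1, 1, 0, 1)))),
    "missing readouts at cuts 1")
})

test_that("a synthetic noiseless series yields the exact per-position G frequencies", {
  set.seed(19)
  for (i in 1:20) {
    k <- sample(3:6, 1L)
    seqs <- unique(replicate(5, paste0("Δ", paste(sample(c("M", "G"), k, replace = TRUE),
                                                  collapse = ""))))
    fr <- rexp(length(seqs)); fr <- fr / sum(fr)
    m <- oligo_mixture(seqs, fr)
    p <- marginals_from_series(generate_series(m, cv = 0, seed = i))
    truth <- vapply(seq_len(k), function(j) position_g_frequency(m, j), numeric(1L))
    expect_equal(p, truth, tolerance = 1e-12)
  }
})

test_that("the independence joint reproduces the published compositions", {
  # DP5: marginals (3.5/4.5, 1.5/2.5, 0, 0)
  inf <- joint_under_independence(c(3.5 / 4.5, 1.5 / 2.5, 0, 0))
  got <- setNames(table2_percent(inf$mixture$fraction), inf$mixture$sequence)
  expect_equal(got[["ΔGGMM"]], 46.7)
  expect_equal(got[["ΔMGMM"]], 13.3)
  expect_equal(got[["ΔGMMM"]], 31.1)
  expect_equal(got[["ΔMMMM"]], 8.9)

  # DP4: marginals (1/4.2, 0, 0)
  inf4 <- joint_under_independence(c(1 / 4.2, 0, 0))
  got4 <- setNames(table2_percent(inf4$mixture$fraction), inf4$mixture$sequence)
  expect_equal(got4[["ΔMMM"]], 76)
  expect_equal(got4[["ΔGMM"]], 24)

  # degenerate marginals collapse the enumeration
  inf1 <- joint_under_independence(c(1, 1, 1))
  expect_identical(inf1$mixture$sequence, "ΔGGG")
  expect_equal(inf1$mixture$fraction, 1)
})

test_that("small fractions are sequenced from a single readout", {
  got <- sequence_small(nmr_readout(3.4, 1.0, 0, 1), dp = 2)
  pct <- setNames(table2_percent(got$mixture$fraction), got$mixture$sequence)
  expect_equal(pct[["ΔG"]], 77)
  expect_equal(pct[["ΔM"]], 23)

  got3 <- sequence_small(nmr_readout(6.7, 1, 1, 0), dp = 3)
  pct3 <- setNames(table2_percent(got3$mixture$fraction), got3$mixture$sequence)
  expect_equal(pct3[["ΔGG"]], 87)
  expect_equal(pct3[["ΔMG"]], 13)

  got3b <- sequence_small(nmr_readout(1, 1, 0, 1), dp = 3)
  pct3b <- setNames(table2_percent(got3b$mixture$fraction), got3b$mixture$sequence)
  expect_equal(pct3b[["ΔGM"]], 50)
  expect_equal(pct3b[["ΔMM"]], 50)

  expect_error(sequence_small(nmr_readout(1, 1, 1, 1), dp = 5), "dp 2 and 3")
})

test_that("factorizing mixtures round-trip to machine precision", {
  set.seed(91)
  for (i in 1:10) {
    p <- runif(4)
    truth <- joint_under_independence(p, prune_threshold = 0)$mixture
    ser <- generate_series(truth, cv = 0, seed = i)
    rec <- infer_sequences(ser, prune_threshold = 0)$mixture
    truth_o <- truth[order(truth$sequence), ]
    rec_o <- rec[order(rec$sequence), ]
    expect_identical(rec_o$sequence, truth_o$sequence)
    expect_equal(rec_o$fraction, truth_o$fraction, tolerance = 1e-9)
  }
})

test_that("the reconstruction always moment-matches the observed marginals", {
  # even for a non-factorizing (anti-correlated) mixture
  adv <- oligo_mixture(c("ΔGM", "ΔMG"), c(0.5, 0.5))
  ser <- generate_series(adv, cv = 0, seed = 1)
  inf <- infer_sequences(ser)
  expect_equal(nrow(inf$mixture), 4L)
  expect_equal(sort(inf$mixture$fraction), rep(0.25, 4L))
  expect_equal(inf$consistency$residual, 0, tolerance = 1e-12)
  expect_match(inf$consistency$note, "does not identify the joint")
  expect_match(inf$assumption, "independence")
})

test_that("pruning renormalizes to 1 and removes bounded mass", {
  set.seed(55)
  for (i in 1:20) {
    p <- runif(sample(3:6, 1L))
    thr <- 0.005
    inf <- joint_under_independence(p, prune_threshold = thr)
    expect_equal(sum(inf$mixture$fraction), 1, tolerance = 1e-12)
    expect_lte(inf$pruned_mass, thr * 2^length(p))
  }
})

test_that("noisy series recover compositions with small error", {
  truth <- c("ΔGGMM" = 0.467, "ΔMGMM" = 0.133, "ΔGMMM" = 0.311, "ΔMMMM" = 0.089)
  m <- table2_udp5()
  err <- vapply(1:50, function(s) {
    inf <- infer_sequences(generate_series(m, cv = 0.05, seed = s))
    got <- setNames(inf$mixture$fraction, inf$mixture$sequence)
    mean(abs(vapply(names(truth), function(q)
      (if (q %in% names(got)) got[[q]] else 0) - truth[[q]], numeric(1L))))
  }, numeric(1L))
  expect_lt(mean(err), 0.03)
})

test_that("series JSON and inference reports round-trip", {
  s <- truncation_series(5, list(`0` = nmr_readout(3.5, 1, 0, 1),
                                 `1` = nmr_readout(1.5, 1, 0, 1),
                                 `2` = nmr_readout(0, 1, 0, 1)))
  f <- withr::local_tempfile(fileext = ".json")
  write_series_json(s, f)
  s2 <- read_series_json(f)
  expect_equal(s2$dp, s$dp)
  expect_equal(lapply(s2$readouts, unclass), lapply(s$readouts, unclass))

  inf <- infer_sequences(s)
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_inference_report(inf, fj, ft)
  rep <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(sort(rep$sequences), sort(inf$mixture$sequence))
  expect_equal(rep$meta$version, as.character(packageVersion("alginseq")))
  tab <- read.delim(ft, comment.char = "#")
  expect_equal(sum(tab$molar_fraction), 1, tolerance = 1e-9)
})
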