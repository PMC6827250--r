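test_that("the size-activity curve peaks at DP 4 with a 6.5-fold polymer drop", {
  curve <- size_activity_curve(exo_rate_profile(), c(2:10, Inf))
  expect_equal(curve$dp[which.max(curve$relative)], 4)
  expect_equal(curve$relative[curve$dp == 4], 6.5)
  expect_equal(curve$relative[is.infinite(curve$dp)], 1)

  flat <- exo_rate_profile(rates = c(`2` = 1, `10` = 1), polymer = 1)
  expect_equal(size_activity_curve(flat, c(2, 5, 9, Inf))$relative, rep(1, 4))
})

test_that("initial monomer release rates scale as r(dp) between substrate pools", {
  # equimolar chain pools (same number of attackable NREs): over a horizon
  # short enough that the pools are nearly unchanged, the release-rate ratio
  # approaches r(4) / r(polymer) = 6.5
  prof <- exo_rate_profile()
  n_chains <- 60
  pool4 <- c("ΔMMM" = n_chains)
  poolP <- stats::setNames(n_chains, paste(rep("M", 60), collapse = ""))
  rate_of <- function(pool, seeds) {
    mean(vapply(seeds, function(s) {
      traj <- simulate_digest(pool, exo = prof, exo_mU = 100, t_end = 0.1, seed = s)
      sum(final_state(traj)$monomers)
    }, numeric(1L)))
  }
  ratio <- rate_of(pool4, 1:60) / rate_of(poolP, 61:120)
  expect_gt(ratio, 6.5 * 0.7)
  expect_lt(ratio, 6.5 * 1.3)
})

test_that("the endolytic-only arm yields no monomer and combined beats exo-only", {
  pool <- generate_chains(alginate_preset("mixed", length_mean = 30), 4, seed = 11)
  rep <- run_synergy(pool, endo_rate_table(), exo_rate_profile(),
                     endo_mU = 50, exo_mU = 50, duration = 10,
                     replicates = 4, seed = 2)
  expect_equal(rep$yields$yield[rep$yields$arm == "endo_only"], 0)
  expect_gt(rep$ratio, 2)
  # property over seeds: endolytic help never hurts on polymeric substrate
  for (s in 1:20) {
    r <- suppressWarnings(
      run_synergy(pool, endo_rate_table(), exo_rate_profile(),
                  endo_mU = 50, exo_mU = 50, duration = 10,
                  replicates = 1, seed = s))
    comb <- r$per_replicate$combined
    exo <- r$per_replicate$exo_only
    expect_gte(comb, exo)
  }
  expect_error(run_synergy(pool, endo_rate_table(), exo_rate_profile(),
                           endo_mU = 100, exo_mU = 0), "undefined")
})

test_that("yield curves are monotone non-decreasing in time", {
  pool <- generate_chains(alginate_preset("mixed", length_mean = 25), 3, seed = 3)
  traj <- simulate_digest(pool, endo = endo_rate_table(), exo = exo_rate_profile(),
                          endo_mU = 50, exo_mU = 50, t_end = 15, seed = 5,
                          record_times = seq(0.5, 14.5, by = 0.5))
  y <- vapply(traj$states, function(st) st$monomers[["UDP1"]], numeric(1L))
  expect_true(all(diff(y) >= 0))
})

test_that("with a flat profile, per-chain release is zero-order in remaining length", {
  # single long chain, exo only, r constant: release events form a Poisson
  # process of constant rate until absorption, so the mean count at t is
  # rate * t (checked well below absorption)
  flat <- exo_rate_profile(rates = c(`2` = 1, `10` = 1), polymer = 1,
                           polymer_from = 11)
  L <- 400; t <- 10; mU <- 100
  rate <- mU * 0.002 * 1  # activity_scale * r
  counts <- vapply(1:60, function(s) {
    traj <- simulate_digest(stats::setNames(1, paste(rep("M", L), collapse = "")),
                            exo = flat, exo_mU = mU, t_end = t, seed = s)
    sum(final_state(traj)$monomers)
  }, numeric(1L))
  expected <- rate * t
  expect_equal(mean(counts), expected,
               tolerance = 3 * sqrt(expected / 60) / expected)
})

test_that("synergy reports serialize with provenance metadata", {
  pool <- generate_chains(alginate_preset("mixed", length_mean = 30), 3, seed = 1)
  rep <- run_synergy(pool, endo_rate_table(), exo_rate_profile(),
                     replicates = 2, seed = 9, duration = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_synergy_json(rep, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(x$meta$seed, 9)
  expect_equal(x$ratio, rep$ratio, tolerance = 1e-12)
  expect_named(x$yields, c("arm", "yield", "se"))
})
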