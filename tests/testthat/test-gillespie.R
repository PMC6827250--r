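test_that("exolytic digestion runs to an all-monomer absorbing state", {
  n0 <- 10
  traj <- simulate_digest(c("ΔMMM" = n0), exo = exo_rate_profile(),
                          exo_mU = 100, t_end = Inf, seed = 3)
  fin <- final_state(traj)
  expect_true(all(fin$chains == 0))
  # DP4 unsaturated chain: 3 unsaturated + 1 saturated monomer per chain
  expect_equal(unname(fin$monomers["UDP1"]), 3 * n0)
  expect_equal(unname(fin$monomers["M"]), n0)
  expect_equal(residue_count(fin), residue_count(traj$states[[1L]]))
})

test_that("ring count is conserved at every snapshot of a mixed digest", {
  pool <- generate_chains(alginate_preset("mixed", length_mean = 25), 3, seed = 5)
  traj <- simulate_digest(pool, endo = endo_rate_table(), exo = exo_rate_profile(),
                          endo_mU = 60, exo_mU = 60, t_end = 20, seed = 8,
                          record_times = seq(1, 19, by = 2))
  rings <- vapply(traj$states, residue_count, numeric(1L))
  expect_true(all(rings == rings[1L]))
  expect_gt(traj$n_events, 0L)
})

test_that("endolytic-only digestion never produces monomers", {
  pool <- generate_chains(alginate_preset("mixed", length_mean = 30), 4, seed = 2)
  traj <- simulate_digest(pool, endo = endo_rate_table(), endo_mU = 200,
                          t_end = Inf, seed = 21)
  fin <- final_state(traj)
  expect_equal(sum(fin$monomers), 0)
  expect_true(all(dp(names(fin$chains[fin$chains > 0])) >= 2L))
})

test_that("2-AB trajectories terminate at the labelled disaccharide", {
  for (seed in 1:5) {
    traj <- simulate_digest(c("ΔMMMM-2AB" = 4), exo = exo_rate_profile(),
                            exo_mU = 100, t_end = Inf, seed = seed)
    fin <- final_state(traj)
    live <- names(fin$chains[fin$chains > 0])
    expect_identical(live, "ΔM-2AB")
    expect_equal(unname(fin$chains[live]), 4)
  }
})

test_that("a fixed seed fixes the serialized trajectory byte-for-byte", {
  pool <- generate_chains(alginate_preset("mixed"), 3, seed = 2)
  run <- function() {
    f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
    traj <- simulate_digest(pool, endo = endo_rate_table(), exo = exo_rate_profile(),
                            endo_mU = 50, exo_mU = 50, t_end = 5, seed = 7)
    write_trajectory_tsv(traj, f)
    readLines(f)
  }
  expect_identical(run(), run())
})

test_that("all-zero propensity warns and returns the initial state", {
  expect_warning(
    traj <- simulate_digest(c("MM" = 3), endo = endo_rate_table(), endo_mU = 10,
                            t_end = 5, seed = 1),
    "zero")
  expect_equal(unname(final_state(traj)$chains["MM"]), 3)
})

test_that("simulated final-state distribution matches exact enumeration", {
  # endo-only digestion of a single unsaturated DP5 chain under the default
  # G-preferring table has two absorbing states; enumerate them exactly.
  dist <- oracle_final_distribution("ΔMGGM", k = default_k)
  # hand check of the oracle itself: first cleavage picks bond M|G (k = 0.25)
  # or G|G (k = 1); both leave absorbing fragments
  expect_equal(dist[[state_key(c("ΔM", "ΔGM"))]], 0.2, tolerance = 1e-12)
  expect_equal(dist[[state_key(c("ΔMG", "ΔM"))]], 0.8, tolerance = 1e-12)

  n <- 2000
  keys <- vapply(seq_len(n), function(i) {
    traj <- simulate_digest(c("ΔMGGM" = 1), endo = endo_rate_table(),
                            endo_mU = 50, t_end = Inf, seed = i)
    sim_state_key(final_state(traj))
  }, character(1L))
  emp <- table(keys) / n
  p <- unlist(dist)
  states <- union(names(p), names(emp))
  pv <- vapply(states, function(s) if (s %in% names(p)) p[[s]] else 0, numeric(1L))
  ev <- vapply(states, function(s) if (s %in% names(emp)) emp[[s]] else 0, numeric(1L))
  tv <- sum(abs(pv - ev)) / 2
  expect_lt(tv, 3 * sqrt(sum(p * (1 - p)) / n))
})

test_that("exhaustive endolytic product summary is size-confined and normalized", {
  pool <- generate_chains(alginate_preset("mixed", length_mean = 30), 3, seed = 4)
  fp <- final_products(pool, endo_rate_table(), seed = 10, replicates = 3)
  expect_equal(sum(fp$size_summary$proportion), 1, tolerance = 1e-9)
  expect_true(all(fp$size_summary$dp >= 2L))
  for (comp in fp$composition)
    expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
  expect_error(final_products(pool, endo_rate_table(k = c(GG = 0, GM = 0, MG = 0, MM = 0))),
               "at least one")
})

test_that("monomer speciation is an expected split of one conserved pool", {
  sp <- monomer_speciation(100)
  expect_equal(sum(sp), 100)
  expect_error(monomer_speciation(10, c(UDP1 = 0.5, DEH = 0.4, TPC = 0.2)))
})
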