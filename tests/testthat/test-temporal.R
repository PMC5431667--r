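test_that("classify_pattern maps all seven nonzero patterns", {
  cases <- list(
    list(c(TRUE, TRUE, TRUE), "constant"),
    list(c(FALSE, TRUE, TRUE), "de_novo_23"),
    list(c(FALSE, FALSE, TRUE), "de_novo_3"),
    list(c(TRUE, FALSE, FALSE), "inconsistent"),
    list(c(FALSE, TRUE, FALSE), "inconsistent"),
    list(c(TRUE, TRUE, FALSE), "inconsistent"),
    list(c(TRUE, FALSE, TRUE), "inconsistent"))
  for (cs in cases) {
    expect_equal(as.character(classify_pattern(cs[[1]])), cs[[2]])
  }
  # the detection-gap pattern carries a diagnostic flag
  gap <- classify_pattern(c(TRUE, FALSE, TRUE))
  expect_true(attr(gap, "gap"))
  expect_false(attr(classify_pattern(c(TRUE, TRUE, FALSE)), "gap"))
  expect_error(classify_pattern(c(FALSE, FALSE, FALSE)), "at least one")
})

test_that("identical calls across all time points form one constant trajectory", {
  calls <- rbind(call_row("S1", 1, "1", 1000, 5000),
                 call_row("S1", 2, "1", 1000, 5000),
                 call_row("S1", 3, "1", 1000, 5000))
  traj <- match_calls(calls)
  expect_equal(nrow(traj), 1)
  expect_equal(traj$temporal_class, "constant")
  expect_true(all(unlist(traj[, c("t1", "t2", "t3")])))
  expect_equal(traj$n_members, 3L)
})

test_that("a call present only at the third time point is de novo (3rd)", {
  traj <- match_calls(call_row("S1", 3, "1", 1000, 5000))
  expect_equal(traj$temporal_class, "de_novo_3")
  expect_identical(unname(unlist(traj[, c("t1", "t2", "t3")])),
                   c(FALSE, FALSE, TRUE))
})

test_that("barely-overlapping calls stay separate under the reciprocal rule", {
  # 10% mutual overlap, threshold 0.5: two trajectories
  calls <- rbind(call_row("S1", 1, "1", 1000, 11000),
                 call_row("S1", 2, "1", 10000, 20000))
  expect_equal(nrow(match_calls(calls, 0.5)), 2)
  # but a permissive threshold merges them
  expect_equal(nrow(match_calls(calls, 0.05)), 1)
})

test_that("calls of different state or subject never merge", {
  calls <- rbind(call_row("S1", 1, "1", 1000, 5000, state = "loss"),
                 call_row("S1", 2, "1", 1000, 5000, state = "gain"),
                 call_row("S2", 3, "1", 1000, 5000, state = "loss"))
  traj <- match_calls(calls)
  expect_equal(nrow(traj), 3)
})

test_that("every call lands in exactly one trajectory", {
  set.seed(31)
  res <- run_report(sim_config(n_subjects = 2, n_chromosomes = 3,
                               markers_per_chromosome = 300, n_constant = 4,
                               n_denovo_23 = 2, n_denovo_3 = 2, seed = 31))
  expect_equal(sum(res$trajectories$n_members), nrow(res$calls))
  members <- unlist(strsplit(res$trajectories$member_call_ids, ","))
  expect_equal(sort(members), sort(res$calls$cnv_id))
  # class counts sum to trajectory count
  s <- res$summary
  expect_equal(s$n_constant + s$n_de_novo + s$n_inconsistent,
               s$n_trajectories)
})

test_that("duplicate same-time-point calls collapse with a warning", {
  calls <- rbind(call_row("S1", 1, "1", 1000, 5000, id = "a"),
                 call_row("S1", 1, "1", 1200, 5200, id = "b"),
                 call_row("S1", 2, "1", 1000, 5000, id = "c"),
                 call_row("S1", 3, "1", 1000, 5000, id = "d"))
  expect_warning(traj <- match_calls(calls), "same time point")
  expect_equal(nrow(traj), 1)
  expect_equal(traj$temporal_class, "constant")
})

test_that("genome coverage accumulates unions and stays monotone", {
  # one constant 100 kb trajectory: flat coverage
  t1 <- traj_row("S1", "1", 0, 100e3, "constant")
  cov <- genome_coverage(t1)
  expect_equal(cov$coverage_bp, rep(100e3, 3))
  # constant 100 kb + disjoint de novo (3rd) 50 kb: 100, 100, 150
  t2 <- rbind(t1, traj_row("S1", "2", 0, 50e3, "de_novo_3"))
  expect_equal(genome_coverage(t2)$coverage_bp, c(100e3, 100e3, 150e3))
  # overlapping constants on one chromosome: union, not sum
  t3 <- rbind(traj_row("S1", "1", 0, 100e3, "constant", id = "a"),
              traj_row("S1", "1", 50e3, 150e3, "constant", id = "b"))
  expect_equal(genome_coverage(t3)$coverage_bp, rep(150e3, 3))
  # inconsistent trajectories never contribute
  t4 <- rbind(t1, traj_row("S1", "3", 0, 500e3, "inconsistent"))
  expect_equal(genome_coverage(t4)$coverage_bp, rep(100e3, 3))
})

test_that("the class coverage statistic is median length times count", {
  expect_equal(coverage_statistic(rep(36e3, 107)), 3.852e6)
  expect_equal(signif(coverage_statistic(rep(36e3, 107)) / 1e6, 2), 3.9)
  expect_equal(coverage_statistic(42), 42)
  expect_equal(coverage_statistic(c(10, 30, 50) * 1e3), 90e3)
  tr <- rbind(traj_row("S1", "1", 0, 10e3, "de_novo_3"),
              traj_row("S1", "2", 0, 30e3, "de_novo_23"),
              traj_row("S1", "3", 0, 50e3, "de_novo_3"))
  expect_equal(class_coverage_statistic(tr, "de_novo"), 90e3)
  expect_error(class_coverage_statistic(tr, "constant"), "no trajectories")
})

test_that("the de novo proportion test is exact and matches enumeration", {
  # observing exactly the null rate gives p = 1
  expect_equal(denovo_proportion_test(50, 100, 5, 10), 1)
  # the in vivo / in vitro contrast is highly significant
  expect_lt(denovo_proportion_test(107, 218, 21, 85), 1e-4)
  # small-n cases agree with full enumeration
  for (cfg in list(c(3, 9, 2, 8), c(5, 10, 1, 7), c(2, 6, 4, 10))) {
    expect_equal(denovo_proportion_test(cfg[1], cfg[2], cfg[3], cfg[4]),
                 binom_two_sided_enum(cfg[3], cfg[4], cfg[1] / cfg[2]),
                 tolerance = 1e-9)
  }
})

test_that("division-corrected rates and the division estimate are plain arithmetic", {
  expect_equal(round_away(division_corrected_rate(107, 120), 1), 0.9)
  expect_equal(round_away(division_corrected_rate(21, 50), 1), 0.4)
  expect_equal(division_corrected_rate(0, 120), 0)
  expect_equal(estimate_divisions_in_vitro(20, 2.5), 50)
  expect_equal(estimate_divisions_in_vitro(0), 0)
  expect_equal(estimate_divisions_in_vitro(10, 2), 20)
  expect_error(division_corrected_rate(10, 0))
})

test_that("round_away rounds halves away from zero at any precision", {
  expect_equal(round_away(13.875), 14)
  expect_equal(round_away(0.85, 1), 0.9)
  expect_equal(round_away(-0.85, 1), -0.9)
  expect_equal(round_away(24.7), 25)
})

test_that("noise-free cohorts classify every planted pattern exactly", {
  res <- run_report(sim_config(n_subjects = 2, n_chromosomes = 4,
                               markers_per_chromosome = 300, noise_sd = 0,
                               n_constant = 3, n_denovo_23 = 2,
                               n_denovo_3 = 2, n_inconsistent = 3,
                               seed = 17))
  s <- res$summary
  expect_equal(s$n_constant, 2 * 3)
  expect_equal(s$n_de_novo_23, 2 * 2)
  expect_equal(s$n_de_novo_3, 2 * 2)
  expect_equal(s$n_inconsistent, 2 * 3)
  expect_equal(res$recovery$fraction, 1)
})
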