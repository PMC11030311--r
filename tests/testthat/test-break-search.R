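test_that("two-section statistic matches the independent likelihood oracle", {
  # frozen value computed with the dpois-based oracle
  expect_equal(chi_sq_two_section(2, 20, 20, 20)$chi_sq,
               17.094487661271, tolerance = 1e-9)
  expect_equal(chi_sq_two_section(2, 20, 20, 20)$chi_sq,
               oracle_chi2_two(2, 20, 20, 20), tolerance = 1e-9)
  # alternative equals null: statistic exactly 0
  expect_equal(chi_sq_two_section(10, 20, 5, 10)$chi_sq, 0)
  # capping makes both models identical when every section is enriched
  expect_equal(chi_sq_two_section(25, 20, 30, 20)$chi_sq, 0)
  # randomized agreement with the oracle
  withr::with_seed(21, {
    for (r in 1:50) {
      e <- runif(2, 1, 40)
      o <- rpois(2, e * runif(1, 0, 1.3))
      expect_equal(chi_sq_two_section(o[1], e[1], o[2], e[2])$chi_sq,
                   oracle_chi2_two(o[1], e[1], o[2], e[2]),
                   tolerance = 1e-9)
    }
  })
})

test_that("three-section statistic matches the oracle and collapses correctly", {
  expect_equal(chi_sq_three_section(2, 20, 20, 20, 2, 20)$chi_sq,
               oracle_chi2_three(2, 20, 20, 20, 2, 20), tolerance = 1e-9)
  expect_equal(chi_sq_three_section(5, 10, 10, 20, 15, 30)$chi_sq, 0)
  # reducing the middle section's contrast with the flanks (same flanks)
  # reduces the statistic
  distinct <- chi_sq_three_section(2, 20, 20, 20, 2, 20)$chi_sq
  collapsed <- chi_sq_three_section(2, 20, 6, 20, 2, 20)$chi_sq
  expect_lt(collapsed, distinct)
  withr::with_seed(22, {
    for (r in 1:50) {
      e <- runif(3, 1, 40)
      o <- rpois(3, e * runif(1, 0, 1.3))
      expect_equal(
        chi_sq_three_section(o[1], e[1], o[2], e[2], o[3], e[3])$chi_sq,
        oracle_chi2_three(o[1], e[1], o[2], e[2], o[3], e[3]),
        tolerance = 1e-9
      )
    }
  })
})

test_that("statistic is non-negative on randomized inputs", {
  withr::with_seed(23, {
    for (r in 1:200) {
      e <- runif(3, 0.5, 50)
      o <- rpois(3, e * runif(3, 0, 1.5))
      expect_gte(chi_sq_two_section(o[1], e[1], o[2], e[2])$chi_sq, -1e-12)
      expect_gte(
        chi_sq_three_section(o[1], e[1], o[2], e[2], o[3], e[3])$chi_sq,
        -1e-12
      )
    }
  })
})

test_that("single-break scan enforces the eligibility rule", {
  # total expectation below 2 x min_expected: no eligible position
  tab <- random_position_table(50, seed = 31)
  tm <- as_tm(tab$obs, rep(0.5, 50))  # total exp 25 < 32
  expect_null(scan_single_break(tm, search_config(min_expected = 16)))
})

test_that("single-break scan equals the brute-force argmax", {
  cfg <- search_config()
  withr::with_seed(32, seeds <- sample.int(1e6, 30))
  for (s in seeds) {
    n <- 50 + (s %% 150)
    tab <- random_position_table(n, seed = s)
    # inflate expectations so instances are eligible
    exp <- tab$exp * 3
    tm <- as_tm(tab$obs, exp)
    got <- scan_single_break(tm, cfg)
    want <- oracle_scan_single(tab$obs, exp, cfg$min_expected,
                               cfg$crit_single)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$break_index, want$pos_index)
      expect_equal(got$chi_sq, want$chi_sq, tolerance = 1e-9)
    }
  }
})

test_that("two-break scan equals brute-force pair enumeration", {
  cfg <- search_config()
  withr::with_seed(33, seeds <- sample.int(1e6, 8))
  for (s in seeds) {
    n <- 60 + (s %% 60)
    tab <- random_position_table(n, seed = s)
    exp <- tab$exp * 2.5
    tm <- as_tm(tab$obs, exp)
    got <- scan_two_breaks(tm, cfg)
    want <- oracle_scan_two(tab$obs, exp, cfg$min_expected, cfg$crit_double)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$break_index, want$pos_index)
      expect_equal(got$chi_sq, want$chi_sq, tolerance = 1e-9)
    }
  }
})

test_that("two-break scan recovers a planted valley profile", {
  # OEs 0.1 / 1.0 / 0.1 with 20 expected per section, counts at expectation:
  # the single-break test cannot represent the valley but the pair can
  obs <- rep(0L, 140)
  obs[c(20, 40)] <- 1L            # ~2 observed in the left flank (OE ~ 0.1)
  obs[seq(51, 89, by = 2)] <- 1L  # 20 observed in the middle (OE ~ 1)
  obs[c(100, 120)] <- 1L          # ~2 observed in the right flank
  tm <- as_tm(obs, rep(0.43, 140))
  got <- scan_two_breaks(tm, search_config())
  expect_false(is.null(got))
  expect_equal(length(got$break_index), 2)
  expect_lt(abs(got$break_index[1] - 50), 8)
  expect_lt(abs(got$break_index[2] - 90), 8)
})

test_that("uniform profiles yield no significant break", {
  sim <- simulate_transcript(sim_profile(200, 0.4, integer(0), 0.6),
                             seed = 35)
  tm <- transcript_model(sim$sites)
  r <- recursive_search(tm)
  expect_equal(nrow(r), 1)
  expect_equal(r$cds_start, 1)
  expect_equal(r$cds_end, 200)
  expect_equal(r$oe, oe_ratio(tm$total_obs, tm$total_exp))
  expect_true(is.na(r$chi_sq))
})

test_that("recursive search recovers planted two- and four-region profiles", {
  sim2 <- simulate_transcript(sim_profile(300, 0.4, 150, c(0.2, 1)),
                              seed = 41)
  r2 <- recursive_search(transcript_model(sim2$sites))
  expect_equal(nrow(r2), 2)
  expect_lt(abs(r2$cds_end[1] - 150), 11)

  sim4 <- simulate_transcript(
    sim_profile(600, 0.4, c(150, 300, 450), c(0.15, 1, 0.15, 1)),
    seed = 7
  )
  r4 <- recursive_search(transcript_model(sim4$sites))
  expect_equal(nrow(r4), 4)
  expect_true(all(abs(r4$cds_end[1:3] - c(150, 300, 450)) <= 10))
})

test_that("regions partition the CDS and conserve totals", {
  withr::with_seed(43, seeds <- sample.int(1e6, 20))
  for (s in seeds) {
    sim <- simulate_transcript(
      sim_profile(250, 0.4, c(100, 170), c(0.2, 1, 0.4)), seed = s
    )
    tm <- transcript_model(sim$sites)
    r <- recursive_search(tm)
    expect_equal(r$cds_start[1], min(tm$positions))
    expect_equal(r$cds_end[nrow(r)], max(tm$positions))
    if (nrow(r) > 1) {
      expect_equal(r$cds_start[-1], r$cds_end[-nrow(r)] + 1)
      expect_true(all(r$exp >= 16))
    }
    expect_equal(sum(r$obs), tm$total_obs)
    expect_equal(sum(r$exp), tm$total_exp, tolerance = 1e-9)
    expect_true(all(r$oe >= 0 & r$oe <= 1))
  }
})

test_that("search output is deterministic for identical input and config", {
  sim <- simulate_transcript(sim_profile(300, 0.4, 150, c(0.2, 1)), seed = 13)
  r1 <- search_regions(sim$sites)
  r2 <- search_regions(sim$sites)
  expect_identical(r1, r2)
})

test_that("search_regions handles several transcripts grouped", {
  s1 <- simulate_transcript(sim_profile(300, 0.4, 150, c(0.2, 1)), "A",
                            seed = 1)$sites
  s2 <- simulate_transcript(sim_profile(150, 0.4), "B", seed = 2)$sites
  r <- search_regions(dplyr::bind_rows(s1, s2))
  expect_setequal(unique(r$transcript_id), c("A", "B"))
  expect_equal(unique(r$n_regions_in_transcript[r$transcript_id == "B"]), 1)
})
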