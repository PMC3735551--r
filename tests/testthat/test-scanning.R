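test_that("scan equals the brute-force rescan oracle", {
  bg <- uniform_background()
  prom <- generate_promoters(20, 60, seed = 41)
  sites <- random_sites(10, 6, seed = 42)
  for (pwm in list(build_mono_pwm(sites, bg), build_di_pwm(sites, bg))) {
    for (cutoff in c(0, -2, -5, min_score(pwm))) {
      model <- scoring_model(pwm, cutoff)
      got <- scan(model, prom)
      want <- brute_force_scan(model, prom)
      expect_equal(got$promoter_id, want$promoter_id)
      expect_equal(got$start, want$start)
      expect_equal(got$score, want$score)
    }
    # window-restricted scan agrees too
    win <- functional_window(10, 30)
    model <- scoring_model(pwm, -4)
    got <- scan(model, prom, win)
    want <- brute_force_scan(model, prom, win)
    expect_equal(got$start, want$start)
    expect_true(all(got$start >= 10 & got$start <= 30 - pwm$L))
  }
})

test_that("cut-off extremes behave as expected", {
  bg <- uniform_background()
  prom <- generate_promoters(15, 40, seed = 43)
  pwm <- build_mono_pwm(site_set(rep("ACGTAC", 3)), bg)
  # cutoff 0: only exact consensus occurrences
  hits0 <- scan(scoring_model(pwm, 0), prom)
  if (nrow(hits0)) expect_true(all(hits0$score == 0))
  # cutoff at the minimum achievable score: every position is a hit
  hits_all <- scan(scoring_model(pwm, min_score(pwm)), prom)
  expect_equal(nrow(hits_all), 15 * (40 - 6 + 1))
})

test_that("z profile matches hand computation and handles flats", {
  # O = (0, 0, 10, 0, 0): E = 2, population sigma = 4, peak z = 2
  pr <- repwm:::profile_from_counts(c(0, 0, 10, 0, 0), 0:4, -1, 4)
  expect_equal(pr$E, 2)
  expect_equal(pr$sigma, 4)
  expect_equal(max(pr$z), 2)
  # constant O -> z identically zero
  flat <- repwm:::profile_from_counts(rep(3, 6), 0:5, -1, 4)
  expect_equal(flat$z, rep(0, 6))

  # end-to-end: planted consensus drives the peak where it was planted
  prom <- generate_promoters(200, 80, seed = 44)
  planted <- plant_motif(prom, consensus_frequency_matrix("ACGTACGT", 1),
                         c(30, 30), plant_rate = 0.5, seed = 45)
  bg <- estimate_background(planted$promoters)
  pwm <- build_mono_pwm(site_set(rep("ACGTACGT", 3)), bg)
  prof <- z_profile(scoring_model(pwm, 0), planted$promoters)
  expect_equal(prof$positions[which.max(prof$z)], 30)
  expect_gt(max(prof$z), 3)
  expect_equal(length(prof$O), 80 - 8 + 1)
  expect_equal(prof$z, (prof$O - prof$E) / prof$sigma)
})

test_that("raising the cut-off never increases positional counts", {
  bg <- uniform_background()
  prom <- generate_promoters(30, 50, seed = 46)
  pwm <- build_mono_pwm(random_sites(8, 6, seed = 47), bg)
  grid <- cutoff_z_grid(pwm, prom)
  expect_true(all(diff(grid$cutoffs) <= 0))
  # rows are ordered stringent -> permissive; O grows monotonically
  expect_true(all(apply(grid$O, 2, function(col) all(diff(col) >= 0))))
  # a single-cutoff grid reduces to z_profile
  g1 <- cutoff_z_grid(pwm, prom, cutoffs = -3)
  prof <- z_profile(scoring_model(pwm, -3), prom)
  expect_equal(unname(g1$z[1, ]), prof$z)
})

test_that("peak column is stable across cutoffs retaining the signal", {
  prom <- generate_promoters(150, 60, seed = 48)
  planted <- plant_motif(prom, consensus_frequency_matrix("TTGACGTA", 1),
                         c(20, 20), plant_rate = 0.4, seed = 49)
  bg <- estimate_background(planted$promoters)
  pwm <- build_mono_pwm(site_set(rep("TTGACGTA", 3)), bg)
  grid <- cutoff_z_grid(pwm, planted$promoters, cutoffs = c(0, -0.5, -1))
  peaks <- apply(grid$z, 1, which.max)
  expect_true(all(grid$positions[peaks] == 20))
})

test_that("window detection fuses nearby peaks and reports empties", {
  # synthetic grid: peaks at 515-516 and 519-520 with L = 13 -> one window
  positions <- 500:530
  z <- matrix(0, nrow = 2, ncol = length(positions))
  z[, positions %in% c(515, 516, 519, 520)] <- 4
  grid <- structure(list(z = z, O = z, cutoffs = c(-1, -5),
                         positions = positions, L = 13L),
                    class = "cutoff_z_grid")
  wins <- detect_functional_windows(grid, z_threshold = 3, L = 13L)
  expect_length(wins, 1L)
  expect_equal(wins[[1]]$start, 515L)
  expect_equal(wins[[1]]$end, 520L + 13L)
  expect_equal(wins[[1]]$cutoff_range, c(-5, -1))

  # peaks separated by 2 L stay separate windows
  z2 <- matrix(0, nrow = 1, ncol = length(positions))
  z2[, positions %in% c(502, 528)] <- 4
  grid2 <- structure(list(z = z2, O = z2, cutoffs = -1,
                          positions = positions, L = 13L),
                     class = "cutoff_z_grid")
  expect_length(detect_functional_windows(grid2, 3, 13L), 2L)

  # all z below threshold -> empty list
  grid3 <- grid
  grid3$z[] <- 1
  expect_identical(detect_functional_windows(grid3, 3, 13L), list())
})

test_that("false-positive z outliers are rare on motif-free promoters", {
  prom <- generate_promoters(100, 200, seed = 50)
  bg <- estimate_background(prom)
  pwm <- build_mono_pwm(random_sites(10, 8, seed = 51), bg)
  # pool z values across a few cut-offs; outliers should stay < 5%
  grid <- cutoff_z_grid(pwm, prom, cutoffs = c(-2, -4, -6, -8))
  frac <- mean(abs(grid$z) >= 3)
  expect_lt(frac, 0.05)
})
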