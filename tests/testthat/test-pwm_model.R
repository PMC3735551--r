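test_that("background estimation pools frequencies over the region", {
  prom <- generate_promoters(100, 600, seed = 31)
  bg <- estimate_background(prom)
  # binomial sampling bound at n = 60,000 per base
  expect_true(all(abs(bg$e_b - 0.25) < 0.01))
  expect_equal(sum(bg$e_b), 1, tolerance = 1e-9)
  expect_equal(sum(bg$e_d), 1, tolerance = 1e-9)
  expect_equal(bg$region, c(0L, 600L))

  # degenerate one-promoter case: zero frequencies floored with a warning
  one <- promoter_set("AAAA", tss_offset = 0)
  # both the base and the dinucleotide vectors warn about flooring
  expect_warning(expect_warning(bg1 <- estimate_background(one),
                                "floored"), "floored")
  expect_gt(bg1$e_b["A"], 0.7)
  expect_true(all(bg1$e_b[c("T", "G", "C")] > 0))
  expect_equal(which.max(bg1$e_d), c(AA = 1L))

  expect_error(estimate_background(prom, c(10, 10)), "empty")
  expect_error(estimate_background(prom, c(0, 601)), "bounds")
})

test_that("mononucleotide weights match the hand-computed log-odds", {
  bg <- uniform_background()
  pwm <- build_mono_pwm(site_set(rep("ACGT", 5)), bg)
  # absent base with pseudocount s = 1: ln(1/9) - ln(6/9) = ln(1/6)
  for (j in 1:4) {
    expect_equal(max(pwm$weights[, j]), 0)
    absent <- setdiff(rownames(pwm$weights), substr("ACGT", j, j))
    expect_equal(unname(pwm$weights[absent, j]), rep(log(1 / 6), 3),
                 tolerance = 1e-12)
  }
  expect_equal(pwm$pseudo, rep(1, 4))

  # all-counts-positive column: no pseudocount, w = log count ratio
  sites <- site_set(c("AAAA", "CAAA", "GAAA", "TAAA", "AAAA"))
  pwm2 <- build_mono_pwm(sites, bg)
  expect_equal(pwm2$pseudo[1], 0)
  expect_equal(unname(pwm2$weights["A", 1]), 0)
  expect_equal(unname(pwm2$weights[c("T", "G", "C"), 1]),
               rep(log(1 / 2), 3), tolerance = 1e-12)

  # dimension rule: 40 sites of length 10 -> 4 x 10
  pwm3 <- build_mono_pwm(random_sites(40, 10, seed = 7), bg)
  expect_equal(dim(pwm3$weights), c(4L, 10L))
  expect_error(build_mono_pwm(site_set("ACGT"), bg), "2 sites")
})

test_that("dinucleotide weights, order, and dimensions are correct", {
  bg <- uniform_background()
  di <- build_di_pwm(site_set(rep("ACGTA", 4)), bg)
  expect_equal(dim(di$weights), c(16L, 4L))
  expect_identical(rownames(di$weights)[1:8],
                   c("AA", "AT", "AG", "AC", "TA", "TT", "TG", "TC"))
  # consensus dinucleotides carry weight 0
  expect_equal(unname(di$weights[c("AC", "CG", "GT", "TA"), 1:4][
    cbind(1:4, 1:4)]), rep(0, 4))

  # toy 3-site set: w_AC = ln(2/19) - ln(3/19) = ln(2/3)
  di2 <- build_di_pwm(site_set(c("AATAA", "AATAA", "ACTAA")), bg)
  expect_equal(unname(di2$weights["AC", 1]), log(2 / 3), tolerance = 1e-12)
  expect_equal(unname(di2$weights["AA", 1]), 0)

  # L = 10 sites -> 16 x 9 matrix
  di3 <- build_di_pwm(random_sites(30, 10, seed = 13), bg)
  expect_equal(dim(di3$weights), c(16L, 9L))
})

test_that("dinucleotide index mapping follows the fixed order", {
  expect_equal(unname(dinucleotide_sequence("AAT")), c(1L, 2L))
  expect_identical(names(dinucleotide_sequence("AAT")), c("AA", "AT"))
  expect_equal(unname(dinucleotide_sequence("AC")), 4L)
  expect_length(dinucleotide_sequence(strrep("ACGT", 3)), 11L)
  expect_error(dinucleotide_sequence("AXT"), "invalid")
})

test_that("scoring is additive, bounded by 0, and matches enumeration", {
  bg <- uniform_background()
  sites <- random_sites(12, 6, seed = 17)
  pwm <- build_mono_pwm(sites, bg)
  expect_equal(score_site(pwm, pwm_consensus(pwm)), 0)

  # per-column additivity against a naive lookup on random sequences
  set.seed(18)
  for (k in 1:20) {
    s <- paste(sample(c("A", "T", "G", "C"), 6, replace = TRUE),
               collapse = "")
    naive <- sum(vapply(1:6, function(j)
      pwm$weights[substr(s, j, j), j], numeric(1)))
    expect_equal(score_site(pwm, s), naive)
  }

  # exhaustive enumeration of all 4^6 sequences: max score is 0 and the
  # arg-max realises the column-wise arg-max
  combos <- expand.grid(rep(list(c("A", "T", "G", "C")), 6),
                        stringsAsFactors = FALSE)
  all_seqs <- do.call(paste0, combos)
  all_scores <- vapply(all_seqs, function(s) score_site(pwm, s), numeric(1))
  expect_equal(max(all_scores), 0)
  expect_true(all(all_scores <= 0))
  # the score-0 set is exactly the set of column-wise arg-max sequences
  argmax_set <- all_seqs[all_scores == 0]
  expect_true(pwm_consensus(pwm) %in% argmax_set)
  per_col_max <- vapply(1:6, function(j)
    sum(pwm$weights[, j] == 0), numeric(1))
  expect_equal(length(argmax_set), prod(per_col_max))
  expect_equal(min(all_scores), min_score(pwm))
  expect_error(score_site(pwm, "ACGT"), "length")
})

test_that("per-column max weight is zero for every built matrix", {
  bg <- uniform_background()
  for (seed in 1:5) {
    pwm <- build_mono_pwm(random_sites(8, 7, seed = seed), bg)
    expect_equal(apply(pwm$weights, 2, max), rep(0, 7))
    expect_true(all(pwm$weights <= 0))
    di <- build_di_pwm(random_sites(8, 7, seed = seed + 100), bg)
    expect_equal(unname(apply(di$weights, 2, max)), rep(0, 6))
    expect_true(all(di$weights <= 0))
  }
})

test_that("information content matches closed forms and stays in [0, 2]", {
  ic <- information_content(site_set(c("AACG", "AGCG")))
  expect_equal(ic$ic[1], 2)            # invariant column
  expect_equal(ic$ic[2], 1)            # (0.5, 0.5, 0, 0) column
  ic2 <- information_content(site_set(c("AAAA", "TAAA", "GAAA", "CAAA")))
  expect_equal(ic2$ic[1], 0)           # uniform column
  for (seed in 1:3) {
    icr <- information_content(random_sites(10, 8, seed = seed))
    expect_true(all(icr$ic >= 0 & icr$ic <= 2 + 1e-12))
    expect_equal(colSums(icr$contributions), icr$ic)
  }
})
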