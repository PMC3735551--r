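test_that("hit matching applies the half-motif-plus-one tolerance rule", {
  truth <- data.frame(id = "t1", insert_start = 27L, motif_length = 8L,
                      stringsAsFactors = FALSE)
  # L = 8, edges 27 and 34, tolerance floor(8/2)+1 = 5
  cc_exact <- match_hits(hit_table("t1", 27L, 0), truth, L = 8,
                         seq_len = 300)
  expect_equal(cc_exact$TP, 1)
  cc_edge <- match_hits(hit_table("t1", 39L, 0), truth, L = 8,
                        seq_len = 300)
  expect_equal(cc_edge$TP, 1)   # distance 5 from edge 34: still correct
  cc_out <- match_hits(hit_table("t1", 40L, 0), truth, L = 8,
                       seq_len = 300)
  expect_equal(cc_out$TP, 0)    # distance 6: a false positive
  expect_equal(cc_out$FP, 1)
  # looser whole-motif-length tolerance mode accepts it
  cc_loose <- match_hits(hit_table("t1", 40L, 0), truth, L = 8,
                         seq_len = 300, tolerance = 8L)
  expect_equal(cc_loose$TP, 1)

  # single-credit rule: two matching hits give 1 TP + 1 FP
  two <- hit_table(c("t1", "t1"), c(27L, 29L), c(0, 0))
  cc_two <- match_hits(two, truth, L = 8, seq_len = 300)
  expect_equal(cc_two$TP, 1)
  expect_equal(cc_two$FP, 1)

  expect_error(match_hits(hit_table("nope", 1L, 0), truth, 8, 300),
               "absent")
})

test_that("match_hits equals a brute-force matcher on random instances", {
  set.seed(111)
  for (trial in 1:10) {
    n_seq <- 6L; L <- 7L; seq_len_ <- 60L
    tol <- L %/% 2L + 1L
    truth <- data.frame(id = sprintf("s%d", 1:n_seq),
                        insert_start = sample(0:(seq_len_ - L), n_seq,
                                              replace = TRUE),
                        motif_length = L, stringsAsFactors = FALSE)
    n_hits <- sample(0:8, 1)
    hits <- hit_table(sample(truth$id, n_hits, replace = TRUE),
                      sample(0:(seq_len_ - L), n_hits, replace = TRUE),
                      rep(0, n_hits))
    cc <- match_hits(hits, truth, L, seq_len_)
    # oracle: enumerate all (truth, hit) distances
    tp <- 0L
    for (i in seq_len(n_seq)) {
      h <- hits$start[hits$promoter_id == truth$id[i]]
      edges <- c(truth$insert_start[i], truth$insert_start[i] + L - 1L)
      ok <- vapply(h, function(s) min(abs(s - edges)) <= tol, logical(1))
      if (any(ok)) tp <- tp + 1L
    }
    expect_equal(cc$TP, tp)
    expect_equal(cc$FP, nrow(hits) - tp)
    expect_equal(cc$FN, n_seq - tp)
    # components always reconcile to N_total
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN,
                 n_seq * (seq_len_ - L + 1))
  }
})

test_that("precision, recall, and MCC match their definitions", {
  cc <- confusion_counts(15, 3, 16, 100, convention = "test")
  expect_equal(precision(cc), 15 / 18)
  expect_equal(recall(cc), 15 / 31)
  # undefined cases render as n/a
  none <- confusion_counts(0, 0, 5, 100, convention = "test")
  expect_true(is.na(precision(none)))
  expect_identical(format_metric(precision(none)), "n/a")
  expect_true(is.na(mcc(none)))
  # MCC closed forms
  expect_equal(mcc(confusion_counts(10, 0, 0, 50)), 1)
  expect_equal(mcc(confusion_counts(1, 1, 1, 1)), 0)
  # bounds on random counts
  set.seed(112)
  for (k in 1:25) {
    v <- sample(0:20, 4, replace = TRUE) + 1
    cck <- confusion_counts(v[1], v[2], v[3], v[4])
    expect_true(precision(cck) >= 0 && precision(cck) <= 1)
    expect_true(recall(cck) >= 0 && recall(cck) <= 1)
    m <- mcc(cck)
    expect_true(is.na(m) || (m >= -1 && m <= 1))
  }
})

test_that("percent change reports signed percentages of the old count", {
  expect_equal(percent_change(77, 123), 59.7, tolerance = 5e-3)
  expect_equal(percent_change(127, 73), -42.5, tolerance = 5e-3)
  expect_equal(percent_change(10, 10), 0)
  expect_true(is.na(percent_change(0, 5)))
})

test_that("model evaluation on replicates recovers a planted consensus", {
  sites <- flanked_sites(10, "TTGACGTAC", flank_max = 4, seed = 121)
  test <- build_site_test(sites, insert_position = 27, total_length = 150,
                          seed = 122)
  reps <- reshuffle_replicates(test, n_replicates = 5, n_shuffles = 30,
                               seed = 123)
  prom_bg <- generate_promoters(50, 150, seed = 124)
  bg <- estimate_background(prom_bg)
  pwm <- build_mono_pwm(site_set(rep("TTGACGTAC", 3)), bg)
  model <- scoring_model(pwm, 0)  # consensus-only model
  ev <- evaluate_model(model, reps)
  # every replicate contains the exact consensus at the planted position
  expect_equal(unname(ev$mean["recall"]), 1)
  expect_equal(unname(ev$mean["precision"]), 1, tolerance = 0.05)
  expect_gt(unname(ev$mean["mcc"]), 0.95)
  expect_equal(nrow(ev$per_replicate), 5L)

  # cutoff at the score floor: recall 1, precision ~ test_size / N_total
  floor_model <- scoring_model(pwm, min_score(pwm))
  ev2 <- evaluate_model(floor_model, reps[1])
  expect_equal(unname(ev2$mean["recall"]), 1)
  n_total <- 10 * (150 - 9 + 1)
  expect_lt(unname(ev2$mean["precision"]), 10 / n_total * 12)
})
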