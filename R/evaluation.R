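#' Match predicted hits against planted truth (synthetic-test convention)
#'
#' A truth motif counts as a true positive when at least one hit start lies
#' within the tolerance of the nearer motif edge; the closest such hit is
#' credited and every other hit is a false positive (at most one TP per
#' truth motif). `tolerance = "paper"` uses `floor(L/2) + 1` nt from the
#' nearer edge (the half-motif-length-plus-one rule); `tolerance = L` gives
#' the looser whole-motif-length mode. FN is the number of truth motifs
#' left undiscovered, and TN complements TP+FP+FN to the total number of
#' possible hits `N_total = test_size * (seq_len - L + 1)`.
#'
#' @param hits a [hit_table()] over the test sequences.
#' @param truth data.frame with columns `id`, `insert_start`,
#'   `motif_length` (one motif per sequence), e.g. a `synthetic_test$truth`.
#' @param L motif length of the scanning matrix.
#' @param seq_len test sequence length.
#' @param tolerance `"paper"` or an integer tolerance in nt.
#' @return a [confusion_counts()] object (`convention = "test"`).
#' @export
match_hits <- function(hits, truth, L, seq_len, tolerance = "paper") {
  tol <- if (identical(tolerance, "paper")) L %/% 2L + 1L
         else as.integer(tolerance)
  if (!all(hits$promoter_id %in% truth$id))
    stop("hits reference sequences absent from the truth table")
  test_size <- nrow(truth)
  tp <- 0L
  for (i in seq_along(truth$id)) {
    h <- hits$start[hits$promoter_id == truth$id[i]]
    if (length(h) == 0L) next
    edge_l <- truth$insert_start[i]
    edge_r <- truth$insert_start[i] + truth$motif_length[i] - 1L
    d <- pmin(abs(h - edge_l), abs(h - edge_r))
    if (min(d) <= tol) tp <- tp + 1L
  }
  fp <- nrow(hits) - tp
  fn <- test_size - tp
  n_total <- test_size * (seq_len - L + 1L)
  tn <- n_total - (tp + fp + fn)
  if (tn < 0) stop("more hits than possible placements; check L / seq_len")
  confusion_counts(tp, fp, fn, tn, convention = "test",
                   test_size = test_size, n_total = n_total)
}

#' Confusion counts from printed TP/FP and the test geometry
#'
#' Convenience constructor for the synthetic-test convention when only TP,
#' FP, the test size and the geometry are known: FN = test_size - TP and
#' TN complements to `test_size * (seq_len - L + 1)`.
#'
#' @param tp,fp counts.
#' @param test_size number of truth sequences.
#' @param seq_len,L test sequence and motif lengths.
#' @return a [confusion_counts()] object.
#' @export
test_confusion <- function(tp, fp, test_size, seq_len, L) {
  fn <- test_size - tp
  n_total <- test_size * (seq_len - L + 1)
  tn <- n_total - (tp + fp + fn)
  confusion_counts(tp, fp, fn, tn, convention = "test",
                   test_size = test_size, n_total = n_total)
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`; undefined (NA, rendered "n/a" in reports) when no
#' positive calls were made.
#'
#' @param cc a [confusion_counts()] object.
#' @return scalar in `[0, 1]`, or `NA`.
#' @export
precision <- function(cc) {
  stopifnot(inherits(cc, "confusion"))
  if (cc$TP + cc$FP == 0) return(NA_real_)
  cc$TP / (cc$TP + cc$FP)
}

#' Recall (sensitivity)
#'
#' `TP / (TP + FN)`; undefined (NA) when there are no positives to find.
#'
#' @param cc a [confusion_counts()] object.
#' @return scalar in `[0, 1]`, or `NA`.
#' @export
recall <- function(cc) {
  stopifnot(inherits(cc, "confusion"))
  if (cc$TP + cc$FN == 0) return(NA_real_)
  cc$TP / (cc$TP + cc$FN)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; undefined (NA)
#' when any marginal is zero. This is the refinement loop's objective
#' (Cor).
#'
#' @param cc a [confusion_counts()] object.
#' @return scalar in `[-1, 1]`, or `NA`.
#' @export
mcc <- function(cc) {
  stopifnot(inherits(cc, "confusion"))
  m <- c(cc$TP + cc$FP, cc$TP + cc$FN, cc$TN + cc$FP, cc$TN + cc$FN)
  if (any(m == 0)) return(NA_real_)
  (cc$TP * cc$TN - cc$FP * cc$FN) / sqrt(prod(m))
}

#' Signed percentage change of a count
#'
#' `100 * (new - old) / old`, the improvement measure used to aggregate
#' TP/FP totals across methods.
#'
#' @param old_count baseline count (> 0).
#' @param new_count new count.
#' @return signed percentage, or `NA` when `old_count` is 0.
#' @export
percent_change <- function(old_count, new_count) {
  if (old_count == 0) return(NA_real_)
  100 * (new_count - old_count) / old_count
}

#' Evaluate a scoring model on synthetic-test replicates
#'
#' Scans every replicate at the model's cut-off, matches hits against the
#' truth, and reports per-replicate and replicate-mean precision, recall
#' and Matthews correlation. Averaging over background-reshuffled
#' replicates reduces the impact of any one random background.
#'
#' @param model a [scoring_model()].
#' @param tests list of `synthetic_test` objects (replicates).
#' @param tolerance passed to [match_hits()].
#' @return list with `per_replicate` (data.frame: replicate, TP, FP, FN,
#'   TN, precision, recall, mcc) and `mean` (named numeric vector of the
#'   metric means, NA values removed).
#' @export
evaluate_model <- function(model, tests, tolerance = "paper") {
  stopifnot(inherits(model, "scoring_model"))
  if (inherits(tests, "synthetic_test")) tests <- list(tests)
  rows <- lapply(tests, function(test) {
    prom <- promoter_set(test$sequences, tss_offset = 0L,
                         ids = test$truth$id)
    hits <- scan(model, prom)
    cc <- match_hits(hits, test$truth, L = model$matrix$L,
                     seq_len = test$seq_length, tolerance = tolerance)
    data.frame(replicate = test$replicate_id,
               TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
               precision = precision(cc), recall = recall(cc),
               mcc = mcc(cc))
  })
  per_replicate <- do.call(rbind, rows)
  means <- colMeans(per_replicate[, c("TP", "FP", "FN", "TN",
                                      "precision", "recall", "mcc")],
                    na.rm = TRUE)
  list(per_replicate = per_replicate, mean = means)
}

#' Render a metric value the way reports print it
#'
#' @param x numeric scalar or NA.
#' @param digits significant digits (default 3).
#' @return `"n/a"` for undefined values, a formatted number otherwise.
#' @export
format_metric <- function(x, digits = 3) {
  if (is.na(x)) "n/a" else format(round(x, digits), nsmall = 0)
}
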