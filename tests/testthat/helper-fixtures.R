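# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite carries no data files.

uniform_background <- function() {
  prom <- generate_promoters(20, 100, seed = 99)
  bg <- estimate_background(prom)
  bg$e_b[] <- 0.25
  bg$e_d[] <- 1 / 16
  bg
}

random_sites <- function(n, L, seed) {
  set.seed(seed)
  site_set(vapply(seq_len(n), function(i)
    paste(sample(c("A", "T", "G", "C"), L, replace = TRUE),
          collapse = ""), character(1L)))
}

# Naive per-window rescan: the independent oracle for scan().
brute_force_scan <- function(model, promoters, window = NULL) {
  pwm <- model$matrix
  L <- pwm$L
  rows <- list()
  for (i in seq_along(promoters$sequences)) {
    seq_i <- promoters$sequences[i]
    starts <- if (is.null(window)) 0:(nchar(seq_i) - L)
              else window$start:(window$end - L)
    for (s in starts) {
      sc <- score_site(pwm, substr(seq_i, s + 1, s + L))
      if (sc >= model$cutoff - 1e-9)
        rows[[length(rows) + 1L]] <-
          data.frame(promoter_id = promoters$ids[i], start = s,
                     score = sc, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(hit_table())
  df <- do.call(rbind, rows)
  hit_table(df$promoter_id, df$start, df$score)
}

# Aligned-site fixture in the synthetic-test style: n sites sharing a
# planted block with random flanks of varying length.
flanked_sites <- function(n, block, flank_max = 6, seed = 5) {
  set.seed(seed)
  seqs <- character(n)
  offs <- integer(n)
  for (i in seq_len(n)) {
    lf <- sample(0:flank_max, 1)
    rf <- sample(0:flank_max, 1)
    seqs[i] <- paste0(
      paste(sample(c("A", "T", "G", "C"), lf, replace = TRUE),
            collapse = ""),
      block,
      paste(sample(c("A", "T", "G", "C"), rf, replace = TRUE),
            collapse = ""))
    offs[i] <- lf
  }
  aligned_sites(seqs, offs, nchar(block))
}
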