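#' Confusion counts between two hit sets (refinement-iteration convention)
#'
#' During refinement, the hits of the matrix preserved from the previous
#' step ("old") are taken as true. TP is the number of (promoter, start)
#' hits shared by both sets; FP the new hits not in the old set; FN the old
#' hits missed by the new set; and TN the complement of TP+FP+FN to the
#' total number of possible window placements
#' `N_total = n_promoters * max(1, span - L + 1)`.
#'
#' @param old_hits,new_hits [hit_table()]s restricted to the window.
#' @param window the [functional_window()] both scans were restricted to.
#' @param n_promoters number of promoters scanned.
#' @param L motif length.
#' @return a [confusion_counts()] object (`convention = "iteration"`).
#' @export
iteration_confusion <- function(old_hits, new_hits, window, n_promoters, L) {
  span <- window$end - window$start
  n_total <- n_promoters * max(1, span - L + 1)
  old_keys <- paste(old_hits$promoter_id, old_hits$start)
  new_keys <- paste(new_hits$promoter_id, new_hits$start)
  tp <- sum(new_keys %in% old_keys)
  fp <- length(new_keys) - tp
  fn <- length(old_keys) - tp
  tn <- n_total - (tp + fp + fn)
  if (tn < 0)
    stop("internal error: N_total smaller than TP + FP + FN")
  confusion_counts(tp, fp, fn, tn, convention = "iteration",
                   n_total = n_total)
}

#' Candidate site sets at motif length L - 1 and L + 1
#'
#' From the current hits, builds the four length-variant site collections:
#' `cl`/`cr` clip one nucleotide from the left/right of every hit site;
#' `el`/`er` extend each hit site by the adjacent promoter nucleotide on the
#' left/right (hits whose extension would cross a promoter boundary are
#' dropped from that variant).
#'
#' @param model a [scoring_model()] (or bare PWM) providing the current L.
#' @param hits a [hit_table()] of the current model's hits.
#' @param promoters the scanned [promoter_set()].
#' @param min_length clipping variants are skipped (NULL) when
#'   `L - 1 < min_length` (default 5).
#' @return named list `cl`, `cr`, `el`, `er` of [site_set()]s (`NULL` where
#'   a variant is skipped or has fewer than 2 usable sites).
#' @export
length_variants <- function(model, hits, promoters, min_length = 5L) {
  pwm <- if (inherits(model, "scoring_model")) model$matrix else model
  stopifnot(inherits(pwm, "pwm"), inherits(promoters, "promoter_set"))
  if (nrow(hits) == 0L) stop("no hits to derive length variants from")
  L <- pwm$L
  plen <- promoters$length
  seqs <- promoters$sequences[match(hits$promoter_id, promoters$ids)]
  s <- hits$start  # 0-based
  out <- list(cl = NULL, cr = NULL, el = NULL, er = NULL)
  as_sites <- function(x) if (length(x) >= 2L) site_set(x) else NULL
  if (L - 1L >= min_length) {
    out$cl <- as_sites(substr(seqs, s + 2L, s + L))
    out$cr <- as_sites(substr(seqs, s + 1L, s + L - 1L))
  }
  keep_l <- s >= 1L
  out$el <- as_sites(substr(seqs[keep_l], s[keep_l], s[keep_l] + L))
  keep_r <- s + L + 1L <= plen
  out$er <- as_sites(substr(seqs[keep_r], s[keep_r] + 1L, s[keep_r] + L + 1L))
  out
}

# Offset mapping a variant hit start back to the original-length frame
# (left edge of the corresponding original-L site): clipping the left
# column moves the variant start one right of the original edge, extending
# left moves it one left.
VARIANT_SHIFT <- c(main = 0L, cl = -1L, cr = 0L, el = 1L, er = 0L)

#' Refinement configuration defaults
#'
#' @param z_threshold qualifying z-score for signal detection (default 3).
#' @param cutoff_step grid step for cut-off searches (default 0.5).
#' @param c1,c2 cut-off grid bounds; `NULL` means `c1` = minimum achievable
#'   score of the matrix at hand and `c2` = 0.
#' @param min_length shortest motif length the optimisation may reach
#'   (default 5).
#' @param max_cycles hard cap on refinement cycles (default 20; typical
#'   convergence is much earlier).
#' @param rewindow re-run window detection with the current matrix every
#'   cycle (default FALSE: the stage-2 window is kept fixed).
#' @param window optional pre-supplied [functional_window()] (skips
#'   detection).
#' @param initial_cutoff optional pre-supplied initial cut-off c0.
#' @return list of configuration values.
#' @export
refine_config <- function(z_threshold = 3, cutoff_step = 0.5,
                          c1 = NULL, c2 = 0, min_length = 5L,
                          max_cycles = 20L, rewindow = FALSE,
                          window = NULL, initial_cutoff = NULL) {
  list(z_threshold = z_threshold, cutoff_step = cutoff_step,
       c1 = c1, c2 = c2, min_length = as.integer(min_length),
       max_cycles = as.integer(max_cycles), rewindow = isTRUE(rewindow),
       window = window, initial_cutoff = initial_cutoff)
}

build_matrix <- function(matrix_type, sites, background) {
  if (matrix_type == "di") build_di_pwm(sites, background)
  else build_mono_pwm(sites, background)
}

# Cut-off grid for a matrix under the config bounds.
config_cutoff_grid <- function(pwm, cfg) {
  c1 <- if (is.null(cfg$c1)) min_score(pwm) else max(cfg$c1, min_score(pwm))
  c2 <- cfg$c2
  grid <- unique(c(seq(c2, c1, by = -cfg$cutoff_step), c1))
  sort(grid, decreasing = TRUE)
}

# Grid-search the cut-off of matrix `pwm` inside `window`, maximising the
# Matthews correlation of its hits against `old_hits` (iteration
# convention). `shift` maps this matrix's starts to the original-L frame;
# `ref_L` is the reference motif length for N_total. Descending grid order
# makes ties resolve to the more stringent cut-off.
grid_search_cutoff <- function(pwm, base_mat, ids, window, old_hits,
                               n_promoters, ref_L, cfg, shift = 0L,
                               label = "main") {
  starts <- tryCatch(window_starts(ncol(base_mat), pwm$L, window),
                     error = function(e) NULL)
  if (is.null(starts)) return(NULL)
  S <- score_matrix(pwm, base_mat, starts)
  old_keys <- paste(old_hits$promoter_id, old_hits$start)
  n_old <- length(old_keys)
  span <- window$end - window$start
  n_total <- n_promoters * max(1, span - ref_L + 1)
  best <- NULL
  for (cc in config_cutoff_grid(pwm, cfg)) {
    idx <- which(S >= cc - SCORE_TOL, arr.ind = TRUE)
    keys <- paste(ids[idx[, 1L]], starts[idx[, 2L]] + shift)
    tp <- sum(keys %in% old_keys)
    fp <- length(keys) - tp
    fn <- n_old - tp
    tn <- n_total - (tp + fp + fn)
    if (tn < 0) next
    cor <- mcc(confusion_counts(tp, fp, fn, tn))
    if (is.na(cor)) next
    if (is.null(best) || cor > best$cor + 1e-12)
      best <- list(pwm = pwm, cutoff = cc, cor = cor, label = label,
                   L = pwm$L, shift = shift)
  }
  best
}

#' Iterative PWM refinement against a promoter set
#'
#' The core optimisation loop. Stage 1 builds the initial matrix from the
#' training sites; stage 2 detects the functional window(s) and initial
#' cut-off from the z-score grid of the initial mononucleotide matrix;
#' stage 3 iterates: (1) scan the window with the current suite <W, c>;
#' (2) union the discovered sites with the training sites and rebuild the
#' matrix; (3) grid-search the cut-off maximising the Matthews correlation
#' Cor of the new suite's hits against the current hits; (4) build the four
#' one-nucleotide length variants (cl, cr, el, er) from the hits and
#' grid-search each, keeping the best-Cor candidate (ties prefer the
#' unmodified length, then the shorter motif, then the more stringent
#' cut-off); (5) reassign and repeat until Cor reaches 1, stops improving,
#' or `max_cycles` is hit. When several windows qualify, each is refined
#' and the one with the maximal optimised Cor is returned.
#'
#' @param initial_sites training [site_set()].
#' @param promoters TSS-aligned [promoter_set()] to mine.
#' @param matrix_type `"mono"` or `"di"`.
#' @param config a [refine_config()] list.
#' @return an object of class `refinement_result`: `model` (final
#'   [scoring_model()] with optimised length and cut-off), `sites`
#'   (discovered [site_set()]), `hits` ([hit_table()]), `trajectory`
#'   (data.frame of cycle, cor, L, cutoff, n_sites), `window`, `improved`,
#'   `converged` (TRUE when Cor reached 1).
#' @export
refine <- function(initial_sites, promoters,
                   matrix_type = c("mono", "di"), config = refine_config()) {
  matrix_type <- match.arg(matrix_type)
  stopifnot(inherits(initial_sites, "site_set"),
            inherits(promoters, "promoter_set"))
  cfg <- utils::modifyList(refine_config(), config)
  bg <- estimate_background(promoters)
  w0 <- build_matrix(matrix_type, initial_sites, bg)
  # stage 2: signal detection always uses the mononucleotide matrix
  w0_mono <- if (matrix_type == "mono") w0
             else build_mono_pwm(initial_sites, bg)
  need_grid <- is.null(cfg$window) || is.null(cfg$initial_cutoff)
  if (need_grid) {
    grid <- cutoff_z_grid(w0_mono, promoters,
                          cutoffs = default_cutoff_grid(w0_mono,
                                                        cfg$cutoff_step))
  }
  windows <- if (is.null(cfg$window)) {
    detect_functional_windows(grid, cfg$z_threshold, L = initial_sites$L)
  } else list(cfg$window)
  if (length(windows) == 0L)
    stop("no functional window detected (all z < ", cfg$z_threshold, ")")
  # Cor-based selection is meaningful only among windows of comparable
  # signal strength: a weak window can reproduce its few hits trivially.
  # Keep the windows whose peak z is within one z-unit of the strongest
  # (threshold-level chance peaks drop out when a clear signal exists).
  pz <- vapply(windows, function(w) w$peak_z, numeric(1L))
  if (!all(is.na(pz)))
    windows <- windows[is.na(pz) | pz >= max(pz, na.rm = TRUE) - 1]
  # the initial cut-off c0 is estimated per window as the most permissive
  # cut-off down to which the window's peak signal is sustained (the
  # deepest row of its persistence range on the grid); a permissive c0
  # admits degenerate candidate sites for refinement to sort out
  window_c0 <- function(win) {
    if (!is.null(cfg$initial_cutoff)) return(cfg$initial_cutoff)
    c0 <- win$cutoff_range[1L]
    if (is.na(c0)) c0 <- initial_cutoff(grid, cfg$z_threshold)
    if (is.na(c0))
      stop("no position sustains z >= ", cfg$z_threshold,
           " at any cut-off; supply an initial cut-off explicitly")
    c0
  }
  # refine every qualifying window; a window with no initial hits is only
  # fatal when it is the sole candidate
  results <- lapply(windows, function(win)
    tryCatch(refine_window(w0, window_c0(win), win, promoters,
                           matrix_type, bg, initial_sites, cfg),
             error = function(e) e))
  failed <- vapply(results, inherits, logical(1L), "error")
  if (all(failed)) stop(conditionMessage(results[[1L]]))
  results <- results[!failed]
  cors <- vapply(results, function(r) {
    if (nrow(r$trajectory)) max(r$trajectory$cor) else -Inf
  }, numeric(1L))
  # maximum optimised Cor wins; exact ties (several windows reaching the
  # same Cor, typically 1) go to the window explaining more sites, then to
  # the stronger z peak
  n_hits <- vapply(results, function(r) nrow(r$hits), numeric(1L))
  peak_z <- vapply(results, function(r) r$window$peak_z, numeric(1L))
  results[[order(round(cors, 9), n_hits, peak_z,
                 decreasing = TRUE)[1L]]]
}

# Run the stage-3 loop inside one functional window.
refine_window <- function(w0, c0, window, promoters, matrix_type, bg,
                          training_sites, cfg) {
  base_mat <- encode_base_matrix(promoters$sequences)
  ids <- promoters$ids
  n_p <- length(ids)
  model <- scoring_model(w0, max(c0, min_score(w0)))
  old_hits <- scan(model, promoters, window)
  if (nrow(old_hits) == 0L)
    stop("no hits in the functional window at the initial cut-off; ",
         "relax the cut-off or the z threshold")
  prev_cor <- -Inf
  trajectory <- data.frame(cycle = integer(), cor = numeric(),
                           L = integer(), cutoff = numeric(),
                           n_sites = integer())
  converged <- FALSE
  for (cycle in seq_len(cfg$max_cycles)) {
    cur_L <- model$matrix$L
    disc_seqs <- extract_hit_sites(promoters, old_hits, cur_L)
    all_seqs <- if (training_sites$L == cur_L)
      c(training_sites$sequences, disc_seqs) else disc_seqs
    if (length(all_seqs) < 2L) break
    wi <- tryCatch(build_matrix(matrix_type, site_set(all_seqs), bg),
                   error = function(e) NULL)
    if (is.null(wi)) break
    n_sites_main <- length(all_seqs)
    cand <- grid_search_cutoff(wi, base_mat, ids, window, old_hits,
                               n_p, cur_L, cfg, shift = 0L, label = "main")
    candidates <- list()
    if (!is.null(cand)) {
      cand$n_sites <- n_sites_main
      candidates$main <- cand
      hits_i <- scan(scoring_model(wi, cand$cutoff), promoters, window)
      if (nrow(hits_i) >= 2L) {
        variants <- length_variants(wi, hits_i, promoters, cfg$min_length)
        for (v in c("cl", "cr", "el", "er")) {
          vs <- variants[[v]]
          if (is.null(vs)) next
          if (matrix_type == "di" && vs$L < 5L) next
          if (vs$L < 4L) next
          wv <- tryCatch(build_matrix(matrix_type, vs, bg),
                         error = function(e) NULL)
          if (is.null(wv)) next
          cv <- grid_search_cutoff(wv, base_mat, ids, window, old_hits,
                                   n_p, cur_L, cfg,
                                   shift = VARIANT_SHIFT[[v]], label = v)
          if (!is.null(cv)) {
            cv$n_sites <- length(vs$sequences)
            candidates[[v]] <- cv
          }
        }
      }
    }
    if (length(candidates) == 0L) break
    # tie-breaks: unmodified length first, then shorter L, then the more
    # stringent cut-off (candidate order and strict improvement give this)
    ord <- order(vapply(candidates, `[[`, numeric(1L), "cor"),
                 decreasing = TRUE)
    best <- candidates[[ord[1L]]]
    for (k in ord[-1L]) {  # prefer main, then shorter L, on exact ties
      other <- candidates[[k]]
      if (abs(other$cor - best$cor) > 1e-12) break
      better_tie <- (other$label == "main" && best$label != "main") ||
        (best$label != "main" && other$label != "main" && other$L < best$L)
      if (better_tie) best <- other
    }
    if (best$cor <= prev_cor) break  # increase terminated
    model <- scoring_model(best$pwm, best$cutoff)
    trajectory <- rbind(trajectory,
                        data.frame(cycle = cycle, cor = best$cor,
                                   L = best$L, cutoff = best$cutoff,
                                   n_sites = best$n_sites))
    prev_cor <- best$cor
    if (isTRUE(cfg$rewindow)) {
      g <- cutoff_z_grid(model$matrix, promoters)
      wins <- detect_functional_windows(g, cfg$z_threshold,
                                        L = model$matrix$L)
      if (length(wins)) window <- wins[[1L]]
    }
    old_hits <- scan(model, promoters, window)
    if (prev_cor >= 1 - 1e-12) { converged <- TRUE; break }
    if (nrow(old_hits) == 0L) break
  }
  improved <- nrow(trajectory) > 0L
  if (!improved) {
    model <- scoring_model(w0, max(c0, min_score(w0)))
    old_hits <- scan(model, promoters, window)
  }
  final_hits <- scan(model, promoters, window)
  sites <- if (nrow(final_hits))
    site_set(extract_hit_sites(promoters, final_hits, model$matrix$L),
             source_labels = paste0(final_hits$promoter_id, ":",
                                    final_hits$start))
  else NULL
  structure(list(model = model, sites = sites, hits = final_hits,
                 trajectory = trajectory, window = window,
                 improved = improved, converged = converged),
            class = "refinement_result")
}

# Site sequences at hit positions (0-based starts), length L.
extract_hit_sites <- function(promoters, hits, L) {
  seqs <- promoters$sequences[match(hits$promoter_id, promoters$ids)]
  substr(seqs, hits$start + 1L, hits$start + L)
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("refinement_result\n")
  cat(sprintf("  window [%d, %d), final L = %d, cut-off = %.3f\n",
              x$window$start, x$window$end, x$model$matrix$L,
              x$model$cutoff))
  cat(sprintf("  %d cycle(s), final Cor = %s, converged (Cor = 1): %s\n",
              nrow(x$trajectory),
              if (nrow(x$trajectory))
                format(x$trajectory$cor[nrow(x$trajectory)], digits = 4)
              else "NA",
              x$converged))
  cat(sprintf("  %d discovered site(s)\n", nrow(x$hits)))
  invisible(x)
}
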