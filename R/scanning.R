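#' Scoring model: a PWM plus its matching cut-off
#'
#' The complete scoring suite <W, c>: a hit is any window whose matching
#' score is at or above the cut-off (closed comparison, so the consensus
#' always qualifies at c = 0).
#'
#' @param pwm a built PWM ([build_mono_pwm()] / [build_di_pwm()]).
#' @param cutoff non-positive matching cut-off, at or above the matrix's
#'   minimum achievable score.
#' @return an object of class `scoring_model`.
#' @export
scoring_model <- function(pwm, cutoff) {
  stopifnot(inherits(pwm, "pwm"), is.numeric(cutoff), length(cutoff) == 1L)
  if (cutoff > 0) stop("cut-off must be <= 0")
  if (is.finite(cutoff) && cutoff < min_score(pwm) - 1e-9)
    stop("cut-off below the minimum achievable score ",
         format(min_score(pwm)))
  structure(list(matrix = pwm, cutoff = as.numeric(cutoff)),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf("scoring_model <W, c>: L = %d, cut-off = %.3f\n",
              x$matrix$L, x$cutoff))
  invisible(x)
}

# Tie tolerance for the closed hit rule S >= c: scores within this of the
# cut-off count as hits, making boundary ties robust to floating-point
# accumulation order.
SCORE_TOL <- 1e-9

# Score matrix for all window starts: n_promoters x n_starts.
# starts are 0-based window start positions. Vectorised over promoters via
# integer-encoded sequence matrices; one gather per motif column.
score_matrix <- function(pwm, base_mat, starts) {
  n_p <- nrow(base_mat)
  idx_mat <- if (inherits(pwm, "di_pwm")) encode_dinuc_matrix(base_mat)
             else base_mat
  ncols <- ncol(pwm$weights)
  S <- matrix(0, nrow = n_p, ncol = length(starts))
  for (j in seq_len(ncols)) {
    cols <- starts + j  # 1-based column in idx_mat for 0-based start
    block <- idx_mat[, cols, drop = FALSE]
    S <- S + matrix(pwm$weights[cbind(as.vector(block), j)], nrow = n_p)
  }
  S
}

# Valid 0-based starts for motif length L, optionally restricted to a window.
window_starts <- function(promoter_length, L, window = NULL) {
  if (is.null(window)) return(0L:(promoter_length - L))
  stopifnot(inherits(window, "functional_window"))
  lo <- window$start
  hi <- window$end - L
  if (hi < lo) stop("window shorter than the motif length")
  lo:hi
}

#' Scan promoters with a scoring model
#'
#' Slides the motif window along each promoter (forward strand only) and
#' reports every (promoter, start) whose matching score is at or above the
#' cut-off. When a functional window is given, only starts whose full motif
#' lies inside the window are considered.
#'
#' @param model a [scoring_model()].
#' @param promoters a [promoter_set()].
#' @param window optional [functional_window()] restricting the scan.
#' @return a [hit_table()].
#' @export
scan <- function(model, promoters, window = NULL) {
  stopifnot(inherits(model, "scoring_model"),
            inherits(promoters, "promoter_set"))
  L <- model$matrix$L
  if (promoters$length < L) stop("promoters shorter than the motif")
  starts <- window_starts(promoters$length, L, window)
  bm <- encode_base_matrix(promoters$sequences)
  S <- score_matrix(model$matrix, bm, starts)
  hit <- which(S >= model$cutoff - SCORE_TOL, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(hit_table())
  ord <- order(hit[, 1L], hit[, 2L])
  hit <- hit[ord, , drop = FALSE]
  hit_table(promoter_id = promoters$ids[hit[, 1L]],
            start = starts[hit[, 2L]],
            score = S[hit])
}

#' Positional z-score profile of matrix hits (over-representation)
#'
#' For each window start position p, `O(p)` counts the promoters with a hit
#' starting at p. The expectation E is the mean of O over all positions and
#' sigma its population standard deviation; `z = (O - E) / sigma` measures
#' positional over-representation of hits on the TSS-aligned promoters.
#' When sigma is 0 the profile is identically 0.
#'
#' @param model a [scoring_model()].
#' @param promoters a [promoter_set()].
#' @return an object of class `positional_profile` with fields `O`, `E`,
#'   `sigma`, `z`, `positions` (0-based starts), `cutoff`, `L`.
#' @export
z_profile <- function(model, promoters) {
  stopifnot(inherits(model, "scoring_model"),
            inherits(promoters, "promoter_set"))
  L <- model$matrix$L
  starts <- window_starts(promoters$length, L)
  bm <- encode_base_matrix(promoters$sequences)
  S <- score_matrix(model$matrix, bm, starts)
  O <- colSums(S >= model$cutoff - SCORE_TOL)
  profile_from_counts(O, starts, model$cutoff, L)
}

profile_from_counts <- function(O, starts, cutoff, L) {
  E <- mean(O)
  sigma <- sqrt(mean((O - E)^2))
  z <- if (sigma == 0) rep(0, length(O)) else (O - E) / sigma
  structure(list(O = O, E = E, sigma = sigma, z = z,
                 positions = starts, cutoff = cutoff, L = L),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf(
    "positional_profile: %d positions, E = %.3f, sigma = %.3f, max z = %.2f\n",
    length(x$O), x$E, x$sigma, max(x$z)))
  invisible(x)
}

#' z-score grid over a range of matching cut-offs
#'
#' Computes the positional z-score profile at each cut-off of a descending
#' grid (one scan; scores are thresholded per cut-off). The resulting
#' cutoff x position matrix is the numerical form of the heat map used to
#' choose the initial cut-off and functional window.
#'
#' @param pwm a built PWM.
#' @param promoters a [promoter_set()].
#' @param cutoffs non-empty numeric vector of cut-offs, all <= 0. Default:
#'   0 down to the matrix's minimum achievable score in steps of 0.5.
#' @return an object of class `cutoff_z_grid` with fields `z` and `O`
#'   (matrices, one row per cut-off), `cutoffs`, `positions`, `L`.
#' @export
cutoff_z_grid <- function(pwm, promoters, cutoffs = NULL) {
  stopifnot(inherits(pwm, "pwm"), inherits(promoters, "promoter_set"))
  if (is.null(cutoffs)) cutoffs <- default_cutoff_grid(pwm)
  if (length(cutoffs) == 0L) stop("empty cut-off grid")
  if (any(cutoffs > 0)) stop("cut-offs must be <= 0")
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  starts <- window_starts(promoters$length, pwm$L)
  bm <- encode_base_matrix(promoters$sequences)
  S <- score_matrix(pwm, bm, starts)
  O <- t(vapply(cutoffs, function(cc) colSums(S >= cc - SCORE_TOL),
                numeric(length(starts))))
  Z <- t(apply(O, 1L, function(o) {
    pr <- profile_from_counts(o, starts, NA_real_, pwm$L)
    pr$z
  }))
  dimnames(O) <- dimnames(Z) <- list(format(cutoffs), NULL)
  structure(list(z = Z, O = O, cutoffs = cutoffs, positions = starts,
                 L = pwm$L),
            class = "cutoff_z_grid")
}

# Descending grid from 0 to the minimum achievable score in steps of `step`.
default_cutoff_grid <- function(pwm, step = 0.5) {
  lo <- min_score(pwm)
  unique(c(seq(0, lo, by = -step), lo))
}

#' @export
print.cutoff_z_grid <- function(x, ...) {
  cat(sprintf("cutoff_z_grid: %d cut-offs x %d positions, max z = %.2f\n",
              length(x$cutoffs), length(x$positions), max(x$z)))
  invisible(x)
}

#' Export a z-score grid as TSV (heat-map input)
#'
#' @param grid a [cutoff_z_grid()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_z_grid <- function(grid, path) {
  df <- data.frame(cutoff = grid$cutoffs, grid$z, check.names = FALSE)
  colnames(df) <- c("cutoff", sprintf("p%d", grid$positions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Most stringent cut-off sustaining a qualifying z-score
#'
#' The initial cut-off heuristic: the highest (most stringent) grid cut-off
#' at which some position reaches `z >= z_threshold`.
#'
#' @param grid a [cutoff_z_grid()] result.
#' @param z_threshold qualifying z-score (default 3).
#' @return scalar cut-off, or `NA` if no cut-off qualifies.
#' @export
initial_cutoff <- function(grid, z_threshold = 3) {
  qual <- apply(grid$z >= z_threshold, 1L, any)
  if (!any(qual)) return(NA_real_)
  max(grid$cutoffs[qual])
}

#' Detect functional windows from a cut-off x position z-score grid
#'
#' Follows the heat-map reading of the grid: the signal is the set of
#' positions whose z-score reaches the threshold within the contiguous run
#' of qualifying cut-offs that starts at the most stringent qualifying
#' cut-off (the run down to which the signal is "sustained"; qualifying
#' rows separated from that run by non-qualifying rows are saturation
#' noise and are ignored). The collected positions are fused into windows:
#' peaks closer than the motif length L merge into a single window
#' spanning both. Each window records its peak z and the range of run
#' cut-offs over which the peak persists. Windows driven by chance
#' outliers are harmless downstream: refinement evaluates every window and
#' keeps the one with the best optimised correlation.
#'
#' @param grid a [cutoff_z_grid()] result.
#' @param z_threshold qualifying z-score (default 3).
#' @param L motif length used for fusion and window extent (default: the
#'   grid's matrix length).
#' @return list of [functional_window()] objects (empty when nothing
#'   qualifies).
#' @export
detect_functional_windows <- function(grid, z_threshold = 3, L = grid$L) {
  qual <- apply(grid$z >= z_threshold, 1L, any)
  if (!any(qual)) return(list())
  # rows are ordered stringent -> permissive; keep the leading contiguous
  # qualifying run from the first qualifying row
  first <- which(qual)[1L]
  run_len <- which(!qual[first:length(qual)])[1L]
  run <- if (is.na(run_len)) first:length(qual)
         else first:(first + run_len - 2L)
  zrun <- grid$z[run, , drop = FALSE]
  hot <- apply(zrun >= z_threshold, 2L, any)
  peaks <- sort(grid$positions[hot])
  group <- cumsum(c(1L, diff(peaks) >= L))
  lapply(split(peaks, group), function(p) {
    cols <- match(p, grid$positions)
    zvals <- apply(zrun[, cols, drop = FALSE], 2L, max)
    peak_col <- cols[which.max(zvals)]
    persists <- grid$z[run, peak_col] >= z_threshold
    cr <- range(grid$cutoffs[run][persists])
    functional_window(start = min(p), end = max(p) + L,
                      peak_z = max(zvals), cutoff_range = cr)
  })
}
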