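#' Estimate the promoter background base and dinucleotide composition
#'
#' Pools base and overlapping-dinucleotide counts over all promoters within
#' `region` and returns position-independent expected fractions. The region
#' defaults to the whole promoter (the EPD-style -500..+100 area when the
#' promoters span it).
#'
#' @param promoters a [promoter_set()].
#' @param region 0-based half-open interval `c(start, end)` of promoter
#'   coordinates to count; `NULL` means the full length.
#' @return an object of class `pwm_background` with fields `e_b` (4 expected
#'   base fractions, order A,T,G,C), `e_d` (16 expected dinucleotide
#'   fractions, order AA..CC), `n_p`, `region`.
#' @export
estimate_background <- function(promoters, region = NULL) {
  stopifnot(inherits(promoters, "promoter_set"))
  len <- promoters$length
  if (is.null(region)) region <- c(0L, len)
  region <- as.integer(region)
  if (region[2L] <= region[1L]) stop("empty background region")
  if (region[1L] < 0L || region[2L] > len)
    stop("region must lie within promoter bounds")
  bm <- encode_base_matrix(promoters$sequences)
  bm <- bm[, (region[1L] + 1L):region[2L], drop = FALSE]
  base_counts <- tabulate(bm, nbins = 4L)
  e_b <- floor_frequencies(base_counts, 4L)
  names(e_b) <- DNA_BASES
  if (ncol(bm) >= 2L) {
    dm <- encode_dinuc_matrix(bm)
    di_counts <- tabulate(dm, nbins = 16L)
  } else {
    di_counts <- rep(0, 16L)
  }
  e_d <- floor_frequencies(di_counts, 16L)
  names(e_d) <- DINUCLEOTIDES
  structure(list(e_b = e_b, e_d = e_d, n_p = length(promoters$sequences),
                 region = region),
            class = "pwm_background")
}

# Counts -> fractions; zero cells are floored at 1/(total + k) with a
# warning, then the vector is renormalised to sum 1.
floor_frequencies <- function(counts, k) {
  total <- sum(counts)
  if (total == 0) return(rep(1 / k, k))
  f <- counts / total
  if (any(f == 0)) {
    warning("zero background frequency floored at 1/(total counts + ", k, ")")
    f[f == 0] <- 1 / (total + k)
    f <- f / sum(f)
  }
  f
}

#' @export
print.pwm_background <- function(x, ...) {
  cat(sprintf("pwm_background: %d promoters, region [%d, %d)\n",
              x$n_p, x$region[1L], x$region[2L]))
  cat("  e_b:", paste(sprintf("%s=%.3f", names(x$e_b), x$e_b),
                      collapse = " "), "\n")
  invisible(x)
}

# Shared core: counts (K x L) -> background-corrected, max-shifted weights.
# Laplace pseudocount s_i = 1 is applied only to columns containing a zero
# count (keeping the log argument positive and giving rare letters a finite
# weight); the per-column constant c_i subtracts the maximum raw weight so
# the best letter in every column scores exactly 0.
weights_from_counts <- function(counts, e, n_m) {
  K <- nrow(counts)
  s <- as.numeric(apply(counts, 2L, function(col) any(col == 0)))
  denom <- n_m + K * s
  p <- sweep(counts, 2L, s, "+")
  p <- sweep(p, 2L, denom, "/")
  raw <- log(p / e)
  shift <- apply(raw, 2L, max)
  w <- sweep(raw, 2L, shift, "-")
  list(weights = w, pseudo = s, shift = shift)
}

#' Build a background-corrected mononucleotide PWM
#'
#' Per column i and base b the weight is the corrected log-odds
#' `ln(p_bi / e_b) - c_i` with `p_bi = (n_bi + s_i) / (n_m + 4 s_i)`, where
#' `s_i = 1` for columns containing a zero count and 0 otherwise, and `c_i`
#' shifts the per-column maximum to 0 (so all weights are <= 0 and the
#' consensus scores 0).
#'
#' @param sites a [site_set()] with at least 2 members, length >= 4.
#' @param background a `pwm_background` from [estimate_background()].
#' @return an object of class `c("mono_pwm", "pwm")` with fields `weights`
#'   (4 x L), `counts`, `L`, `pseudo`, `shift`, `background`, `n_m`.
#' @examples
#' prom <- generate_promoters(20, 100, seed = 1)
#' bg <- estimate_background(prom)
#' pwm <- build_mono_pwm(site_set(c("ACGT", "ACGT", "ACGA")), bg)
#' @export
build_mono_pwm <- function(sites, background) {
  stopifnot(inherits(sites, "site_set"),
            inherits(background, "pwm_background"))
  n_m <- length(sites$sequences)
  if (n_m < 2L) stop("at least 2 sites required to build a matrix")
  if (sites$L < 4L) stop("motif length must be >= 4")
  bm <- encode_base_matrix(sites$sequences)
  counts <- vapply(seq_len(ncol(bm)),
                   function(j) tabulate(bm[, j], nbins = 4L),
                   numeric(4L))
  rownames(counts) <- DNA_BASES
  parts <- weights_from_counts(counts, background$e_b, n_m)
  structure(list(weights = parts$weights, counts = counts,
                 L = sites$L, pseudo = parts$pseudo, shift = parts$shift,
                 background = background, n_m = n_m),
            class = c("mono_pwm", "pwm"))
}

#' Build a background-corrected dinucleotide PWM
#'
#' As [build_mono_pwm()], but over the 16 overlapping dinucleotides at
#' positions i, i+1 (16 x (L-1) matrix, rows in the fixed order AA, AT, AG,
#' AC, TA, TT, TG, TC, GA, GT, GG, GC, CA, CT, CG, CC). The pseudocount
#' denominator uses the 16-letter alphabet, and expected fractions are the
#' pooled empirical promoter dinucleotide frequencies, so the model can
#' capture background neighbour dependence.
#'
#' @param sites a [site_set()] with at least 2 members, length >= 5.
#' @param background a `pwm_background`.
#' @return an object of class `c("di_pwm", "pwm")`; `L` is the nucleotide
#'   motif length, `weights` has `L - 1` columns.
#' @export
build_di_pwm <- function(sites, background) {
  stopifnot(inherits(sites, "site_set"),
            inherits(background, "pwm_background"))
  n_m <- length(sites$sequences)
  if (n_m < 2L) stop("at least 2 sites required to build a matrix")
  if (sites$L < 5L) stop("motif length must be >= 5 for a dinucleotide PWM")
  bm <- encode_base_matrix(sites$sequences)
  dm <- encode_dinuc_matrix(bm)
  counts <- vapply(seq_len(ncol(dm)),
                   function(j) tabulate(dm[, j], nbins = 16L),
                   numeric(16L))
  rownames(counts) <- DINUCLEOTIDES
  parts <- weights_from_counts(counts, background$e_d, n_m)
  structure(list(weights = parts$weights, counts = counts,
                 L = sites$L, pseudo = parts$pseudo, shift = parts$shift,
                 background = background, n_m = n_m),
            class = c("di_pwm", "pwm"))
}

#' @export
print.pwm <- function(x, ...) {
  kind <- if (inherits(x, "di_pwm")) "dinucleotide" else "mononucleotide"
  cat(sprintf("%s PWM: motif length %d, %d training sites\n",
              kind, x$L, x$n_m))
  invisible(x)
}

#' Minimum achievable matching score of a matrix
#'
#' The sum of per-column minimum weights; the score of any sequence lies in
#' `[min_score(pwm), 0]`.
#'
#' @param pwm a built PWM.
#' @return a non-positive scalar.
#' @export
min_score <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  sum(apply(pwm$weights, 2L, min))
}

#' Score a single sequence against a PWM
#'
#' The matching score S(seq) is the sum of the selected per-column weights:
#' for a mononucleotide PWM the weight of the base at each position, for a
#' dinucleotide PWM the weight of each overlapping dinucleotide. Scores are
#' always <= 0 and equal 0 exactly when the sequence realises a per-column
#' maximum at every column.
#'
#' @param pwm a built PWM.
#' @param seq DNA string of length `pwm$L`.
#' @return scalar score.
#' @export
score_site <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm"), is.character(seq), length(seq) == 1L)
  if (nchar(seq) != pwm$L)
    stop("sequence length ", nchar(seq), " != motif length ", pwm$L)
  b <- encode_base_matrix(seq)[1L, ]
  idx <- if (inherits(pwm, "di_pwm")) {
    dinuc_index(b[-length(b)], b[-1L])
  } else b
  sum(pwm$weights[cbind(idx, seq_along(idx))])
}

#' Consensus sequence of a PWM
#'
#' The sequence realising the per-column maximum weight at every column
#' (score 0). For dinucleotide matrices the consensus of the underlying
#' nucleotide counts is returned.
#'
#' @param pwm a built PWM.
#' @return DNA string of length `pwm$L`.
#' @export
pwm_consensus <- function(pwm) {
  if (inherits(pwm, "di_pwm")) {
    # chain the maximal dinucleotides greedily from the left
    first <- which.max(pwm$weights[, 1L])
    b <- c((first - 1L) %/% 4L + 1L, (first - 1L) %% 4L + 1L)
    if (ncol(pwm$weights) >= 2L) {
      for (j in 2L:ncol(pwm$weights)) {
        prev <- b[length(b)]
        cand <- dinuc_index(prev, 1:4)
        b <- c(b, which.max(pwm$weights[cand, j]))
      }
    }
    paste(DNA_BASES[b], collapse = "")
  } else {
    paste(DNA_BASES[apply(pwm$weights, 2L, which.max)], collapse = "")
  }
}

#' Per-column information content of aligned sites
#'
#' `IC_i = 2 + sum_b f_bi log2 f_bi` (bits, with 0 log 0 = 0), together with
#' the per-base contributions `f_bi * IC_i` used for sequence-logo export.
#' No small-sample correction is applied.
#'
#' @param sites a [site_set()].
#' @return list with `ic` (length-L vector in `[0, 2]`) and `contributions`
#'   (4 x L matrix, rows A,T,G,C).
#' @export
information_content <- function(sites) {
  stopifnot(inherits(sites, "site_set"))
  bm <- encode_base_matrix(sites$sequences)
  n <- nrow(bm)
  f <- vapply(seq_len(ncol(bm)),
              function(j) tabulate(bm[, j], nbins = 4L) / n,
              numeric(4L))
  rownames(f) <- DNA_BASES
  plogp <- ifelse(f > 0, f * log2(f), 0)
  ic <- 2 + colSums(plogp)
  contributions <- sweep(f, 2L, ic, "*")
  list(ic = ic, contributions = contributions)
}

#' Export an information-content matrix as TSV
#'
#' Writes the per-base logo contributions (rows A,T,G,C) with a final `IC`
#' row, one column per motif position, consumable by logo-drawing tools.
#'
#' @param sites a [site_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ic_table <- function(sites, path) {
  icr <- information_content(sites)
  tab <- rbind(icr$contributions, IC = icr$ic)
  df <- data.frame(base = rownames(tab), tab, check.names = FALSE)
  colnames(df) <- c("base", sprintf("pos%d", seq_along(icr$ic)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-column base (or dinucleotide) frequency matrix of a site set
#'
#' @param sites a [site_set()].
#' @return 4 x L matrix of per-column base fractions (rows A,T,G,C).
#' @export
site_frequency_matrix <- function(sites) {
  stopifnot(inherits(sites, "site_set"))
  bm <- encode_base_matrix(sites$sequences)
  f <- vapply(seq_len(ncol(bm)),
              function(j) tabulate(bm[, j], nbins = 4L) / nrow(bm),
              numeric(4L))
  rownames(f) <- DNA_BASES
  f
}
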