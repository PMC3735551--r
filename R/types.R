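#' TSS-aligned promoter set
#'
#' A set of equal-length, gap-free DNA sequences aligned on the transcription
#' start site (TSS). Internal coordinates are 0-based, half-open; a promoter
#' position `p` corresponds to TSS-relative position `p - tss_offset`.
#'
#' @param sequences character vector of equal-length uppercase DNA strings
#'   over \{A,C,G,T\}.
#' @param tss_offset 0-based index of the TSS within each sequence. The
#'   default places the TSS so that sequences span -(len-101)..+100, the
#'   EPD-style window (600 nt -> -499..+100, `tss_offset = 499`).
#' @param ids one identifier per sequence (generated when `NULL`).
#' @return an object of class `promoter_set` with fields `sequences`,
#'   `tss_offset`, `ids`, `length`.
#' @export
promoter_set <- function(sequences, tss_offset = NULL, ids = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("empty promoter set")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("promoter sequences must have equal length")
  if (any(grepl("[^ACGT]", sequences)))
    stop("promoter sequences must contain only A, C, G, T")
  if (is.null(tss_offset)) tss_offset <- max(0L, len - 101L)
  tss_offset <- as.integer(tss_offset)
  if (tss_offset < 0L || tss_offset >= len)
    stop("tss_offset must lie within the sequence")
  if (is.null(ids)) ids <- sprintf("prom_%04d", seq_along(sequences))
  if (length(ids) != length(sequences)) stop("one id per sequence required")
  structure(list(sequences = sequences, tss_offset = tss_offset,
                 ids = as.character(ids), length = len),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d sequences x %d nt (TSS at index %d)\n",
              length(x$sequences), x$length, x$tss_offset))
  invisible(x)
}

#' @export
length.promoter_set <- function(x) length(x$sequences)

#' Aligned binding-site set
#'
#' Equal-length, gap-free aligned transcription-factor binding sites, the
#' training material for matrix construction.
#'
#' @param sequences character vector of equal-length uppercase DNA strings.
#' @param source_labels optional provenance strings, one per site.
#' @return an object of class `site_set` with fields `sequences`, `L`,
#'   `source_labels`.
#' @export
site_set <- function(sequences, source_labels = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("empty site set")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("site sequences must have identical length")
  if (any(grepl("[^ACGT]", sequences)))
    stop("sites must be gap-free and contain only A, C, G, T")
  if (!is.null(source_labels) && length(source_labels) != length(sequences))
    stop("one source label per site required")
  structure(list(sequences = sequences, L = as.integer(L),
                 source_labels = source_labels),
            class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set: %d sites of length %d\n",
              length(x$sequences), x$L))
  invisible(x)
}

#' @export
length.site_set <- function(x) length(x$sequences)

#' Hit table
#'
#' One row per matrix hit: promoter identifier, 0-based start of the motif's
#' first nucleotide, matching score, and strand (always "+"; only the forward
#' strand is scanned).
#'
#' @param promoter_id character vector.
#' @param start integer vector of 0-based starts.
#' @param score numeric vector of finite scores.
#' @return a `data.frame` of class `hit_table`.
#' @export
hit_table <- function(promoter_id = character(), start = integer(),
                      score = numeric()) {
  stopifnot(length(promoter_id) == length(start),
            length(start) == length(score))
  if (length(score) && any(!is.finite(score))) stop("scores must be finite")
  if (length(start) && any(start < 0L)) stop("starts must be >= 0")
  out <- data.frame(promoter_id = as.character(promoter_id),
                    start = as.integer(start),
                    score = as.numeric(score),
                    strand = rep("+", length(start)),
                    stringsAsFactors = FALSE)
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Functional window on TSS-aligned promoter coordinates
#'
#' An interval (0-based, half-open) where matrix hits are over-represented
#' (positional z-score at or above threshold).
#'
#' @param start,end 0-based half-open interval bounds.
#' @param peak_z z-score of the strongest peak inside the window.
#' @param cutoff_range numeric length-2 vector, the cut-off range over which
#'   the peak signal persists.
#' @return an object of class `functional_window`.
#' @export
functional_window <- function(start, end, peak_z = NA_real_,
                              cutoff_range = c(NA_real_, NA_real_)) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("window end must exceed start")
  structure(list(start = start, end = end, peak_z = peak_z,
                 cutoff_range = cutoff_range),
            class = "functional_window")
}

#' @export
print.functional_window <- function(x, ...) {
  cat(sprintf("functional_window: [%d, %d) peak z = %.2f, cut-offs [%s, %s]\n",
              x$start, x$end, x$peak_z,
              format(x$cutoff_range[1]), format(x$cutoff_range[2])))
  invisible(x)
}

#' Confusion-matrix counts
#'
#' TP/FP/FN/TN counts under either the refinement-iteration convention
#' (hits of the previous matrix are "true") or the synthetic-test convention
#' (planted motifs are "true").
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param convention `"iteration"` or `"test"`.
#' @param ... further fields stored on the object (e.g. `test_size`,
#'   `n_total`).
#' @return an object of class `confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn, convention = "iteration", ...) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(list(TP = as.numeric(tp), FP = as.numeric(fp),
                 FN = as.numeric(fn), TN = as.numeric(tn),
                 convention = convention, ...),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion (%s): TP=%g FP=%g FN=%g TN=%g\n",
              x$convention, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}
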