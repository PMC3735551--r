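#' Generate i.i.d. random promoter sequences
#'
#' Emulates a TSS-aligned promoter substrate (EPD-style: 600-nt sequences
#' spanning -499..+100 by default) with an independent-base background
#' model. Fully reproducible under a seed.
#'
#' @param n number of promoters.
#' @param length sequence length in nt (default 600).
#' @param background length-4 base fractions in order A, T, G, C (default
#'   uniform), or `"uniform"`.
#' @param seed optional integer seed.
#' @param tss_offset passed to [promoter_set()].
#' @return a [promoter_set()].
#' @examples
#' prom <- generate_promoters(10, 600, seed = 42)
#' @export
generate_promoters <- function(n, length = 600L,
                               background = c(0.25, 0.25, 0.25, 0.25),
                               seed = NULL, tss_offset = NULL) {
  stopifnot(n > 0, length > 0)
  background <- normalize_background(background)
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(sample(DNA_BASES, n * length, replace = TRUE,
                       prob = background),
                nrow = n)
  seqs <- apply(mat, 1L, paste, collapse = "")
  promoter_set(seqs, tss_offset = tss_offset)
}

normalize_background <- function(background) {
  if (identical(background, "uniform")) background <- rep(0.25, 4L)
  background <- as.numeric(background)
  if (length(background) != 4L || any(background < 0) ||
      sum(background) <= 0)
    stop("background must be 4 non-negative base fractions (A, T, G, C)")
  background / sum(background)
}

#' Build a consensus-biased frequency matrix
#'
#' Convenience generator for planted-motif fixtures: the consensus base of
#' each column carries probability `consensus_prob`, the rest is split
#' evenly among the other three bases.
#'
#' @param consensus DNA string.
#' @param consensus_prob probability of the consensus base per column
#'   (default 0.7).
#' @return 4 x L column-stochastic matrix, rows A, T, G, C.
#' @export
consensus_frequency_matrix <- function(consensus, consensus_prob = 0.7) {
  b <- encode_base_matrix(consensus)[1L, ]
  f <- matrix((1 - consensus_prob) / 3, nrow = 4L, ncol = length(b),
              dimnames = list(DNA_BASES, NULL))
  f[cbind(b, seq_along(b))] <- consensus_prob
  f
}

#' Plant motif instances into promoters
#'
#' Overwrites, in a `plant_rate` fraction of the promoters, a site sampled
#' column-wise from `frequency_matrix` at a uniform-random offset within
#' `offset_window`. Every insertion is recorded in the truth table.
#'
#' @param promoters a [promoter_set()].
#' @param frequency_matrix 4 x L column-stochastic matrix (rows A, T, G, C;
#'   columns are normalised if needed).
#' @param offset_window integer `c(lo, hi)`: inclusive range of 0-based
#'   start offsets.
#' @param plant_rate fraction of promoters receiving a site (0 < rate <= 1).
#' @param seed optional integer seed.
#' @return list with `promoters` (modified [promoter_set()]) and `truth`
#'   (data.frame: promoter_id, start, length, site).
#' @export
plant_motif <- function(promoters, frequency_matrix, offset_window,
                        plant_rate, seed = NULL) {
  stopifnot(inherits(promoters, "promoter_set"),
            plant_rate > 0, plant_rate <= 1)
  f <- sweep(frequency_matrix, 2L, colSums(frequency_matrix), "/")
  L <- ncol(f)
  offset_window <- as.integer(offset_window)
  if (offset_window[1L] < 0L ||
      offset_window[2L] + L > promoters$length)
    stop("motif does not fit inside the offset window")
  if (!is.null(seed)) set.seed(seed)
  n <- length(promoters$sequences)
  n_plant <- max(1L, round(plant_rate * n))
  chosen <- sort(sample.int(n, n_plant))
  seqs <- promoters$sequences
  # sample.int avoids sample()'s scalar-range surprise when lo == hi
  starts <- offset_window[1L] +
    sample.int(offset_window[2L] - offset_window[1L] + 1L, n_plant,
               replace = TRUE) - 1L
  sites <- vapply(seq_len(n_plant), function(i) {
    paste(vapply(seq_len(L),
                 function(j) sample(DNA_BASES, 1L, prob = f[, j]),
                 character(1L)),
          collapse = "")
  }, character(1L))
  for (i in seq_len(n_plant)) {
    k <- chosen[i]
    substr(seqs[k], starts[i] + 1L, starts[i] + L) <- sites[i]
  }
  truth <- data.frame(promoter_id = promoters$ids[chosen],
                      start = starts, length = L, site = sites,
                      stringsAsFactors = FALSE)
  list(promoters = promoter_set(seqs, tss_offset = promoters$tss_offset,
                                ids = promoters$ids),
       truth = truth)
}

#' Aligned site collection with flanking context
#'
#' JASPAR-style sites: each sequence may be longer than the aligned motif
#' block; `block_start` gives the 0-based offset of the aligned block
#' within each sequence and `block_length` its common length.
#'
#' @param sequences character vector of (possibly unequal-length) DNA
#'   strings.
#' @param block_start integer vector of 0-based aligned-block offsets, one
#'   per sequence.
#' @param block_length common length of the aligned block.
#' @return an object of class `aligned_sites`.
#' @export
aligned_sites <- function(sequences, block_start, block_length) {
  sequences <- toupper(as.character(sequences))
  block_start <- as.integer(block_start)
  block_length <- as.integer(block_length)
  stopifnot(length(block_start) == length(sequences), block_length >= 1L)
  if (any(grepl("[^ACGT]", sequences)))
    stop("sites must contain only A, C, G, T")
  if (any(block_start < 0L) ||
      any(block_start + block_length > nchar(sequences)))
    stop("aligned block must lie within each site sequence")
  structure(list(sequences = sequences, block_start = block_start,
                 block_length = block_length),
            class = "aligned_sites")
}

#' Build a synthetic test by embedding aligned sites in random padding
#'
#' Each site sequence (aligned block plus its unaligned flanks, preserved
#' verbatim) is embedded into equally-distributed random nucleotides so
#' that its aligned block starts at `insert_position` in every test
#' sequence; padding extends both ends to `total_length`.
#'
#' @param sites an [aligned_sites()] collection.
#' @param insert_position 0-based position of the aligned block in every
#'   output sequence (default 27).
#' @param total_length output sequence length (default 300).
#' @param background padding base fractions (default uniform).
#' @param seed optional integer seed.
#' @return an object of class `synthetic_test`: `sequences`, `truth`
#'   (data.frame: id, insert_start, motif_length), `seq_length`, `pad`
#'   (data.frame of 0-based half-open padding regions per sequence),
#'   `replicate_id` (0 for the source test), `seed`.
#' @export
build_site_test <- function(sites, insert_position = 27L,
                            total_length = 300L,
                            background = c(0.25, 0.25, 0.25, 0.25),
                            seed = NULL) {
  stopifnot(inherits(sites, "aligned_sites"))
  insert_position <- as.integer(insert_position)
  total_length <- as.integer(total_length)
  background <- normalize_background(background)
  if (!is.null(seed)) set.seed(seed)
  n <- length(sites$sequences)
  site_len <- nchar(sites$sequences)
  left_pad <- insert_position - sites$block_start
  if (any(left_pad < 0L))
    stop("insert_position is left of an aligned block offset")
  if (any(left_pad + site_len > total_length))
    stop("site longer than the test sequence")
  right_pad <- total_length - left_pad - site_len
  seqs <- character(n)
  for (i in seq_len(n)) {
    lp <- paste(sample(DNA_BASES, left_pad[i], replace = TRUE,
                       prob = background), collapse = "")
    rp <- paste(sample(DNA_BASES, right_pad[i], replace = TRUE,
                       prob = background), collapse = "")
    seqs[i] <- paste0(lp, sites$sequences[i], rp)
  }
  ids <- sprintf("test_%04d", seq_len(n))
  truth <- data.frame(id = ids, insert_start = insert_position,
                      motif_length = sites$block_length,
                      stringsAsFactors = FALSE)
  pad <- data.frame(id = ids,
                    left_start = 0L, left_end = left_pad,
                    right_start = left_pad + site_len,
                    right_end = total_length,
                    stringsAsFactors = FALSE)
  structure(list(sequences = seqs, truth = truth,
                 seq_length = total_length, pad = pad,
                 replicate_id = 0L, seed = seed),
            class = "synthetic_test")
}

#' @export
print.synthetic_test <- function(x, ...) {
  cat(sprintf(
    "synthetic_test: %d sequences x %d nt, block at %d (replicate %d)\n",
    length(x$sequences), x$seq_length, x$truth$insert_start[1L],
    x$replicate_id))
  invisible(x)
}

#' Background-reshuffled replicates of a synthetic test
#'
#' Produces `n_replicates` copies of a test in which only the random
#' padding is permuted (`n_shuffles` successive permutations of the
#' padding characters); the embedded sites and their unaligned flanks are
#' preserved verbatim at the same coordinates, and the padding base
#' composition is conserved exactly. Per-replicate random streams are
#' derived deterministically from the master seed and the replicate index.
#'
#' @param test a [build_site_test()] result.
#' @param n_replicates number of replicates (default 10).
#' @param n_shuffles successive permutations per replicate (default 30).
#' @param seed master integer seed.
#' @return list of `synthetic_test` objects with `replicate_id` 1..n.
#' @export
reshuffle_replicates <- function(test, n_replicates = 10L,
                                 n_shuffles = 30L, seed = 1L) {
  stopifnot(inherits(test, "synthetic_test"))
  lapply(seq_len(n_replicates), function(r) {
    set.seed((seed %% 100000L) * 1000L + r)
    seqs <- test$sequences
    for (i in seq_along(seqs)) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      p <- test$pad[i, ]
      pad_idx <- c(if (p$left_end > p$left_start)
                     (p$left_start + 1L):p$left_end,
                   if (p$right_end > p$right_start)
                     (p$right_start + 1L):p$right_end)
      if (length(pad_idx) > 1L) {
        pad_chars <- chars[pad_idx]
        for (k in seq_len(n_shuffles)) pad_chars <- sample(pad_chars)
        chars[pad_idx] <- pad_chars
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    out <- test
    out$sequences <- seqs
    out$replicate_id <- r
    out$seed <- seed
    out
  })
}
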