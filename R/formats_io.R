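#' Read a FASTA file as a promoter set or site set
#'
#' Sequences are uppercased on load. For promoter sets, records containing
#' unknown nucleotides (`n`/`N`) are dropped and the number of dropped
#' records is reported via `message()`; for site sets any non-ACGT character
#' is an error (sites must be gap-free and unambiguous).
#'
#' @param path FASTA file path.
#' @param what `"promoters"` or `"sites"`.
#' @param tss_offset passed to [promoter_set()] (default: EPD-style).
#' @return a [promoter_set()] or [site_set()] in file order.
#' @export
read_fasta <- function(path, what = c("promoters", "sites"),
                       tss_offset = NULL) {
  what <- match.arg(what)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (what == "promoters") {
    has_n <- grepl("N", seqs, fixed = TRUE)
    if (any(has_n)) {
      message(sum(has_n), " record(s) containing unknown nucleotides (N) ",
              "dropped on load")
      seqs <- seqs[!has_n]
      ids <- ids[!has_n]
    }
    if (length(seqs) == 0L) stop("no usable records in ", path)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- ids[lens != lens[1L]][1L]
      stop("unequal sequence lengths; offending record: ", bad)
    }
    promoter_set(seqs, tss_offset = tss_offset, ids = ids)
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- ids[lens != lens[1L]][1L]
      stop("unequal sequence lengths; offending record: ", bad)
    }
    site_set(seqs, source_labels = ids)
  }
}

#' Write sequences to FASTA
#'
#' @param x a [promoter_set()], [site_set()], or named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "promoter_set")) {
    seqs <- x$sequences; ids <- x$ids
  } else if (inherits(x, "site_set")) {
    seqs <- x$sequences
    ids <- x$source_labels
    if (is.null(ids)) ids <- sprintf("site_%04d", seq_along(seqs))
  } else {
    seqs <- as.character(x)
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq_%04d", seq_along(seqs))
  }
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a nucleotide count matrix (TRANSFAC-style or JASPAR PFM)
#'
#' Counts are returned in the fixed row order A, T, G, C regardless of the
#' column/row order used in the file.
#'
#' TRANSFAC dialect: an optional `AC`/`NA` metadata line, a `P0` (or `PO`)
#' header naming the four column letters, then numbered rows of four counts
#' (an optional trailing consensus letter is ignored). JASPAR PFM dialect:
#' an optional `>` header, then four rows, each optionally prefixed by its
#' base letter and with counts optionally bracketed.
#'
#' @param path file path.
#' @param dialect `"transfac"` or `"jaspar_pfm"`.
#' @return list with `counts` (4 x L numeric matrix, rownames A,T,G,C),
#'   `accession`, `name`.
#' @export
read_matrix_table <- function(path, dialect = c("transfac", "jaspar_pfm")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  if (dialect == "transfac") {
    acc <- NA_character_; nm <- NA_character_
    ac_line <- grep("^AC\\s", lines, value = TRUE)
    if (length(ac_line)) acc <- trimws(sub("^AC\\s+", "", ac_line[1L]))
    na_line <- grep("^NA\\s", lines, value = TRUE)
    if (length(na_line)) nm <- trimws(sub("^NA\\s+", "", na_line[1L]))
    hdr <- grep("^P[O0]\\b", lines)
    if (length(hdr) != 1L) stop("TRANSFAC table needs exactly one P0 header")
    cols <- strsplit(trimws(sub("^P[O0]", "", lines[hdr])), "\\s+")[[1L]]
    if (!setequal(cols, DNA_BASES))
      stop("P0 header must name the four bases A, C, G, T")
    rows <- grep("^[0-9]+\\s", lines)
    rows <- rows[rows > hdr]
    if (length(rows) == 0L) stop("no count rows found")
    parse_row <- function(line) {
      parts <- strsplit(trimws(line), "\\s+")[[1L]][-1L]
      # drop a trailing consensus letter if present
      if (grepl("^[A-Za-z]+$", parts[length(parts)]))
        parts <- parts[-length(parts)]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 4L || anyNA(vals))
        stop("malformed count row: ", line)
      vals
    }
    counts_file <- vapply(lines[rows], parse_row, numeric(4L))
    counts <- counts_file[match(DNA_BASES, cols), , drop = FALSE]
  } else {
    body <- lines[!grepl("^>", lines)]
    acc <- NA_character_; nm <- NA_character_
    hdr <- grep("^>", lines, value = TRUE)
    if (length(hdr)) {
      parts <- strsplit(sub("^>", "", hdr[1L]), "\\s+")[[1L]]
      acc <- parts[1L]
      if (length(parts) > 1L) nm <- paste(parts[-1L], collapse = " ")
    }
    if (length(body) != 4L) stop("JASPAR PFM needs exactly 4 count rows")
    letters_file <- character(4L)
    vals <- vector("list", 4L)
    for (i in seq_len(4L)) {
      line <- gsub("[][]", " ", body[i])
      parts <- strsplit(trimws(line), "\\s+")[[1L]]
      if (grepl("^[ACGT]$", parts[1L])) {
        letters_file[i] <- parts[1L]
        parts <- parts[-1L]
      }
      vals[[i]] <- suppressWarnings(as.numeric(parts))
      if (anyNA(vals[[i]])) stop("malformed count row: ", body[i])
    }
    lens <- lengths(vals)
    if (length(unique(lens)) != 1L) stop("ragged count rows")
    counts_file <- do.call(rbind, vals)
    if (all(nzchar(letters_file))) {
      if (!setequal(letters_file, DNA_BASES))
        stop("row letters must be A, C, G, T")
      counts <- counts_file[match(DNA_BASES, letters_file), , drop = FALSE]
    } else {
      # unlabelled PFMs are A, C, G, T by convention
      counts <- counts_file[match(DNA_BASES, c("A", "C", "G", "T")),
                            , drop = FALSE]
    }
  }
  if (any(counts < 0)) stop("negative counts in matrix table")
  dimnames(counts) <- list(DNA_BASES, NULL)
  list(counts = counts, accession = acc, name = nm)
}

#' Write a count matrix in TRANSFAC-style or JASPAR-PFM form
#'
#' @param counts 4 x L numeric matrix with rownames A, T, G, C (any row
#'   order; rows are looked up by name).
#' @param path output file path.
#' @param dialect `"transfac"` or `"jaspar_pfm"`.
#' @param accession,name metadata strings.
#' @return `path`, invisibly.
#' @export
write_matrix_table <- function(counts, path,
                               dialect = c("transfac", "jaspar_pfm"),
                               accession = "NA0000", name = "unknown") {
  dialect <- match.arg(dialect)
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (dialect == "transfac") {
    # TRANSFAC files conventionally list columns A C G T
    ord <- c("A", "C", "G", "T")
    lines <- c(paste("AC", accession),
               "XX",
               paste("NA", name),
               "XX",
               paste(c("P0", ord), collapse = "\t"))
    for (j in seq_len(ncol(counts))) {
      lines <- c(lines, paste(c(sprintf("%02d", j),
                                format(counts[ord, j], trim = TRUE)),
                              collapse = "\t"))
    }
    lines <- c(lines, "XX", "//")
  } else {
    lines <- paste0(">", accession, " ", name)
    for (b in c("A", "C", "G", "T")) {
      lines <- c(lines, paste(b, "[",
                              paste(format(counts[b, ], trim = TRUE),
                                    collapse = " "), "]"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a hit table as TSV
#'
#' Tab-separated, one row per hit, with a header comment documenting the
#' 0-based start convention.
#'
#' @param hits a [hit_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# start coordinates are 0-based (first promoter position = 0)",
             con)
  writeLines(paste(c("promoter_id", "start", "score", "strand"),
                   collapse = "\t"), con)
  if (nrow(hits)) {
    body <- paste(hits$promoter_id, hits$start,
                  format(hits$score, digits = 17, trim = TRUE),
                  hits$strand, sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a hit table written by [write_hits_table()]
#'
#' @param path TSV file path.
#' @return a [hit_table()].
#' @export
read_hits_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric",
                                         "character"))
  hit_table(df$promoter_id, df$start, df$score)
}
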