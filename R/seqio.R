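#' Sequence records
#'
#' A `seq_record` is a named DNA sequence over `{A,C,G,T,N}` with optional
#' per-base Phred quality scores. Collections of records are plain lists.
#'
#' @param id record identifier (non-empty string).
#' @param seq DNA sequence string; lowercase is accepted and uppercased.
#' @param qual optional integer vector of Phred scores, one per base.
#' @return An object of class `seq_record` with fields `id`, `seq`, `qual`.
#' @examples
#' r <- seq_record("r1", "acgtACGT")
#' r$seq
#' @export
seq_record <- function(id, seq, qual = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("seq_record '", id, "': illegal character in sequence")
  if (!is.null(qual)) {
    qual <- as.integer(qual)
    if (length(qual) != nchar(seq))
      stop("seq_record '", id, "': quality length ", length(qual),
           " != sequence length ", nchar(seq))
  }
  structure(list(id = id, seq = seq, qual = qual), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record>", x$id, " (", nchar(x$seq), " bp",
      if (!is.null(x$qual)) ", with qualities", ")\n", sep = "")
  invisible(x)
}

record_lengths <- function(records) {
  vapply(records, function(r) nchar(r$seq), integer(1))
}

#' Read and write FASTA
#'
#' FASTA IO is backed by Biostrings; sequences are uppercased on read and
#' wrapped at 80 columns on write.
#'
#' @param path file path (plain or gzip).
#' @return `read_fasta()`: a list of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  mapply(function(i, s) seq_record(i, s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @param records list of [seq_record] objects.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(x) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read and write FASTQ (Sanger Phred+33)
#'
#' The reader validates the 4-line record structure explicitly so that a
#' malformed file fails with an error naming the offending record and line
#' rather than being silently misread.
#'
#' @param path file path (plain or gzip).
#' @return `read_fastq()`: a list of [seq_record] objects with qualities.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) return(list())
  if (length(lines) %% 4L != 0L)
    stop("FASTQ '", path, "': line count ", length(lines),
         " is not a multiple of 4")
  n <- length(lines) %/% 4L
  out <- vector("list", n)
  for (r in seq_len(n)) {
    ln <- (r - 1L) * 4L + 1L
    hdr <- lines[ln]
    if (!startsWith(hdr, "@"))
      stop("FASTQ '", path, "', line ", ln, ": expected '@' header")
    id <- sub("\\s.*$", "", substring(hdr, 2L))
    sq <- toupper(lines[ln + 1L])
    if (!startsWith(lines[ln + 2L], "+"))
      stop("FASTQ '", path, "', line ", ln + 2L,
           ": expected '+' separator in record '", id, "'")
    ql <- lines[ln + 3L]
    if (nchar(ql) != nchar(sq))
      stop("FASTQ '", path, "', line ", ln + 3L, ": record '", id,
           "' quality length ", nchar(ql),
           " != sequence length ", nchar(sq))
    if (grepl("[^ACGTN]", sq))
      stop("FASTQ '", path, "', line ", ln + 1L, ": record '", id,
           "' has illegal sequence characters")
    qual <- as.integer(charToRaw(ql)) - 33L
    if (any(qual < 0L | qual > 93L))
      stop("FASTQ '", path, "', line ", ln + 3L, ": record '", id,
           "' quality outside Phred+33 range")
    out[[r]] <- seq_record(id, sq, qual)
  }
  out
}

#' @param records list of [seq_record]; records lacking qualities are
#'   written with a constant placeholder quality of 30.
#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (r in records) {
    q <- r$qual
    if (is.null(q)) q <- rep.int(30L, nchar(r$seq))
    writeLines(c(paste0("@", r$id), r$seq, "+",
                 rawToChar(as.raw(q + 33L))), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement; `revcomp(revcomp(s))` is `s`.
#' @examples
#' revcomp("AAAC") # "GTTT"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(seq)
  if (grepl("[^ACGTNacgtn]", seq)) stop("revcomp: illegal character")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC fraction
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from the denominator.
#'
#' @param seq DNA string.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  d <- Biostrings::DNAString(toupper(seq))
  f <- Biostrings::letterFrequency(d, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0L) stop("gc_fraction: no A/C/G/T bases")
  unname((f[["C"]] + f[["G"]]) / denom)
}

#' Write intervals as BED6
#'
#' Intervals use 0-based half-open coordinates throughout the package,
#' matching BED on disk.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `name`, and
#'   optionally `score` and `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(df)))
  if (is.null(df$score)) df$score <- 0L
  if (is.null(df$strand)) df$strand <- "+"
  out <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[seq_len(min(6L, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(df)))]
  df
}
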