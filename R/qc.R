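# Read-level and contig-level QC observables: length statistics, GC
# distributions with a fitted normal, per-position quality summaries, and
# coverage profiles with a depth histogram.

#' Read length statistics
#'
#' N50 is the largest length L such that reads of length >= L contain at
#' least half of all sequenced bases (length-weighted, not a median).
#'
#' @param reads list of [seq_record] objects, or an integer vector of
#'   lengths.
#' @return object of class `read_stats`: `n_reads`, `n_bases`,
#'   `mean_length`, `n50_length`, `max_length`.
#' @export
read_stats <- function(reads) {
  lens <- if (is.numeric(reads)) as.integer(reads) else record_lengths(reads)
  if (length(lens) == 0L) stop("read_stats: no reads")
  if (any(lens <= 0L)) stop("read_stats: non-positive read length")
  total <- sum(as.numeric(lens))
  sl <- sort(lens, decreasing = TRUE)
  csum <- cumsum(as.numeric(sl))
  n50 <- sl[which(csum >= total / 2)[1L]]
  structure(list(n_reads = length(lens), n_bases = total,
                 mean_length = total / length(lens),
                 n50_length = n50, max_length = max(lens)),
            class = "read_stats")
}

#' @export
print.read_stats <- function(x, ...) {
  cat(sprintf(paste0("<read_stats> %d reads, %.0f bases, mean %.1f, ",
                     "N50 %d, max %d\n"),
              x$n_reads, x$n_bases, x$mean_length, x$n50_length,
              x$max_length))
  invisible(x)
}

#' Per-read GC distribution with fitted normal
#'
#' Computes the per-read GC fraction, optionally split by a label
#' partition (e.g. repeat region vs the rest, assigned by probe hit), and
#' fits a normal by sample mean and standard deviation per label.
#'
#' @param reads list of [seq_record] objects.
#' @param region_labels optional character vector, one label per read.
#' @param breaks histogram breaks passed to [graphics::hist()] semantics
#'   (computed with `hist(plot = FALSE)`).
#' @return data frame with one row per label: `label`, `n`, `mean`, `sd`,
#'   plus attribute `gc` holding the per-read fractions by label.
#' @export
gc_distribution <- function(reads, region_labels = NULL, breaks = 30) {
  stopifnot(length(reads) > 0L)
  gc <- vapply(reads, function(r) gc_fraction(r$seq), numeric(1))
  labels <- if (is.null(region_labels)) rep("all", length(reads))
            else as.character(region_labels)
  stopifnot(length(labels) == length(reads))
  by_lab <- split(gc, labels)
  out <- data.frame(
    label = names(by_lab),
    n = vapply(by_lab, length, integer(1)),
    mean = vapply(by_lab, mean, numeric(1)),
    sd = vapply(by_lab, function(v) if (length(v) > 1L) sd(v) else 0,
                numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "gc") <- by_lab
  attr(out, "histogram") <- lapply(by_lab, function(v)
    graphics::hist(v, breaks = breaks, plot = FALSE))
  out
}

#' Per-position quality summaries
#'
#' Read positions (5'→3') are binned; each bin is summarized by its
#' five-number summary of Phred scores across all reads reaching it. Bins
#' that no read reaches are omitted.
#'
#' @param reads list of [seq_record] objects; all must carry qualities.
#' @param n_bins number of position bins (default 100).
#' @return data frame with `bin`, `pos_start`, `pos_end` (0-based
#'   half-open), `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
positional_quality <- function(reads, n_bins = 100L) {
  stopifnot(length(reads) > 0L)
  if (any(vapply(reads, function(r) is.null(r$qual), logical(1))))
    stop("positional_quality: reads lack quality scores")
  max_len <- max(record_lengths(reads))
  edges <- unique(as.integer(round(seq(0, max_len, length.out = n_bins + 1L))))
  pos <- unlist(lapply(reads, function(r) seq_len(length(r$qual)) - 1L))
  qs <- unlist(lapply(reads, `[[`, "qual"))
  bin <- findInterval(pos, edges, rightmost.closed = TRUE)
  by_bin <- split(qs, bin)
  rows <- lapply(names(by_bin), function(b) {
    v <- by_bin[[b]]
    i <- as.integer(b)
    fn <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(bin = i, pos_start = edges[i], pos_end = edges[i + 1L],
               n = length(v), min = fn[1], q1 = fn[2], median = fn[3],
               q3 = fn[4], max = fn[5])
  })
  do.call(rbind, rows)
}

#' Coverage profile of a contig
#'
#' Each read is placed once, at its best local alignment to the contig;
#' depth is the number of reads covering each position, summarized also as
#' a depth histogram. Reads without an acceptable hit are counted as
#' unmapped, and reads with multiple candidate placements (the ambiguity
#' that skews coverage inside repeat arrays) are surfaced in
#' `n_multi_hit` rather than being multi-placed.
#'
#' @param reads list of [seq_record] objects.
#' @param contig DNA string.
#' @param min_identity minimum placement identity.
#' @param seed_length seed length for [local_align()].
#' @return object of class `coverage_profile`: `depth` (integer vector,
#'   one per contig position), `histogram` (data frame `depth`, `n_pos`),
#'   `n_unmapped`, `n_multi_hit`.
#' @export
coverage_profile <- function(reads, contig, min_identity = 0.7,
                             seed_length = 13L) {
  stopifnot(nchar(contig) > 0L)
  L <- nchar(contig)
  depth <- integer(L)
  n_unmapped <- 0L
  n_multi <- 0L
  for (rd in reads) {
    hits <- local_hits(rd$seq, contig, seed_length = seed_length,
                       min_identity = min_identity, max_clusters = 16L)
    if (length(hits) == 0L) { n_unmapped <- n_unmapped + 1L; next }
    if (length(hits) > 1L) n_multi <- n_multi + 1L
    sc <- vapply(hits, `[[`, 0, "score")
    ts <- vapply(hits, `[[`, 0L, "target_start")
    best <- hits[[order(-sc, ts)[1L]]]
    span <- (best$target_start + 1L):best$target_end
    depth[span] <- depth[span] + 1L
  }
  tab <- table(depth)
  structure(list(
    depth = depth,
    histogram = data.frame(depth = as.integer(names(tab)),
                           n_pos = as.integer(tab)),
    n_unmapped = n_unmapped, n_multi_hit = n_multi),
    class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d positions, mean depth %.1f, %d unmapped, %d multi-hit reads\n",
              length(x$depth), mean(x$depth), x$n_unmapped, x$n_multi_hit))
  invisible(x)
}
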