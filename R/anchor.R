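# Anchor selection: pick reads containing a unique flank, trim them at the
# flank, and orientation-normalize so the anchor sits at the 5' end of the
# stored sequence with the repeat array extending 3' of it.

#' Select, trim and orientation-normalize flank-anchored reads
#'
#' Each read is searched on both strands for the 5' flank and for the
#' reverse complement of the 3' flank (so that, once oriented, both groups
#' read anchor-first into the repeat array). A read joins a group when the
#' best flank hit covers at least `min_anchor_cov` of the flank at
#' `min_identity` or better; it is trimmed to start at the anchor hit (the
#' anchor is retained) and reverse-complemented as needed. A read matching
#' both flanks spans the array and is assigned to both groups.
#'
#' @param reads list of [seq_record] objects.
#' @param flank5,flank3 flank sequences as they occur on the forward
#'   strand of the locus.
#' @param min_identity minimum hit identity (default 0.85).
#' @param min_anchor_cov minimum fraction of the flank the hit must cover
#'   (default 0.6).
#' @param seed_length seed length for [local_align()].
#' @param scoring see [default_scoring()].
#' @return list with `flank5` and `flank3` (lists of `anchored_read`:
#'   `read_id`, `anchor`, `seq`, `original_strand`, `anchor_identity`) and
#'   `report`, a data frame with one row per group giving `n_reads`,
#'   `max_depth` (maximum coverage depth of the left-anchored stack) and
#'   `max_length` (longest trimmed read).
#' @export
select_anchored_reads <- function(reads, flank5, flank3,
                                  min_identity = 0.85,
                                  min_anchor_cov = 0.6,
                                  seed_length = 13L,
                                  scoring = default_scoring()) {
  stopifnot(nchar(flank5) > 0, nchar(flank3) > 0)
  cross <- local_align(flank5, flank3, seed_length = seed_length,
                       min_identity = min_identity, scoring = scoring)
  if (!is.null(cross))
    stop("select_anchored_reads: flanks are not mutually dissimilar ",
         "(cross-hit identity ", round(cross$identity, 3), ")")

  anchors <- list(flank5 = flank5, flank3 = revcomp(flank3))
  groups <- list(flank5 = list(), flank3 = list())
  for (rd in reads) {
    for (anc in names(anchors)) {
      q <- anchors[[anc]]
      hit <- local_align(q, rd$seq, seed_length = seed_length,
                         min_identity = min_identity, scoring = scoring)
      if (is.null(hit)) next
      if (hit$query_coverage < min_anchor_cov) next
      n <- nchar(rd$seq)
      if (hit$strand == "+") {
        oriented <- rd$seq
        trim_from <- hit$target_start
      } else {
        oriented <- revcomp(rd$seq)
        trim_from <- n - hit$target_end
      }
      ar <- structure(list(
        read_id = rd$id, anchor = anc,
        seq = substring(oriented, trim_from + 1L),
        original_strand = hit$strand,
        anchor_identity = hit$identity,
        # bases of the anchor missing at the read's 5' end (0 when the
        # read covers the whole flank); lets the MSA place the row at its
        # true offset instead of force-pinning it to column 0
        anchor_offset = hit$query_start), class = "anchored_read")
      groups[[anc]][[length(groups[[anc]]) + 1L]] <- ar
    }
  }
  report <- anchor_report(groups)
  list(flank5 = groups$flank5, flank3 = groups$flank3, report = report)
}

# Per-group stack statistics in the shape of the anchored-subread table:
# n_reads, max coverage depth of the left-pinned stack, max trimmed length.
anchor_report <- function(groups) {
  one <- function(name, grp) {
    if (length(grp) == 0L)
      return(data.frame(group = name, n_reads = 0L, max_depth = 0L,
                        max_length = 0L, stringsAsFactors = FALSE))
    lens <- vapply(grp, function(a) nchar(a$seq), integer(1))
    # left-anchored stack: depth at offset p = number of reads longer
    # than p, which is non-increasing in p, so the maximum sits at the
    # anchor column
    data.frame(group = name, n_reads = length(grp),
               max_depth = sum(lens > 0L),
               max_length = max(lens), stringsAsFactors = FALSE)
  }
  rbind(one("flank5", groups$flank5), one("flank3", groups$flank3))
}

#' Write anchored read groups and report
#'
#' Writes each non-empty group as FASTA and the report as a tab-separated
#' table.
#' @param sel result of [select_anchored_reads()].
#' @param prefix output path prefix.
#' @return invisibly, the report path.
#' @export
write_anchored <- function(sel, prefix) {
  for (g in c("flank5", "flank3")) {
    recs <- lapply(sel[[g]], function(a) seq_record(a$read_id, a$seq))
    if (length(recs) > 0L)
      write_fasta(recs, paste0(prefix, ".", g, ".fa"))
  }
  rp <- paste0(prefix, ".report.tsv")
  write.table(sel$report, rp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rp)
}
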