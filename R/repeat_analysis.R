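# Repeat-unit analyses: segmentation of a sequence into unit copies,
# copy counting, pairwise unit comparison, dot plots, IUPAC motif scans,
# in silico restriction digests, and copy-number estimation from
# restriction-fragment lengths.

#' Segment a sequence into repeat-unit copies
#'
#' Finds local hits of the unit probe on both strands, then greedily
#' chains non-overlapping forward hits by score (ties: leftmost). A
#' trailing hit covering at least 30% but less than 85% of the probe is
#' flagged partial (a truncated terminal unit); hits below 30% coverage
#' are dropped. Inverted (minus-strand) hits are reported separately as
#' distractors, not counted as copies.
#'
#' @param sequence DNA string to segment.
#' @param probe repeat-unit probe (>= 100 bases).
#' @param min_identity minimum hit identity (default 0.8; unit copies
#'   diverge little, but consensus sequences carry residual errors).
#' @param seed_length seed length for hit finding.
#' @return object of class `unit_segmentation`: `intervals` (data frame
#'   `start`, `end`, `partial`, `identity`, 0-based half-open, 5'→3'),
#'   `distractors` (same shape for minus-strand hits), `probe`.
#' @export
segment_units <- function(sequence, probe, min_identity = 0.8,
                          seed_length = 13L) {
  stopifnot(nchar(probe) >= 100L)
  hits <- local_hits(probe, sequence, seed_length = seed_length,
                     min_identity = min_identity,
                     max_clusters = 256L)
  plen <- nchar(probe)
  cov <- vapply(hits, `[[`, 0, "query_coverage")
  keep <- cov >= 0.30
  hits <- hits[keep]
  to_df <- function(hs) {
    if (length(hs) == 0L)
      return(data.frame(start = integer(0), end = integer(0),
                        partial = logical(0), identity = numeric(0)))
    df <- data.frame(
      start = vapply(hs, `[[`, 0L, "target_start"),
      end = vapply(hs, `[[`, 0L, "target_end"),
      partial = vapply(hs, `[[`, 0, "query_coverage") < 0.85,
      identity = vapply(hs, `[[`, 0, "identity"))
    df[order(df$start), , drop = FALSE]
  }
  strands <- vapply(hits, `[[`, "", "strand")
  fwd <- hits[strands == "+"]
  # greedy chain: best score first, drop overlaps (>10% of probe length)
  if (length(fwd) > 1L) {
    sc <- vapply(fwd, `[[`, 0, "score")
    ts <- vapply(fwd, `[[`, 0L, "target_start")
    ord <- order(-sc, ts)
    chosen <- list()
    for (i in ord) {
      h <- fwd[[i]]
      ok <- TRUE
      for (c2 in chosen) {
        ov <- min(h$target_end, c2$target_end) -
          max(h$target_start, c2$target_start)
        if (ov > 0.10 * plen) { ok <- FALSE; break }
      }
      if (ok) chosen[[length(chosen) + 1L]] <- h
    }
    fwd <- chosen
  }
  iv <- to_df(fwd)
  rownames(iv) <- NULL
  dis <- to_df(hits[strands == "-"])
  rownames(dis) <- NULL
  structure(list(intervals = iv, distractors = dis, probe = probe),
            class = "unit_segmentation")
}

#' @export
print.unit_segmentation <- function(x, ...) {
  cat("<unit_segmentation> ", nrow(x$intervals), " unit intervals (",
      sum(x$intervals$partial), " partial), ",
      nrow(x$distractors), " inverted distractor hits\n", sep = "")
  invisible(x)
}

#' Count repeat copies at half-unit resolution
#'
#' Full intervals count 1, partial intervals 0.5.
#' @param seg a `unit_segmentation`.
#' @return copy number (multiple of 0.5).
#' @export
count_copies <- function(seg) {
  stopifnot(inherits(seg, "unit_segmentation"))
  sum(ifelse(seg$intervals$partial, 0.5, 1))
}

#' Compare two repeat units by exact global alignment
#'
#' Optimal global alignment under the package scoring; the identity is
#' `100 * match columns / total columns` and `differences` counts every
#' mismatch column plus every gap column (one gap position = one
#' difference). That gap convention is recorded in the result so users can
#' recompute under another one.
#'
#' @param a,b DNA strings (non-empty).
#' @param scoring see [default_scoring()].
#' @return object of class `unit_comparison`: `percent_identity` (0-100),
#'   `differences`, `columns`, `matches`, `mismatches`, `gap_columns`,
#'   `convention`.
#' @examples
#' compare_units("ACGT", "ACGA") # 75% identity, 1 difference
#' @export
compare_units <- function(a, b, scoring = default_scoring()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  a <- toupper(a); b <- toupper(b)
  # the pair is unordered: align in a canonical orientation so that
  # co-optimal alignments cannot make (a,b) and (b,a) disagree
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  al <- align_global(a, b, scoring = scoring, free_end = FALSE)
  ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  gap <- ca == "-" | cb == "-"
  match_col <- !gap & ca == cb & ca != "N"
  mismatch_col <- !gap & !match_col
  structure(list(
    percent_identity = 100 * sum(match_col) / length(ca),
    differences = sum(mismatch_col) + sum(gap),
    columns = length(ca),
    matches = sum(match_col),
    mismatches = sum(mismatch_col),
    gap_columns = sum(gap),
    convention = "each gap column counts as one difference"),
    class = "unit_comparison")
}

#' @export
print.unit_comparison <- function(x, ...) {
  cat(sprintf("<unit_comparison> %.2f%% identity, %d differences over %d columns\n",
              x$percent_identity, x$differences, x$columns))
  invisible(x)
}

#' Pairwise comparison table for a set of units
#'
#' All-vs-all [compare_units()] in the shape of a pairwise-identity table:
#' one row per unordered pair with percent identity and difference count.
#'
#' @param units named list or character vector of unit sequences.
#' @param scoring see [default_scoring()].
#' @return data frame with `unit_a`, `unit_b`, `percent_identity`,
#'   `differences`.
#' @export
compare_unit_set <- function(units, scoring = default_scoring()) {
  seqs <- unlist(units)
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("unit", seq_along(seqs))
  n <- length(seqs)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    cmp <- compare_units(seqs[[i]], seqs[[j]], scoring)
    rows[[length(rows) + 1L]] <- data.frame(
      unit_a = nm[i], unit_b = nm[j],
      percent_identity = cmp$percent_identity,
      differences = cmp$differences, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(unit_a = character(0), unit_b = character(0),
                      percent_identity = numeric(0),
                      differences = integer(0)))
  do.call(rbind, rows)
}

#' Window dot plot of two sequences
#'
#' `(i, j)` is reported when the windows `a[i, i+window)` and
#' `b[j, j+window)` agree at `min_matches` or more positions (0-based
#' coordinates).
#'
#' @param a,b DNA strings.
#' @param window window length (>= 4).
#' @param min_matches minimum matching positions per window pair.
#' @return data frame with columns `i`, `j`.
#' @export
dotplot <- function(a, b, window = 20L, min_matches = window) {
  stopifnot(window >= 4L)
  m <- cpp_dotplot(toupper(a), toupper(b), as.integer(window),
                   as.integer(min_matches))
  data.frame(i = m[, 1L], j = m[, 2L])
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
               H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(pattern) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% names(IUPAC_MAP))
  if (any(bad))
    stop("invalid IUPAC symbol(s): ", paste(unique(ch[bad]), collapse = ", "))
  paste(IUPAC_MAP[ch], collapse = "")
}

#' Scan repeat units for IUPAC motifs
#'
#' Exact degenerate matching on the given strand. The conservation report
#' lists motifs found at the same offset in every unit (homologous
#' position, units being aligned from their starts).
#'
#' @param units named list or character vector of unit sequences.
#' @param motifs named character vector or list of IUPAC patterns
#'   (e.g. `c(TACAA_box = "TACAA")`). No default motif set ships with the
#'   package: supply the motifs relevant to your locus.
#' @return list with `hits` (data frame `unit`, `motif`, `start`, 0-based)
#'   and `conserved` (data frame `motif`, `offset` for offsets shared by
#'   all units).
#' @export
scan_motifs <- function(units, motifs) {
  seqs <- unlist(units)
  unm <- names(seqs)
  if (is.null(unm)) unm <- paste0("unit", seq_along(seqs))
  mot <- unlist(motifs)
  mnm <- names(mot)
  if (is.null(mnm) || any(!nzchar(mnm))) mnm <- paste0("motif", seq_along(mot))
  rows <- list()
  for (mi in seq_along(mot)) {
    rx <- iupac_to_regex(mot[[mi]])
    for (ui in seq_along(seqs)) {
      g <- gregexpr(paste0("(?=", rx, ")"), toupper(seqs[[ui]]),
                    perl = TRUE)[[1]]
      pos <- if (g[1L] == -1L) integer(0) else as.integer(g) - 1L
      if (length(pos) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          unit = unm[ui], motif = mnm[mi], start = pos,
          stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(unit = character(0), motif = character(0),
               start = integer(0), stringsAsFactors = FALSE)
  conserved <- data.frame(motif = character(0), offset = integer(0),
                          stringsAsFactors = FALSE)
  if (nrow(hits) > 0L && length(seqs) > 0L) {
    for (mn in unique(hits$motif)) {
      h <- hits[hits$motif == mn, ]
      offs <- Reduce(intersect, split(h$start, factor(h$unit, levels = unm)))
      if (length(unique(h$unit)) == length(seqs) && length(offs) > 0L)
        conserved <- rbind(conserved, data.frame(
          motif = mn, offset = sort(offs), stringsAsFactors = FALSE))
    }
  }
  list(hits = hits, conserved = conserved)
}

#' In silico restriction digest
#'
#' Cuts at every occurrence of each recognition sequence; for a
#' non-palindromic site the reverse-complement occurrences are cut as
#' well, with the cut offset mirrored. The default cut offset is the
#' midpoint of the site (blunt EcoRV-style); give `cut_offset` per site to
#' change it. Fragment lengths always sum to the sequence length.
#'
#' @param sequence DNA string.
#' @param sites data frame with columns `enzyme`, `recognition`, and
#'   optionally `cut_offset` (0-based offset of the cut within the site),
#'   or a named character vector of recognition sequences.
#' @return integer vector of fragment lengths, 5'→3'.
#' @examples
#' in_silico_digest("AAAGATATCAAA", c(EcoRV = "GATATC")) # 6 6
#' @export
in_silico_digest <- function(sequence, sites) {
  s <- toupper(sequence)
  L <- nchar(s)
  if (is.character(sites))
    sites <- data.frame(enzyme = names(sites) %||% seq_along(sites),
                        recognition = unname(sites),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("enzyme", "recognition") %in% names(sites)))
  if (any(grepl("[^ACGT]", toupper(sites$recognition))))
    stop("in_silico_digest: recognition sequences must be non-degenerate")
  cuts <- integer(0)
  for (k in seq_len(nrow(sites))) {
    rec <- toupper(sites$recognition[k])
    off <- if (!is.null(sites$cut_offset)) sites$cut_offset[k] else
      nchar(rec) %/% 2L
    occ <- find_occurrences(s, rec)
    cuts <- c(cuts, occ + off)
    rc <- revcomp(rec)
    if (rc != rec) {
      occ2 <- find_occurrences(s, rc)
      cuts <- c(cuts, occ2 + (nchar(rec) - off))
    }
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < L]
  diff(c(0L, cuts, L))
}

# 0-based start positions of every (possibly overlapping) occurrence
find_occurrences <- function(s, pattern) {
  g <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
  if (g[1L] == -1L) integer(0) else as.integer(g) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate repeat copy number from a region length
#'
#' `(region_length - flank_total) / unit_length`, reported at half-unit
#' resolution. The flank total is model-dependent: it encodes how much of
#' the measured region is attributed to unique flanking sequence, and the
#' result moves by half a unit per ~`unit_length/2` bases of flank
#' misattribution.
#'
#' @param region_length measured repeat-region length in bases (e.g. from
#'   a restriction digest).
#' @param unit_length repeat-unit length.
#' @param flank_total total flanking sequence included in the region.
#' @return copy number rounded to the nearest half unit.
#' @examples
#' estimate_copies_from_length(48000, 3300, 3450) # 13.5
#' @export
estimate_copies_from_length <- function(region_length, unit_length,
                                        flank_total) {
  stopifnot(region_length > 0, unit_length > 0, flank_total >= 0)
  if (region_length <= flank_total)
    stop("estimate_copies_from_length: region_length must exceed flank_total")
  round((region_length - flank_total) / unit_length * 2) / 2
}

#' Segmentation intervals as a BED-shaped data frame
#' @param seg a `unit_segmentation`.
#' @param chrom contig name.
#' @return data frame suitable for [write_bed()].
#' @export
segmentation_to_bed <- function(seg, chrom = "consensus") {
  iv <- seg$intervals
  n <- nrow(iv)
  fwd <- if (n > 0L) data.frame(
    chrom = chrom, start = iv$start, end = iv$end,
    name = ifelse(iv$partial, paste0("unit", seq_len(n), "_partial"),
                  paste0("unit", seq_len(n))),
    score = as.integer(round(1000 * iv$identity)), strand = "+",
    stringsAsFactors = FALSE) else NULL
  dv <- seg$distractors
  m <- nrow(dv)
  rev <- if (m > 0L) data.frame(
    chrom = chrom, start = dv$start, end = dv$end,
    name = paste0("distractor", seq_len(m)),
    score = as.integer(round(1000 * dv$identity)), strand = "-",
    stringsAsFactors = FALSE) else NULL
  out <- rbind(fwd, rev)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  out
}
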