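# Anchored star alignment: all reads of one anchor group are pinned at
# column 0 (the anchor) and stacked into a gapped column matrix.
#
# The anchor removes the hard placement problem of repetitive reads, so a
# draft-based star alignment suffices: align every read to a backbone,
# merge insertions into the column set, then do one refinement pass
# against the draft consensus.

MSA_ALPHABET <- c("A", "C", "G", "T", "-")
GAP_CODE <- 5L

#' Column matrix of an anchored read stack
#'
#' Rows are reads, columns the gapped alignment over `{A,C,G,T,-}`;
#' positions beyond a read's end are missing (`NA`) — every row's
#' non-missing region is a contiguous block starting at column 0.
#' Internally bases are stored as integer codes 1:5 into
#' `c("A","C","G","T","-")`.
#'
#' @param mat integer matrix of codes (rows = reads), `NA` = missing.
#' @param row_ids read identifiers.
#' @return an object of class `column_matrix`.
#' @keywords internal
column_matrix <- function(mat, row_ids) {
  stopifnot(is.matrix(mat), nrow(mat) == length(row_ids))
  structure(list(mat = mat, row_ids = row_ids), class = "column_matrix")
}

#' @export
print.column_matrix <- function(x, ...) {
  cat("<column_matrix> ", nrow(x$mat), " reads x ", ncol(x$mat),
      " columns\n", sep = "")
  invisible(x)
}

#' Recover a row's ungapped sequence
#' @param m a `column_matrix`.
#' @param i row index.
#' @return the row's sequence with gaps and missing positions removed.
#' @export
msa_row_sequence <- function(m, i) {
  v <- m$mat[i, ]
  v <- v[!is.na(v) & v != GAP_CODE]
  paste(MSA_ALPHABET[v], collapse = "")
}

# Align one read to the backbone and express it in backbone coordinates:
# lead     backbone positions skipped before the read starts (its anchor
#          offset relative to the backbone's)
# at[i]    base aligned to backbone position lead + i (or "-")
# ins[[i]] bases inserted after backbone position i - 1 (absolute;
#          ins[[1]] sits before position 1), i in 1..m+1
# cov_end  last backbone position covered by the read (lead = none)
read_vs_backbone <- function(read_seq, backbone, scoring, band, lead = 0L) {
  m <- nchar(backbone)
  lead <- min(lead, m - 1L)
  al <- align_global(substring(backbone, lead + 1L), read_seq,
                     scoring = scoring, band = band, free_end = TRUE)
  aa <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  ab <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  at <- character(al$a_end)
  ins <- vector("list", m + 1L)
  bi <- 0L
  for (k in seq_along(aa)) {
    if (aa[k] != "-") {
      bi <- bi + 1L
      at[bi] <- ab[k]
    } else {
      ins[[lead + bi + 1L]] <- c(ins[[lead + bi + 1L]], ab[k])
    }
  }
  # read overhang past the backbone end lands in the final insertion slot
  # only when the whole backbone was consumed; otherwise the read ended
  # first and b_end equals the read length
  if (lead + al$a_end == m && al$b_end < nchar(read_seq)) {
    tail_chars <- strsplit(substring(read_seq, al$b_end + 1L), "",
                           fixed = TRUE)[[1]]
    ins[[m + 1L]] <- c(ins[[m + 1L]], tail_chars)
  }
  list(lead = lead, at = at, ins = ins, cov_end = lead + al$a_end)
}

stack_rows <- function(parsed, m) {
  max_ins <- integer(m + 1L)
  for (p in parsed)
    for (i in seq_len(m + 1L)) {
      li <- length(p$ins[[i]])
      if (li > max_ins[i]) max_ins[i] <- li
    }
  # column layout: [ins slot 0] pos1 [ins slot 1] pos2 ... posm [ins slot m]
  n_cols <- m + sum(max_ins)
  col_of_pos <- integer(m) # column index of backbone position i
  cpos <- max_ins[1L]
  for (i in seq_len(m)) {
    cpos <- cpos + 1L
    col_of_pos[i] <- cpos
    if (i < m) cpos <- cpos + max_ins[i + 1L]
  }
  ins_slot_start <- integer(m + 1L) # first column of ins slot i (after pos i-1)
  ins_slot_start[1L] <- 1L
  for (i in seq_len(m)) ins_slot_start[i + 1L] <- col_of_pos[i] + 1L

  mat <- matrix(NA_integer_, nrow = length(parsed), ncol = n_cols)
  for (r in seq_along(parsed)) {
    p <- parsed[[r]]
    if (p$cov_end <= p$lead) next
    covered <- (p$lead + 1L):p$cov_end
    mat[r, col_of_pos[covered]] <-
      match(p$at[covered - p$lead], MSA_ALPHABET)
    first_col <- col_of_pos[p$lead + 1L]
    last_col <- col_of_pos[p$cov_end]
    for (i in seq_len(m + 1L)) {
      v <- p$ins[[i]]
      if (length(v) > 0L) {
        cols <- ins_slot_start[i] + seq_along(v) - 1L
        mat[r, cols] <- match(v, MSA_ALPHABET)
        if (max(cols) > last_col) last_col <- max(cols)
        if (min(cols) < first_col) first_col <- min(cols)
      }
    }
    # inside the covered block, unset cells are gaps; outside it, missing
    span <- first_col:last_col
    row <- mat[r, span]
    row[is.na(row)] <- GAP_CODE
    mat[r, span] <- row
  }
  mat
}

plurality_draft <- function(mat) {
  counts <- vapply(1:5, function(s) colSums(mat == s, na.rm = TRUE),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1L)
  base_best <- max.col(counts[, 1:4, drop = FALSE], ties.method = "first")
  base_n <- counts[cbind(seq_len(nrow(counts)), base_best)]
  gap_n <- counts[, 5L]
  keep <- base_n > 0 & base_n >= gap_n   # '-' loses ties to any base
  paste(MSA_ALPHABET[base_best[keep]], collapse = "")
}

#' Build an anchored multiple alignment of one read group
#'
#' Star alignment with one refinement pass: (1) the longest read is the
#' initial backbone; (2) every read is aligned to it by banded global
#' alignment with free end gaps at the far (3') end only — reads are
#' pinned at the anchor and end wherever the molecule ended; (3) per-read
#' insertions are merged into the column set; (4) a plurality draft
#' consensus of that first stack becomes the backbone for one refinement
#' pass over all reads.
#'
#' @param group list of `anchored_read` (from [select_anchored_reads()]),
#'   or a list of [seq_record]; all must share the same anchor.
#' @param scoring see [default_scoring()].
#' @param band initial band half-width for the banded alignment (doubled
#'   automatically on overflow, up to 8x).
#' @param refine logical; run the refinement pass (default `TRUE`).
#' @return a `column_matrix`.
#' @export
build_msa <- function(group, scoring = default_scoring(), band = 200L,
                      refine = TRUE) {
  if (length(group) == 0L) stop("build_msa: empty group")
  seqs <- vapply(group, function(g) {
    if (!is.null(g$seq)) g$seq else stop("build_msa: no sequence field")
  }, character(1))
  ids <- vapply(group, function(g) {
    if (!is.null(g$read_id)) g$read_id else g$id
  }, character(1))
  anchors <- vapply(group, function(g)
    if (!is.null(g$anchor)) g$anchor else NA_character_, character(1))
  if (length(unique(anchors[!is.na(anchors)])) > 1L)
    stop("build_msa: reads do not share the same anchor")
  if (any(grepl("[^ACGT]", seqs)))
    stop("build_msa: the column alphabet is {A,C,G,T,-}; reads must not ",
         "contain N or other ambiguity codes")

  offsets <- vapply(group, function(g)
    as.integer(g$anchor_offset %||% 0L), integer(1))
  # backbone: the longest read among those with the smallest anchor
  # offset, so row offsets relative to it are non-negative
  cand <- which(offsets == min(offsets))
  bb <- cand[which.max(nchar(seqs[cand]))]
  backbone <- seqs[[bb]]
  rel_off <- pmax(0L, offsets - offsets[bb])
  passes <- if (refine) 2L else 1L
  for (pass in seq_len(passes)) {
    parsed <- mapply(read_vs_backbone, seqs, lead = rel_off,
                     MoreArgs = list(backbone = backbone, scoring = scoring,
                                     band = band), SIMPLIFY = FALSE)
    mat <- stack_rows(parsed, nchar(backbone))
    if (pass < passes) backbone <- plurality_draft(mat)
  }
  column_matrix(mat, ids)
}

#' Serialize / read a column matrix as aligned FASTA
#'
#' Rows are written padded with `-` inside the alignment and `.` for
#' missing positions beyond the read end.
#'
#' @param m a `column_matrix`.
#' @param path file path.
#' @export
write_msa <- function(m, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(m$mat))) {
    v <- m$mat[i, ]
    ch <- ifelse(is.na(v), ".", MSA_ALPHABET[ifelse(is.na(v), 1L, v)])
    writeLines(c(paste0(">", m$row_ids[i]), paste(ch, collapse = "")), con)
  }
  invisible(path)
}

#' @rdname write_msa
#' @export
read_msa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("read_msa: no records in '", path, "'")
  ids <- sub("^>", "", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  rows <- vapply(seq_along(hdr), function(i)
    paste(lines[starts[i]:ends[i]], collapse = ""), character(1))
  if (length(unique(nchar(rows))) != 1L)
    stop("read_msa: rows have unequal lengths")
  mat <- t(vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    v <- match(ch, MSA_ALPHABET)
    v[ch == "."] <- NA_integer_
    v
  }, integer(nchar(rows[1L]))))
  dimnames(mat) <- NULL
  column_matrix(mat, ids)
}
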