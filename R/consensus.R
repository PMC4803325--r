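# Threshold consensus calling from an anchored column matrix.
#
# Per column the plurality character over the non-missing rows wins; a
# winning base is emitted when its fraction of the column depth reaches
# the threshold (13-14% is the working range for indel-noisy
# single-molecule reads), a sub-threshold winner emits N, and a
# gap-plurality column emits nothing (such columns are insertion noise).
# The threshold denominator is the column depth (non-missing rows), not
# the total read count: coverage decays toward the 3' end of an anchored
# stack and a total-read denominator would make one threshold meaningless
# there.

#' Call a threshold consensus from a column matrix
#'
#' Per column: depth is the number of non-missing rows; the winner is the
#' plurality character among `{A,C,G,T,-}` (ties: `-` loses to any base;
#' tied bases resolve A < C < G < T). A winning `-` emits nothing; a
#' winning base is emitted when its fraction of depth is at least
#' `threshold`, otherwise `N`. Calling stops at the first run of
#' `stop_window` consecutive low-support columns (depth below `min_depth`,
#' or an emitted `N`), and the consensus is trimmed back to the last
#' confidently called base — a sustained collapse of signal terminates the
#' sequence, a lone bad column does not.
#'
#' @param m a `column_matrix` from [build_msa()] or [read_msa()].
#' @param threshold minimum winner fraction to call a base (in (0, 1]).
#' @param min_depth minimum depth for a column to count as supported.
#' @param stop_window number of consecutive low-support columns that
#'   terminates calling.
#' @return object of class `consensus_result`: `sequence` (DNA, may
#'   contain interior `N`), `per_column` (data frame with 0-based
#'   `column`, `depth`, `winner`, `winner_fraction`, `emitted`),
#'   `called_length`, `threshold`.
#' @export
call_consensus <- function(m, threshold = 0.14, min_depth = 3L,
                           stop_window = 50L) {
  stopifnot(inherits(m, "column_matrix"))
  stopifnot(threshold > 0, threshold <= 1)
  mat <- m$mat
  if (nrow(mat) == 0L || ncol(mat) == 0L)
    stop("call_consensus: empty matrix")
  nc <- ncol(mat)
  counts <- vapply(1:5, function(s) colSums(mat == s, na.rm = TRUE),
                   numeric(nc))
  if (nc == 1L) counts <- matrix(counts, nrow = 1L)
  depth <- rowSums(counts)

  base_idx <- max.col(counts[, 1:4, drop = FALSE], ties.method = "first")
  base_n <- counts[cbind(seq_len(nc), base_idx)]
  gap_n <- counts[, 5L]

  winner <- character(nc)
  frac <- rep(NA_real_, nc)
  emitted <- character(nc)
  gap_wins <- gap_n > base_n                  # '-' loses ties to any base
  has_rows <- depth > 0
  winner[has_rows & gap_wins] <- "-"
  frac[has_rows & gap_wins] <- gap_n[has_rows & gap_wins] /
    depth[has_rows & gap_wins]
  bcols <- has_rows & !gap_wins
  winner[bcols] <- MSA_ALPHABET[base_idx[bcols]]
  frac[bcols] <- base_n[bcols] / depth[bcols]
  winner[!has_rows] <- NA_character_

  emit_base <- bcols & frac >= threshold
  emit_n <- bcols & frac < threshold
  emitted[emit_base] <- winner[emit_base]
  emitted[emit_n] <- "N"

  low <- (depth < min_depth) | emit_n
  stop_at <- nc + 1L
  if (stop_window >= 1L && any(low)) {
    r <- rle(low)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= stop_window)
    if (length(hit) > 0L)
      stop_at <- ends[hit[1L]] - r$lengths[hit[1L]] + 1L
  }
  use <- seq_len(min(stop_at - 1L, nc))
  # trim back to the last confidently called base
  conf <- use[emitted[use] %in% c("A", "C", "G", "T")]
  if (length(conf) == 0L) {
    use <- integer(0)
  } else {
    use <- use[use <= max(conf)]
  }
  seq_chars <- emitted[use]
  seq_chars <- seq_chars[seq_chars != ""]
  structure(list(
    sequence = paste(seq_chars, collapse = ""),
    per_column = data.frame(
      column = seq_len(nc) - 1L, depth = as.integer(depth),
      winner = winner, winner_fraction = frac, emitted = emitted,
      stringsAsFactors = FALSE),
    called_length = length(seq_chars),
    threshold = threshold), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", x$called_length, " bases called at threshold ",
      x$threshold, " (", sum(strsplit(x$sequence, "")[[1]] == "N"),
      " N)\n", sep = "")
  invisible(x)
}

#' Per-column support profile of a consensus
#'
#' Depth and winner fraction per alignment column — the observable that
#' motivates the calling threshold: in anchored stacks depth decays with
#' distance from the anchor as reads drop out.
#'
#' @param result a `consensus_result`.
#' @return data frame with `column` (0-based), `depth`, `winner_fraction`.
#' @export
consensus_support_profile <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  result$per_column[, c("column", "depth", "winner_fraction")]
}

#' Write a consensus and its support profile
#' @param result a `consensus_result`.
#' @param path FASTA output path.
#' @param id FASTA record id.
#' @param profile_path optional TSV path for the support profile.
#' @export
write_consensus <- function(result, path, id = "consensus",
                            profile_path = NULL) {
  con <- file(path, "wt")
  writeLines(paste0(">", id), con)
  s <- result$sequence
  if (nchar(s) > 0L) {
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  close(con)
  if (!is.null(profile_path))
    write.table(consensus_support_profile(result), profile_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
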