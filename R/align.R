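# Pairwise alignment wrappers over the compiled core.
#
# Scoring convention everywhere: match +2, mismatch -4, a gap run of
# length L costs gap_open + L * gap_extend (defaults -4 / -2) — blastn-like
# scoring tolerant of indel-rich reads.

#' Default alignment scoring
#' @return list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function() {
  list(match = 2L, mismatch = -4L, gap_open = -4L, gap_extend = -2L)
}

check_scoring <- function(s) {
  stopifnot(all(c("match", "mismatch", "gap_open", "gap_extend") %in% names(s)))
  lapply(s, as.integer)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment pinned at both sequence starts. With
#' `free_end = TRUE` trailing gaps in either sequence are free
#' (semi-global; used for anchored read stacking, where reads simply end
#' wherever the molecule ended). A banded search is used when `band` is
#' given; if the optimal path touches the band edge the band is doubled
#' automatically (up to 8x) before giving up.
#'
#' @param a,b DNA strings.
#' @param scoring see [default_scoring()].
#' @param band band half-width in columns, or `NULL` for an unrestricted
#'   search.
#' @param free_end free trailing gaps (see above).
#' @return list with `aligned_a`, `aligned_b` (gapped strings over the
#'   aligned region), `score`, and `a_end`, `b_end` (0-based half-open end
#'   of the aligned region in each sequence; both ends equal the lengths
#'   unless `free_end`).
#' @export
align_global <- function(a, b, scoring = default_scoring(), band = NULL,
                         free_end = FALSE) {
  sc <- check_scoring(scoring)
  m <- nchar(a); n <- nchar(b)
  stopifnot(m > 0, n > 0)
  full_band <- max(m, n)
  b0 <- if (is.null(band)) full_band else max(1L, as.integer(band))
  cap <- min(full_band, b0 * 8L)
  repeat {
    res <- cpp_align_pinned(a, b, sc$match, sc$mismatch, sc$gap_open,
                            sc$gap_extend, b0, free_end)
    if (!res$band_hit || b0 >= full_band) break
    if (b0 >= cap)
      stop("align_global: optimal path leaves the band at cap ", cap)
    b0 <- min(full_band, b0 * 2L)
  }
  res[c("aligned_a", "aligned_b", "score", "a_end", "b_end")]
}

#' Edit distance
#'
#' Unit-cost Levenshtein distance via an adaptive banded computation that
#' is exact for arbitrarily long sequences.
#'
#' @param a,b strings.
#' @return integer edit distance.
#' @export
edit_distance <- function(a, b) {
  cpp_edit_distance(a, b)
}

# Cluster seed hits (q_pos, t_pos) by diagonal and return per-cluster
# target windows to hand to the local aligner.  A cluster breaks on a
# diagonal gap AND when its total diagonal span exceeds the indel drift a
# single true hit can accumulate — without the span cap, stray seeds
# (internal repeats of the query echoed across tandem copies) can bridge
# neighbouring copies into one giant window.
seed_clusters <- function(hits, qlen, tlen, pad) {
  if (nrow(hits) == 0L) return(list())
  d <- hits[, 2L] - hits[, 1L]
  d <- sort(d)
  gap_tol <- max(50L, as.integer(0.3 * qlen))
  span_tol <- max(100L, as.integer(0.35 * qlen))
  grp <- integer(length(d))
  g <- 1L; first_d <- d[1L]
  grp[1L] <- g
  for (k in seq_along(d)[-1L]) {
    if (d[k] - d[k - 1L] > gap_tol || d[k] - first_d > span_tol) {
      g <- g + 1L
      first_d <- d[k]
    }
    grp[k] <- g
  }
  lapply(split(d, grp), function(dv) {
    list(n_seeds = length(dv),
         start = max(0L, min(dv) - pad),
         end = min(tlen, max(dv) + qlen + pad))
  })
}

#' Seeded local alignment of a query against a target
#'
#' Re-implementation of a blastn-style search as exact k-mer seeding on
#' both strands followed by Smith-Waterman extension in a window around
#' each seed cluster. Returns the best hit, or `NULL` when nothing reaches
#' `min_identity`. Ties are broken by leftmost target position, then the
#' plus strand.
#'
#' @param query,target DNA strings.
#' @param seed_length exact-match seed length (>= 8; default 13 — short
#'   enough that seeds survive indel-rich reads, unlike the 50-mers usable
#'   on near-perfect reads).
#' @param min_identity minimum alignment identity of a reported hit.
#' @param scoring see [default_scoring()].
#' @param max_clusters cap on seed clusters extended per strand (highest
#'   seed support first).
#' @return a `local_hit`: list with `query_start`, `query_end`,
#'   `target_start`, `target_end` (0-based half-open, always on the
#'   forward target), `strand` (`+` if the query matches the target
#'   forward, `-` if it matches the reverse complement), `identity`,
#'   `score`, `query_coverage`; or `NULL`.
#' @export
local_align <- function(query, target, seed_length = 13L,
                        min_identity = 0.85,
                        scoring = default_scoring(),
                        max_clusters = 8L) {
  hits <- local_hits(query, target, seed_length, min_identity, scoring,
                     max_clusters)
  if (length(hits) == 0L) return(NULL)
  sc <- vapply(hits, `[[`, 0, "score")
  ts <- vapply(hits, `[[`, 0L, "target_start")
  st <- vapply(hits, `[[`, "", "strand")
  best <- order(-sc, ts, st)[1L]
  hits[[best]]
}

#' All seeded local hits of a query against a target
#'
#' Like [local_align()] but returns every cluster hit reaching
#' `min_identity` (used for repeat-unit segmentation, where the probe hits
#' once per copy).
#'
#' @inheritParams local_align
#' @return list of `local_hit` objects (possibly empty).
#' @export
local_hits <- function(query, target, seed_length = 13L,
                       min_identity = 0.85,
                       scoring = default_scoring(),
                       max_clusters = 64L) {
  stopifnot(seed_length >= 8L)
  sc <- check_scoring(scoring)
  qlen <- nchar(query); tlen <- nchar(target)
  if (qlen == 0L || tlen == 0L) return(list())
  pad <- max(30L, as.integer(0.25 * qlen))

  clusters <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    seeds <- cpp_seed_hits(q, target, as.integer(seed_length))
    for (w in seed_clusters(seeds, qlen, tlen, pad)) {
      w$strand <- strand
      w$q <- q
      clusters[[length(clusters) + 1L]] <- w
    }
  }
  if (length(clusters) == 0L) return(list())
  ns <- vapply(clusters, `[[`, 0L, "n_seeds")
  clusters <- clusters[order(-ns)]
  if (length(clusters) > max_clusters)
    clusters <- clusters[seq_len(max_clusters)]

  # evaluate strongest clusters first and skip windows whose core is
  # already claimed by an accepted hit: weak stray clusters (short
  # internal repeats of the query echoed across tandem copies) always
  # fall inside a stronger hit and would only duplicate it
  covered <- function(a, b) {
    if (length(accepted) == 0L || b <= a) return(0)
    ov <- 0L
    for (iv in accepted)
      ov <- ov + max(0L, min(b, iv[2L]) - max(a, iv[1L]))
    ov / (b - a)
  }
  accepted <- list()
  out <- list()
  for (w in clusters) {
    if (covered(w$start + pad, w$end - pad) >= 0.9) next
    win <- substr(target, w$start + 1L, w$end)
    r <- cpp_local_align(w$q, win, sc$match, sc$mismatch,
                         sc$gap_open, sc$gap_extend)
    if (!isTRUE(r$found) || r$columns == 0L) next
    ident <- r$matches / r$columns
    if (ident < min_identity) next
    qs <- r$q_start; qe <- r$q_end
    if (w$strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
    ts <- w$start + r$t_start; te <- w$start + r$t_end
    accepted[[length(accepted) + 1L]] <- c(ts, te)
    out[[length(out) + 1L]] <- structure(list(
      query_start = qs, query_end = qe,
      target_start = ts, target_end = te,
      strand = w$strand,
      identity = ident,
      score = r$score,
      query_coverage = (r$q_end - r$q_start) / qlen), class = "local_hit")
  }
  out
}
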