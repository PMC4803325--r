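# Independent oracles and fixture builders. Everything here is written
# naively (loops, direct definitions) on purpose: these implementations
# must not share code paths with the package internals they check.

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Mutate a sequence with the given per-base rates (independent of the
# package's corrupt()).
mutate_seq <- function(s, p_sub = 0, p_ins = 0, p_del = 0) {
  ch <- strsplit(s, "")[[1]]
  out <- character(0)
  for (c0 in ch) {
    r <- runif(1)
    if (r < p_del) {
      # dropped
    } else if (r < p_del + p_sub) {
      out <- c(out, sample(setdiff(c("A", "C", "G", "T"), c0), 1))
    } else {
      out <- c(out, c0)
    }
    if (runif(1) < p_ins) out <- c(out, sample(c("A", "C", "G", "T"), 1))
  }
  paste(out, collapse = "")
}

# Optimal global affine-gap alignment SCORE by straightforward 3-matrix
# dynamic programming (quadratic, no band, no traceback).
oracle_global_score <- function(a, b, match = 2, mismatch = -4,
                                gap_open = -4, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in seq_len(m)) X[i + 1, 1] <- gap_open + gap_extend * i
  for (j in seq_len(n)) Y[1, j + 1] <- gap_open + gap_extend * j
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend,
                             Y[i, j + 1] + gap_open + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend,
                             X[i + 1, j] + gap_open + gap_extend)
    }
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# Score an alignment given as two gapped strings, affine convention
# gap_open + L * gap_extend per maximal gap run.
score_gapped <- function(aa, ab, match = 2, mismatch = -4,
                         gap_open = -4, gap_extend = -2) {
  A <- strsplit(aa, "")[[1]]; B <- strsplit(ab, "")[[1]]
  stopifnot(length(A) == length(B))
  sc <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_along(A)) {
    if (A[k] == "-") {
      sc <- sc + gap_extend + if (!in_gap_a) gap_open else 0
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (B[k] == "-") {
      sc <- sc + gap_extend + if (!in_gap_b) gap_open else 0
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      sc <- sc + if (A[k] == B[k] && A[k] != "N") match else mismatch
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  sc
}

# Best local (Smith-Waterman) affine score, naive full-matrix DP.
oracle_local_score <- function(q, t, match = 2, mismatch = -4,
                               gap_open = -4, gap_extend = -2) {
  A <- strsplit(q, "")[[1]]; B <- strsplit(t, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

# N50 straight from the definition: the largest length L among the reads
# such that reads of length >= L hold at least half of all bases.
oracle_n50 <- function(lens) {
  total <- sum(lens)
  best <- NA_integer_
  for (L in sort(unique(lens))) {
    if (sum(lens[lens >= L]) >= total / 2) best <- L
  }
  best
}

# Brute-force threshold consensus: per-column counting with the tie rules
# ('-' loses to any base; tied bases resolve alphabetically), emission
# (base if fraction >= threshold, else N; nothing on gap plurality), and
# trailing trim back to the last confidently called base. No stop rule.
oracle_consensus <- function(mat, threshold) {
  chars <- c("A", "C", "G", "T", "-")
  emitted <- character(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    if (length(col) == 0) { emitted <- c(emitted, ""); next }
    cnt <- integer(5)
    for (v in col) cnt[v] <- cnt[v] + 1
    best_base <- which.max(cnt[1:4])          # first max = alphabetical tie
    if (cnt[5] > cnt[best_base]) { emitted <- c(emitted, ""); next }
    frac <- cnt[best_base] / length(col)
    emitted <- c(emitted, if (frac >= threshold) chars[best_base] else "N")
  }
  conf <- which(emitted %in% c("A", "C", "G", "T"))
  if (length(conf) == 0) return("")
  paste(emitted[seq_len(max(conf))], collapse = "")
}

# Random prefix-contiguous column matrix (rows end, never restart).
rand_column_matrix <- function(max_rows = 12, max_cols = 50) {
  nr <- sample(max_rows, 1)
  nc <- sample(max_cols, 1)
  mat <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) {
    len <- sample(0:nc, 1)
    if (len > 0)
      mat[r, seq_len(len)] <- sample(5, len, replace = TRUE,
                                     prob = c(.19, .19, .19, .19, .24))
  }
  mat
}

# Wrap an integer code matrix as the package's column matrix class.
as_column_matrix <- function(mat) {
  ids <- if (nrow(mat) == 0) character(0) else paste0("r", seq_len(nrow(mat)))
  anchorcons:::column_matrix(mat, ids)
}

# Standard small synthetic benchmark used across tests.
benchmark_truth <- function(seed = 42, divergence = 0.02) {
  build_array(array_spec(unit_length = 500, n_copies = 6.5,
                         inter_unit_divergence = divergence,
                         flank5_length = 500, flank3_length = 500,
                         seed = seed))
}
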