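code <- function(ch) match(ch, c("A", "C", "G", "T", "-"))

test_that("unanimous columns call the full sequence", {
  mat <- matrix(rep(code(c("A", "C", "G", "T")), each = 10), nrow = 10)
  cs <- call_consensus(as_column_matrix(mat), threshold = 0.14)
  expect_equal(cs$sequence, "ACGT")
  expect_true(all(cs$per_column$winner_fraction == 1))
  expect_equal(cs$called_length, 4)
})

test_that("gap-plurality columns emit nothing", {
  # counts A:2 C:2 -:6 over depth 10 -> '-' wins the column, no emission
  col <- code(c("A", "A", "C", "C", rep("-", 6)))
  mat <- cbind(matrix(code("G"), 10, 1), col, matrix(code("T"), 10, 1))
  cs <- call_consensus(as_column_matrix(mat), threshold = 0.14,
                       min_depth = 1)
  expect_equal(cs$sequence, "GT")
  expect_equal(cs$per_column$winner[2], "-")
  expect_equal(cs$per_column$emitted[2], "")
})

test_that("ties resolve as specified", {
  # base ties alphabetically: A:3 C:3 T:4? no - equal A and C
  col1 <- code(c("A", "A", "A", "C", "C", "C"))
  # '-' loses a tie against a base: -:3 G:3
  col2 <- code(c("-", "-", "-", "G", "G", "G"))
  mat <- cbind(col1, col2)
  cs <- call_consensus(as_column_matrix(mat), threshold = 0.14,
                       min_depth = 1)
  expect_equal(cs$per_column$winner, c("A", "G"))
  expect_equal(cs$sequence, "AG")
})

test_that("sub-threshold winners become N", {
  # counts A:2 C:3 G:3 T:2 -> winner C (alphabetical tie) at 3/10
  col <- code(c("A", "A", "C", "G", "T", "C", "G", "T", "C", "G"))
  # confident neighbours so the trailing trim keeps the N visible
  mat <- cbind(matrix(code("A"), 10), col, matrix(code("T"), 10))
  lo <- call_consensus(as_column_matrix(mat), threshold = 0.14,
                       min_depth = 1)
  expect_equal(lo$sequence, "ACT")
  hi <- call_consensus(as_column_matrix(mat), threshold = 0.35,
                       min_depth = 1)
  expect_equal(hi$sequence, "ANT")
})

test_that("sustained low support terminates and trims the call", {
  set.seed(51)
  good <- matrix(code("A"), nrow = 6, ncol = 40)
  # beyond column 40 only 1 read continues: depth < min_depth
  tail_block <- matrix(NA_integer_, nrow = 6, ncol = 30)
  tail_block[1, ] <- sample(4, 30, replace = TRUE)
  mat <- cbind(good, tail_block)
  cs <- call_consensus(as_column_matrix(mat), threshold = 0.14,
                       min_depth = 3, stop_window = 10)
  expect_equal(cs$sequence, strrep("A", 40))
  # a short dip does not terminate: the lone surviving read's bases are
  # still emitted (fraction 1 at depth 1) and calling resumes after it
  mat2 <- cbind(good[, 1:20], tail_block[, 1:5], good[, 1:20])
  cs2 <- call_consensus(as_column_matrix(mat2), threshold = 0.14,
                        min_depth = 3, stop_window = 10)
  dip <- paste(c("A", "C", "G", "T")[mat2[1, 21:25]], collapse = "")
  expect_equal(cs2$sequence,
               paste0(strrep("A", 20), dip, strrep("A", 20)))
})

test_that("raising the threshold never adds called bases", {
  set.seed(52)
  for (case in 1:20) {
    mat <- rand_column_matrix()
    called <- sapply(c(0.05, 0.14, 0.3, 0.51, 0.9), function(th) {
      cs <- call_consensus(as_column_matrix(mat), threshold = th,
                           min_depth = 1, stop_window = 1000)
      sum(strsplit(cs$sequence, "")[[1]] %in% c("A", "C", "G", "T"))
    })
    expect_true(all(diff(called) <= 0))
  }
})

test_that("consensus equals the brute-force per-column oracle", {
  set.seed(53)
  for (case in 1:200) {
    mat <- rand_column_matrix()
    th <- sample(c(0.13, 0.14, 0.3, 0.6), 1)
    cs <- call_consensus(as_column_matrix(mat), threshold = th,
                         min_depth = 1, stop_window = 10000)
    expect_identical(cs$sequence, oracle_consensus(mat, th))
  }
})

test_that("support profile exposes per-column depth and winner fraction", {
  mat <- rbind(code(c("A", "C", "G")), code(c("A", "C", "G")),
               c(code("A"), NA, NA))
  cs <- call_consensus(as_column_matrix(mat), threshold = 0.14,
                       min_depth = 1)
  pr <- consensus_support_profile(cs)
  expect_equal(pr$column, 0:2)
  expect_equal(pr$depth, c(3L, 2L, 2L))
  expect_equal(pr$winner_fraction, c(1, 1, 1))
})

test_that("anchored stacks show non-increasing smoothed depth", {
  tr <- benchmark_truth(seed = 54)
  em <- error_model(0.07, 0.02, 0.01, read_length_mean = 2000,
                    read_length_max = 6000, seed = 54)
  reads <- sample_reads(tr, em, 40)
  fl <- truth_flanks(tr)
  sel <- select_anchored_reads(reads, fl$flank5, fl$flank3)
  cs <- call_consensus(build_msa(sel$flank5))
  d <- consensus_support_profile(cs)$depth
  sm <- stats::filter(d, rep(1 / 100, 100), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-9 + 0.5))  # no systematic rises
  expect_gte(sm[1], sm[length(sm)])
})

test_that("an empty matrix is an error", {
  expect_error(call_consensus(as_column_matrix(
    matrix(integer(0), 0, 0)), threshold = 0.14), "empty")
})
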