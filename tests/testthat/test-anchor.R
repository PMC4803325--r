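# Group membership and trimming are checked against the true read
# coordinates carried in the simulated read ids.

overlap_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

test_that("membership on noiseless reads matches the coordinate truth", {
  tr <- build_array(array_spec(unit_length = 500, n_copies = 4,
                               flank5_length = 300, flank3_length = 300,
                               inter_unit_divergence = 0.01, seed = 31))
  em <- error_model(0, 0, 0, read_length_mean = 1200,
                    read_length_max = 3000, seed = 31)
  reads <- sample_reads(tr, em, 60)
  fl <- truth_flanks(tr)
  sel <- select_anchored_reads(reads, fl$flank5, fl$flank3,
                               min_anchor_cov = 0.6)
  truth <- parse_read_truth(vapply(reads, `[[`, "", "id"))
  cov5 <- mapply(overlap_len, truth$start, truth$end,
                 tr$flank5[["start"]], tr$flank5[["end"]])
  cov3 <- mapply(overlap_len, truth$start, truth$end,
                 tr$flank3[["start"]], tr$flank3[["end"]])
  expect_setequal(vapply(sel$flank5, `[[`, "", "read_id"),
                  truth$id[cov5 >= 0.6 * 300])
  expect_setequal(vapply(sel$flank3, `[[`, "", "read_id"),
                  truth$id[cov3 >= 0.6 * 300])
})

test_that("noiseless trimming recovers the true locus suffix", {
  tr <- build_array(array_spec(unit_length = 400, n_copies = 3,
                               flank5_length = 250, flank3_length = 250,
                               seed = 32))
  em <- error_model(0, 0, 0, read_length_mean = 900,
                    read_length_max = 2000, seed = 32)
  reads <- sample_reads(tr, em, 50)
  fl <- truth_flanks(tr)
  sel <- select_anchored_reads(reads, fl$flank5, fl$flank3)
  truth <- parse_read_truth(vapply(reads, `[[`, "", "id"))
  rownames(truth) <- truth$id
  for (a in sel$flank5) {
    iv <- truth[a$read_id, ]
    from <- max(iv$start, tr$flank5[["start"]])
    expect_identical(a$seq, substr(tr$full_sequence, from + 1, iv$end))
    expect_equal(a$anchor_offset, from - tr$flank5[["start"]])
  }
  for (a in sel$flank3) {
    # flank3-anchored reads are stored reverse-complemented: the anchor
    # (revcomp of flank3) at the 5' end, the array extending 3' of it
    iv <- truth[a$read_id, ]
    to <- min(iv$end, tr$flank3[["end"]])
    expect_identical(a$seq,
                     revcomp(substr(tr$full_sequence, iv$start + 1, to)))
  }
})

test_that("a read built as revcomp(array + flank3) anchors in the 3' group", {
  tr <- build_array(array_spec(unit_length = 400, n_copies = 2,
                               flank5_length = 250, flank3_length = 250,
                               seed = 33))
  fl <- truth_flanks(tr)
  frag <- substr(tr$full_sequence, tr$units$start[2] + 1,
                 tr$flank3[["end"]])       # unit2 + flank3, forward
  rd <- seq_record("r", revcomp(frag))
  sel <- select_anchored_reads(list(rd), fl$flank5, fl$flank3)
  expect_length(sel$flank3, 1)
  expect_length(sel$flank5, 0)
  expect_true(startsWith(sel$flank3[[1]]$seq, revcomp(fl$flank3)))
})

test_that("group membership and trimmed sequences are strand-invariant", {
  tr <- benchmark_truth(seed = 34)
  em <- error_model(0.05, 0.02, 0.01, read_length_mean = 2000,
                    read_length_max = 6000, seed = 34)
  reads <- sample_reads(tr, em, 30)
  flipped <- lapply(reads, function(r)
    seq_record(r$id, revcomp(r$seq), r$qual))
  fl <- truth_flanks(tr)
  s1 <- select_anchored_reads(reads, fl$flank5, fl$flank3)
  s2 <- select_anchored_reads(flipped, fl$flank5, fl$flank3)
  for (g in c("flank5", "flank3")) {
    expect_equal(vapply(s1[[g]], `[[`, "", "read_id"),
                 vapply(s2[[g]], `[[`, "", "read_id"))
    expect_equal(lapply(s1[[g]], `[[`, "seq"),
                 lapply(s2[[g]], `[[`, "seq"))
  }
  expect_equal(s1$report, s2$report)
})

test_that("a read spanning the whole array joins both groups", {
  tr <- build_array(array_spec(unit_length = 300, n_copies = 2,
                               flank5_length = 200, flank3_length = 200,
                               seed = 35))
  fl <- truth_flanks(tr)
  rd <- seq_record("span", tr$full_sequence)
  sel <- select_anchored_reads(list(rd), fl$flank5, fl$flank3)
  expect_length(sel$flank5, 1)
  expect_length(sel$flank3, 1)
  expect_equal(sel$report$n_reads, c(1L, 1L))
})

test_that("empty input and similar flanks are handled", {
  tr <- build_array(array_spec(unit_length = 300, n_copies = 2, seed = 36))
  fl <- truth_flanks(tr)
  sel <- select_anchored_reads(list(), fl$flank5, fl$flank3)
  expect_length(sel$flank5, 0)
  expect_equal(sel$report$n_reads, c(0L, 0L))
  expect_equal(sel$report$max_length, c(0L, 0L))
  expect_error(select_anchored_reads(list(), fl$flank5, fl$flank5),
               "dissimilar")
})

test_that("the report max length equals the longest trimmed read", {
  tr <- benchmark_truth(seed = 37)
  em <- error_model(0, 0, 0, read_length_mean = 2000,
                    read_length_max = 5000, seed = 37)
  reads <- sample_reads(tr, em, 25)
  fl <- truth_flanks(tr)
  sel <- select_anchored_reads(reads, fl$flank5, fl$flank3)
  for (g in c("flank5", "flank3")) {
    lens <- vapply(sel[[g]], function(a) nchar(a$seq), integer(1))
    expect_equal(sel$report$max_length[sel$report$group == g],
                 max(lens, 0L))
    expect_equal(sel$report$n_reads[sel$report$group == g], length(lens))
  }
})
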