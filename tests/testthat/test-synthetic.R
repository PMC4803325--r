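test_that("array length follows the locus arithmetic", {
  tr <- build_array(array_spec(unit_length = 3300, n_copies = 13.5,
                               flank5_length = 500, flank3_length = 500,
                               seed = 1))
  expect_equal(nchar(tr$full_sequence), 500 + 13 * 3300 + 1650 + 500)
  expect_equal(nrow(tr$units), 14)
  expect_true(tr$units$partial[14])
  expect_false(any(tr$units$partial[1:13]))
})

test_that("a single zero-divergence copy equals the template", {
  tr <- build_array(array_spec(unit_length = 400, n_copies = 1,
                               inter_unit_divergence = 0, seed = 2))
  expect_equal(nrow(tr$units), 1)
  expect_equal(tr$units$sequence[1], tr$unit_template)
})

test_that("unit GC tracks the requested fraction", {
  for (gc in c(0.5, 0.70)) {
    tr <- build_array(array_spec(unit_length = 2000, n_copies = 3,
                                 unit_gc = gc, seed = 5))
    for (u in tr$units$sequence)
      expect_lt(abs(gc_fraction(u) - gc), 0.03)
  }
})

test_that("interval concatenation reconstructs the full sequence", {
  for (spec in list(
    array_spec(unit_length = 300, n_copies = 4.5, flank5_length = 120,
               flank3_length = 150, seed = 3),
    array_spec(unit_length = 300, n_copies = 2, flank5_length = 120,
               flank3_length = 120, include_inverted_distractor = TRUE,
               distractor_offset = 200, seed = 4))) {
    tr <- build_array(spec)
    s <- tr$full_sequence
    # units are adjacent, ordered, and match their recorded sequences
    expect_equal(tr$units$start[1], tr$flank5[["end"]])
    expect_equal(tr$flank3[["start"]], tr$units$end[nrow(tr$units)])
    if (nrow(tr$units) > 1)
      expect_equal(tr$units$start[-1], tr$units$end[-nrow(tr$units)])
    for (i in seq_len(nrow(tr$units)))
      expect_equal(substr(s, tr$units$start[i] + 1, tr$units$end[i]),
                   tr$units$sequence[i])
    expect_equal(tr$flank3[["end"]], nchar(s))
    if (!is.null(tr$distractor))
      expect_equal(tr$flank5[["start"]],
                   tr$distractor[["end"]] + spec$distractor_offset)
  }
})

test_that("generation is deterministic under a fixed seed", {
  sp <- array_spec(unit_length = 300, n_copies = 2.5, seed = 7)
  expect_identical(build_array(sp), build_array(sp))
  tr <- build_array(sp)
  em <- error_model(0.05, 0.03, 0.01, read_length_mean = 400,
                    read_length_max = 900, seed = 9)
  expect_identical(sample_reads(tr, em, 25), sample_reads(tr, em, 25))
})

test_that("invalid specs and models are rejected", {
  expect_error(array_spec(n_copies = 0.25), "n_copies")
  expect_error(array_spec(n_copies = 1.3), "n_copies")
  expect_error(array_spec(flank5_length = 50), "flank")
  expect_error(array_spec(inter_unit_divergence = 0.5), "divergence")
  expect_error(error_model(0.10, 0.10, 0.01), "ceiling")
  expect_error(error_model(0.01, 0.01, 0.01, read_length_mean = 500,
                           read_length_max = 100), "read_length")
})

test_that("inter-unit divergence yields the expected pairwise identity", {
  # two copies each mutated at 2% of sites: a site differs with
  # probability 2q(1-q) + q^2 * 2/3, about 3.95%, so identity ~ 96%
  tr <- build_array(array_spec(unit_length = 500, n_copies = 4,
                               inter_unit_divergence = 0.02, seed = 7))
  ids <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    cmp <- compare_units(tr$units$sequence[i], tr$units$sequence[j])
    ids <- c(ids, cmp$percent_identity)
  }
  expect_true(all(ids > 93), info = paste(round(ids, 2), collapse = " "))
  expect_lt(abs(mean(ids) - 96.05), 1.5)
})

test_that("noiseless reads are exact substrings of the locus", {
  tr <- build_array(array_spec(unit_length = 300, n_copies = 3,
                               seed = 8))
  em <- error_model(0, 0, 0, read_length_mean = 400,
                    read_length_max = 900, seed = 8)
  reads <- sample_reads(tr, em, 30)
  truth <- parse_read_truth(vapply(reads, `[[`, "", "id"))
  for (k in seq_along(reads)) {
    fwd <- substr(tr$full_sequence, truth$start[k] + 1, truth$end[k])
    expected <- if (truth$strand[k] == "+") fwd else revcomp(fwd)
    expect_identical(reads[[k]]$seq, expected)
    expect_true(grepl(reads[[k]]$seq, tr$full_sequence, fixed = TRUE) ||
                grepl(reads[[k]]$seq, revcomp(tr$full_sequence),
                      fixed = TRUE))
  }
})

test_that("read lengths hit the configured mean on a long molecule", {
  tr <- build_array(array_spec(unit_length = 3300, n_copies = 30,
                               seed = 10))
  em <- error_model(0, 0, 0, read_length_mean = 4500,
                    read_length_max = 32000, seed = 10)
  reads <- sample_reads(tr, em, 10000)
  lens <- vapply(reads, function(r) nchar(r$seq), integer(1))
  expect_lt(abs(mean(lens) - 4500) / 4500, 0.05)
  expect_lte(max(lens), 32000)
})

test_that("corrupt honours its edge cases", {
  em0 <- error_model(0, 0, 0)
  s <- rand_dna(500)
  expect_identical(corrupt(s, em0), s)
  em_del <- error_model(0, 1, 0, max_total = 1)
  expect_identical(corrupt(s, em_del), "")
})

test_that("realized error rate matches the configured rate", {
  set.seed(1)
  s <- rand_dna(50000)
  em <- error_model(0.07, 0.04, 0.01, seed = NULL)
  set.seed(2)
  cr <- corrupt(s, em)
  rate <- edit_distance(s, cr) / nchar(s)
  expect_gt(rate, 0.12 * 0.8)
  expect_lt(rate, 0.12 * 1.2)
})
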