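test_that("segmentation recovers configured copy numbers exactly", {
  for (nc in c(1, 1.5, 2.5, 4, 6.5, 10)) {
    tr <- build_array(array_spec(unit_length = 300, n_copies = nc,
                                 inter_unit_divergence = 0,
                                 flank5_length = 150, flank3_length = 150,
                                 seed = 60 + nc * 2))
    seg <- segment_units(tr$full_sequence, tr$unit_template)
    expect_equal(count_copies(seg), nc, info = paste("n_copies", nc))
    # zero divergence: intervals sit at the true coordinates
    expect_equal(seg$intervals$start, tr$units$start)
    expect_equal(seg$intervals$end, tr$units$end)
    expect_equal(seg$intervals$partial, tr$units$partial)
  }
})

test_that("divergent copies are still counted correctly", {
  tr <- build_array(array_spec(unit_length = 500, n_copies = 6.5,
                               inter_unit_divergence = 0.02, seed = 61))
  seg <- segment_units(tr$full_sequence, tr$unit_template)
  expect_equal(count_copies(seg), 6.5)
})

test_that("an inverted copy is reported as a distractor, not a unit", {
  tr <- build_array(array_spec(unit_length = 300, n_copies = 3,
                               inter_unit_divergence = 0,
                               include_inverted_distractor = TRUE,
                               distractor_offset = 300, seed = 62))
  seg <- segment_units(tr$full_sequence, tr$unit_template)
  expect_equal(count_copies(seg), 3)
  expect_equal(nrow(seg$distractors), 1)
  expect_equal(seg$distractors$start, tr$distractor[["start"]])
  expect_equal(seg$distractors$end, tr$distractor[["end"]])
})

test_that("a probe absent from a random sequence yields no segments", {
  set.seed(63)
  seg <- segment_units(rand_dna(3000), rand_dna(200))
  expect_equal(nrow(seg$intervals), 0)
  expect_equal(count_copies(seg), 0)
})

test_that("compare_units handles the canonical cases", {
  self <- compare_units("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(self$percent_identity, 100)
  expect_equal(self$differences, 0)
  one <- compare_units("ACGT", "ACGA")
  expect_equal(one$percent_identity, 75)
  expect_equal(one$differences, 1)
})

test_that("compare_units is symmetric and consistent with its alignment", {
  set.seed(64)
  for (case in 1:40) {
    a <- rand_dna(sample(10:60, 1))
    b <- mutate_seq(a, p_sub = 0.08, p_ins = 0.05, p_del = 0.05)
    if (nchar(b) == 0) b <- "A"
    ab <- compare_units(a, b)
    ba <- compare_units(b, a)
    expect_equal(ab$percent_identity, ba$percent_identity)
    expect_equal(ab$differences, ba$differences)
    expect_equal(ab$matches + ab$mismatches + ab$gap_columns, ab$columns)
    expect_equal(ab$differences, ab$mismatches + ab$gap_columns)
  }
})

test_that("dotplot matches its brute-force definition", {
  # identical sequences: full main diagonal at exact-match settings
  set.seed(65)
  a <- rand_dna(120)
  d <- dotplot(a, a, window = 20, min_matches = 20)
  expect_true(all((0:(120 - 20)) %in% d$i[d$i == d$j]))

  # 3 exact tandem copies vs the unit: 3 clean diagonals
  u <- rand_dna(60)
  d3 <- dotplot(strrep(u, 3), u, window = 20, min_matches = 20)
  diags <- unique(d3$i - d3$j)
  expect_setequal(diags, c(0L, 60L, 120L))

  # random pair: agree with a direct double loop
  b <- rand_dna(80); c2 <- rand_dna(70)
  d2 <- dotplot(b, c2, window = 8, min_matches = 6)
  bv <- strsplit(b, "")[[1]]; cv <- strsplit(c2, "")[[1]]
  expected <- list()
  for (i in 0:(80 - 8)) for (j in 0:(70 - 8)) {
    if (sum(bv[i + 1:8] == cv[j + 1:8]) >= 6)
      expected[[length(expected) + 1]] <- c(i, j)
  }
  exp_df <- do.call(rbind, expected)
  expect_equal(nrow(d2), nrow(exp_df))
  expect_equal(d2$i, exp_df[, 1])
  expect_equal(d2$j, exp_df[, 2])
})

test_that("motif scanning follows IUPAC semantics", {
  # R = A/G, Y = C/T: "RY" hits "AC" but not "AG"
  hits_ac <- scan_motifs(list(u = "AC"), c(m = "RY"))
  expect_equal(hits_ac$hits$start, 0L)
  hits_ag <- scan_motifs(list(u = "AG"), c(m = "RY"))
  expect_equal(nrow(hits_ag$hits), 0)
  expect_error(scan_motifs(list(u = "ACGT"), c(m = "AZ")), "IUPAC")
  empty <- scan_motifs(list(u = "ACGT"), character(0))
  expect_equal(nrow(empty$hits), 0)
  expect_equal(nrow(empty$conserved), 0)
})

test_that("motifs at homologous offsets are reported conserved", {
  set.seed(66)
  core <- rand_dna(120)
  units <- lapply(1:4, function(i)
    paste0(core, "TACAA", rand_dna(40)))
  names(units) <- paste0("u", 1:4)
  sc <- scan_motifs(units, c(tacaa = "TACAA", gcbox = "GGGCGG"))
  expect_true(120 %in% sc$conserved$offset[sc$conserved$motif == "tacaa"])
  # a motif present in only one unit is not conserved
  units$u1 <- paste0(units$u1, "GGGCGG")
  sc2 <- scan_motifs(units, c(gcbox = "GGGCGG"))
  expect_false("gcbox" %in% sc2$conserved$motif)
})

test_that("in silico digestion conserves total length", {
  expect_equal(in_silico_digest("AAAGATATCAAA", c(EcoRV = "GATATC")),
               c(6L, 6L))
  set.seed(67)
  s <- rand_dna(400)
  expect_equal(in_silico_digest(s, c(none = "ACGTACGTAC")), 400L)
  for (case in 1:25) {
    s <- rand_dna(sample(200:2000, 1))
    site <- rand_dna(sample(4:6, 1))
    fr <- in_silico_digest(s, setNames(site, "e"))
    expect_equal(sum(fr), nchar(s))
  }
})

test_that("non-palindromic sites cut on both strands at mirrored offsets", {
  # site ACGGT cut at offset 1 (after 1 base); its revcomp ACCGT is also
  # cut, at offset 5 - 1 = 4
  s <- paste0("TTTT", "ACGGT", "TTTT", "ACCGT", "TTTT")
  fr <- in_silico_digest(s, data.frame(enzyme = "e", recognition = "ACGGT",
                                       cut_offset = 1L))
  expect_equal(sum(fr), nchar(s))
  expect_equal(fr, c(5L, 12L, 5L))
  expect_error(in_silico_digest("ACGT", c(e = "GATNTC")), "degenerate")
})

test_that("copy number from region length reproduces the 48 kb reading", {
  expect_equal(estimate_copies_from_length(48000, 3300, 3450), 13.5)
  expect_equal(estimate_copies_from_length(3300 + 1000, 3300, 1000), 1.0)
  expect_error(estimate_copies_from_length(1000, 3300, 1000), "exceed")
})
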