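---
title: "Anchored consensus assembly of tandem repeat arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored consensus assembly of tandem repeat arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorcons)
```

## The method

Tandem macrosatellite arrays such as D4Z4 (3.3 kb units, ~70% GC, 8–100
copies in healthy chromosomes) defeat both mapping and overlap assembly:
a read internal to the array fits every copy nearly equally well, and the
unit-to-unit divergence (a percent or less) is an order of magnitude
below the error rate of long single-molecule reads, whose
insertion/deletion-dominated errors can reach 15%. `anchorcons`
reconstructs such arrays from the outside in, using the unique sequences
flanking the array as placement anchors.

**Anchor selection.** Each read is searched, on both strands, for the 5'
flank and for the reverse complement of the 3' flank. Searching for the
reverse-complemented 3' flank means that after orientation normalization
*both* groups read anchor-first into the array: a read from the forward
strand containing the 3' flank is reverse complemented, putting the
anchor at its 5' end with the distal array copies following. A read
joins a group when its best flank hit covers at least `min_anchor_cov`
of the flank at `min_identity` or better; it is trimmed to begin at the
hit (the anchor is retained as the left edge of the stack), and a read
containing both flanks — one spanning the whole array — joins both
groups. The hit itself comes from a seeded local aligner: exact k-mer
seeds, clustered by diagonal, each cluster extended by Smith–Waterman in
a window.

**Anchored star alignment.** A group is stacked into a gapped column
matrix over `{A,C,G,T,-}` with a missing mask beyond each read's extent.
The longest read (among those whose hit covers the most flank) is the
initial backbone; every read is aligned to it by banded global alignment
that is pinned at the anchor end and has free end gaps only at the far
(3') end — reads end wherever the molecule ended, and that must not be
penalized, while the anchored end is a hard constraint. Per-read
insertions are merged into shared insertion columns (left-justified
within each slot), and a single refinement pass re-aligns every read to
the plurality draft of the first stack. The anchor removes the placement
ambiguity that makes general multiple alignment of repeats hard, which
is why a draft-based star alignment in O(reads × length × band)
suffices here. Reads whose anchor hit starts inside the flank carry an
`anchor_offset` and are placed at that offset with a leading missing
region, rather than being force-pinned to column 0 and corrupting the
flank columns.

**Threshold consensus.** Per column, depth is the number of non-missing
rows and the plurality character wins, with two tie rules: `-` loses to
any base, and tied bases resolve alphabetically (A < C < G < T). A
winning base is emitted when its fraction of depth reaches the
threshold; a sub-threshold winner emits `N`; a gap-plurality column
emits nothing, which is what removes the insertion noise that dominates
this read type. The working threshold range for such data is 13–14%,
originally chosen by inspecting alignments toward the 3' end where
signal-to-noise decays.

Two details of the rule are deliberate interpretations and are flagged
as such:

* **Denominator.** The threshold fraction is taken over the column depth
  (non-missing rows), not the total read count. Coverage in an anchored
  stack decays with distance from the anchor as shorter reads drop out;
  against a total-read denominator a single threshold would be
  meaningless in exactly the distal region the method exists to reach.
* **Termination.** Instead of stopping at a visually chosen point,
  calling stops at the first run of `stop_window` consecutive
  low-support columns — a column is low-support when its depth falls
  below `min_depth` or it emitted `N` — and the consensus is trimmed
  back to the last confidently called base. A lone bad column does not
  terminate; a sustained collapse does.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `seed_length` | 13 | exact-seed length for flank/probe search. A 50-mer exact seed (the classic near-perfect-read setting) almost never survives 10–15% indel errors; 13 keeps the expected number of surviving seeds per 500 b flank high while random 13-mer hits stay rare. Configurable up to 50 for clean sequences. |
| `min_identity` | 0.85 | minimum alignment identity of an anchor/probe hit; matches the classic 85% extraction threshold for this task. |
| `min_anchor_cov` | 0.6 | fraction of the flank a hit must cover. Prevents anchoring on a few-bp spurious match; 0.6 of a 500 b flank still admits reads that enter the flank up to 200 b from its edge. |
| scoring | +2 / −4 / −4 / −2 | match, mismatch, gap open, gap extend (a gap run of length L costs open + L·extend) — blastn-like scoring tolerant of indel-rich reads. |
| `band` | 200 | half-width (columns) of the banded alignment; doubled automatically (up to 8×) if the optimal path touches the band edge. Generous relative to the indel drift of a few-kb read at ≤15% error. |
| `threshold` | 0.14 | consensus calling threshold (13% and 14% are the reference settings for the two chemistries this method was developed on). |
| `min_depth` | 3 | below this depth a column counts as low-support for termination. |
| `stop_window` | 50 | consecutive low-support columns that terminate calling. |

## What the simulator emulates — and what it does not

`build_array()` generates one random unit template at the requested GC
(default 0.70 against ~0.5 flanks, matching the GC contrast of the
motivating locus), derives each copy by independent per-base
substitutions at `inter_unit_divergence`, truncates the distal-most unit
at its 3' side when the copy number is half-integral (13.5 copies means
13 full units plus a 5' half — the locus diagram places the partial unit
at the distal end), and frames the array with unique flanks of 500 b by
default. An optional inverted unit copy upstream of the 5' flank
reproduces the DUX4c-like misassembly hazard; it is off by default so
that default tests probe the core path.

`sample_reads()` draws read lengths log-normal (sdlog fixed at 0.55,
meanlog set so the mean matches `read_length_mean`; with a 4,500 b mean
the tail reaches past 30 kb at realistic frequency) truncated at
`read_length_max` and the molecule end. The length *family* is a
modeling choice — only mean, N50 and maximum are constrained by the data
this emulates. Each read starts at a uniform position on either strand,
the start being the 5' end of the read *on its own strand*, so
minus-strand reads extend leftward in forward coordinates and both
molecule edges receive coverage, as they do when fragments of a longer
clone overlap the locus. `corrupt()` applies, per position,
deletion/substitution (mutually exclusive) and insertion-after events at
the configured rates; the expected edit distance is the summed rate
times length, with a default mix of 7% insertion / 2–4% deletion / 1%
substitution under a configurable 15% ceiling. Read qualities are a
constant placeholder: the consensus never uses base qualities (they are
a QC observable only), though the QC functions ingest real qualities
when present.

Not emulated: chimeric reads and adapter artifacts, sequence-context
error hotspots, quality-correlated error rates, and chemistry-specific
behavior beyond parameter presets. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical error model,
not robustness to every artifact of real instruments.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally and in BED
  output; any 1-based display is formatting. One convention, no
  off-by-one drift.
* `compare_units()` counts each gap column as one difference and reports
  identity as match columns over total alignment columns; the convention
  is recorded in the result object. Because co-optimal global alignments
  can differ in match/gap composition, the unordered pair is aligned in
  a canonical orientation so comparison results are exactly symmetric.
* Local-hit ties break by score, then leftmost target position, then the
  plus strand. Unit segmentation chains hits greedily by score (then
  leftmost), discards candidates overlapping a chosen hit by more than
  10% of the probe, flags hits covering 30–85% of the probe as partial
  units, and reports minus-strand hits separately as distractors rather
  than copies.
* Restriction cuts default to the midpoint of the recognition site
  (blunt EcoRV-style); for non-palindromic sites the cut offset is part
  of the site definition and is mirrored on the opposite strand.
  Fragment lengths always sum to the input length.
* No motif set ships with the package: the relevant promoter motifs
  (PRE, YY1, GC box, TACAA box and the like) are named in the
  literature without canonical sequences, so shipping defaults would be
  invention; motifs are user configuration.
* `estimate_copies_from_length()` is deliberately transparent about
  being model-dependent: the flank total encodes how much of the
  measured region is attributed to unique sequence, and the result is
  reported at half-unit resolution because that is the physical
  resolution of a truncated terminal unit.
* Band overflow raises after 8 doublings rather than silently returning
  a clipped alignment.

## Test and benchmark sizes

The test suite exercises the full pipeline on a scaled-down standard
benchmark — 6.5 copies of 500 b units, 500 b flanks, 2% inter-unit
divergence, 60 reads of mean 3 kb at 10% total error — chosen so that
stack depths (15–25 per anchor group) and the depth decay toward the 3'
end reproduce the regime of the full-scale problem while a complete run
takes seconds. Property checks (consensus and alignment oracle
equivalence, N50, digestion conservation) run on hundreds to a thousand
randomized small cases under fixed seeds. The acceptance script
additionally segments a full-scale simulated locus (13.5 copies of
3.3 kb units, ~45.6 kb total).

```{r benchmark}
truth <- build_array(array_spec(unit_length = 500, n_copies = 6.5,
                                inter_unit_divergence = 0.02, seed = 42))
model <- error_model(0.07, 0.02, 0.01, read_length_mean = 3000,
                     read_length_max = 10000, seed = 42)
reads <- sample_reads(truth, model, 60)
fl <- truth_flanks(truth)
sel <- select_anchored_reads(reads, fl$flank5, fl$flank3)
sel$report
cons <- call_consensus(build_msa(sel$flank5), threshold = 0.14)
compare_units(substr(cons$sequence, 1, 2000),
              substr(truth$full_sequence, 1, 2000))
```

## Known limitations

* The star alignment assumes the anchor fixes each read's placement; a
  read whose flank hit is spurious (below ~0.85 identity this is
  filtered, but adversarial inputs exist) would be stacked at the wrong
  position and dilute, though rarely flip, the consensus.
* Consensus accuracy is depth-limited: with ~15 reads at 10% error the
  residual error is a few parts per thousand, concentrated where depth
  has decayed. The method reaches as far into the array as the read
  length distribution allows and no further.
* Heterozygosity is out of scope: the consensus model assumes a single
  haplotype (the natural setting for clone-based sequencing). Two
  alleles in one read pool would produce mixed columns, `N` calls, or
  early termination rather than two sequences.
* `coverage_profile()` places each read once, at its best hit; inside a
  repeat array that placement is ambiguous by construction, which is
  surfaced as a multi-hit count instead of multi-placing reads.
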