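# Ground-truth locus and read simulator.
#
# The generator emulates a D4Z4-like macrosatellite locus: a tandem array
# of GC-rich ~3.3 kb units with small inter-unit divergence, unique 500 bp
# flanks on both sides, optionally an inverted distractor copy upstream
# (the DUX4c hazard), and indel-dominated long reads with a long-tailed
# length distribution.

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb
#' the caller's RNG stream.
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed) || length(seed) == 0L) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic tandem-repeat locus
#'
#' Defaults mirror the motivating locus: 3.3 kb units at 70% GC in a
#' 13.5-copy array (the truncated terminal unit counts 0.5), with 500 bp
#' unique flanks.
#'
#' @param unit_length repeat-unit length in bases.
#' @param n_copies copy number in half-unit steps (e.g. 13.5); the partial
#'   copy is the distal-most unit, truncated at its 3' side.
#' @param unit_gc GC fraction of the unit template.
#' @param inter_unit_divergence per-base substitution rate applied
#'   independently to each unit copy (in `[0, 0.2]`).
#' @param flank5_length,flank3_length unique flank lengths (>= 100).
#' @param include_inverted_distractor place an inverted unit copy upstream
#'   of the 5' flank (off by default).
#' @param distractor_offset spacer between the distractor and the 5' flank.
#' @param seed integer seed for deterministic generation.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(unit_length = 3300, n_copies = 13.5, unit_gc = 0.70,
                       inter_unit_divergence = 0.01,
                       flank5_length = 500, flank3_length = 500,
                       include_inverted_distractor = FALSE,
                       distractor_offset = 1000, seed = 1L) {
  s <- structure(list(
    unit_length = as.integer(unit_length), n_copies = n_copies,
    unit_gc = unit_gc, inter_unit_divergence = inter_unit_divergence,
    flank5_length = as.integer(flank5_length),
    flank3_length = as.integer(flank3_length),
    include_inverted_distractor = isTRUE(include_inverted_distractor),
    distractor_offset = as.integer(distractor_offset),
    seed = as.integer(seed)), class = "array_spec")
  validate_array_spec(s)
  s
}

validate_array_spec <- function(s) {
  if (!isTRUE(all.equal(s$n_copies * 2, round(s$n_copies * 2))) ||
      s$n_copies < 0.5)
    stop("array_spec: n_copies must be >= 0.5 in half-unit steps")
  if (s$unit_gc < 0 || s$unit_gc > 1)
    stop("array_spec: unit_gc must be in [0, 1]")
  if (s$inter_unit_divergence < 0 || s$inter_unit_divergence > 0.2)
    stop("array_spec: inter_unit_divergence must be in [0, 0.2]")
  if (s$flank5_length < 100 || s$flank3_length < 100)
    stop("array_spec: flanks shorter than 100 bases make anchors unusable")
  if (s$unit_length < 2) stop("array_spec: unit_length too short")
  invisible(s)
}

#' Long-read error model
#'
#' Indel-dominated random errors of single-molecule long reads. The default
#' total rate is 12% (7% insertion, 2% deletion, 1% substitution sums to
#' 10%; pass explicit rates to change the mix); the configurable ceiling of
#' 15% reflects the worst case for this read type.
#'
#' @param insertion_rate,deletion_rate,substitution_rate per-base event
#'   probabilities.
#' @param read_length_mean,read_length_max mean and maximum read length in
#'   bases (lengths are drawn log-normal and truncated at the maximum).
#' @param seed integer seed used by [sample_reads()].
#' @param max_total ceiling on the summed rates (default 0.15).
#' @return An object of class `error_model`.
#' @export
error_model <- function(insertion_rate = 0.07, deletion_rate = 0.04,
                        substitution_rate = 0.01,
                        read_length_mean = 4500, read_length_max = 32000,
                        seed = 1L, max_total = 0.15) {
  m <- structure(list(
    insertion_rate = insertion_rate, deletion_rate = deletion_rate,
    substitution_rate = substitution_rate,
    read_length_mean = as.numeric(read_length_mean),
    read_length_max = as.numeric(read_length_max),
    seed = as.integer(seed), max_total = max_total), class = "error_model")
  validate_error_model(m)
  m
}

validate_error_model <- function(m) {
  rates <- c(m$insertion_rate, m$deletion_rate, m$substitution_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("error_model: rates must be probabilities")
  if (sum(rates) > m$max_total)
    stop("error_model: total error rate ", sum(rates),
         " exceeds ceiling ", m$max_total)
  if (!(m$read_length_max >= m$read_length_mean && m$read_length_mean > 0))
    stop("error_model: need read_length_max >= read_length_mean > 0")
  invisible(m)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Apply per-position substitutions at the given rate (to a random
# different base); used for inter-unit divergence.
diverge <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < rate
  n <- sum(hit)
  if (n > 0) {
    shift <- sample.int(3L, n, replace = TRUE)
    ch[hit] <- BASES[(match(ch[hit], BASES) - 1L + shift) %% 4L + 1L]
  }
  paste(ch, collapse = "")
}

#' Build a ground-truth repeat locus
#'
#' One random unit template is drawn at the requested GC; each copy derives
#' from it by independent per-base substitutions at
#' `inter_unit_divergence`. A half copy is the distal-most unit truncated
#' at its 3' side. The full sequence is (optional inverted distractor +
#' spacer) + 5' flank + units + 3' flank.
#'
#' @param spec an [array_spec()].
#' @return An object of class `array_truth` with fields `full_sequence`,
#'   `flank5`, `flank3` (0-based half-open intervals), `units` (data frame
#'   of `index`, `start`, `end`, `partial`, `sequence`), `distractor`
#'   (interval or `NULL`), `unit_template`, and `spec`.
#' @examples
#' tr <- build_array(array_spec(unit_length = 500, n_copies = 2.5,
#'                              flank5_length = 150, flank3_length = 150,
#'                              seed = 3))
#' nchar(tr$full_sequence)
#' @export
build_array <- function(spec) {
  validate_array_spec(spec)
  with_seed(spec$seed, {
    template <- random_dna(spec$unit_length, spec$unit_gc)
    n_full <- floor(spec$n_copies)
    has_partial <- (spec$n_copies - n_full) > 0
    n_units <- n_full + has_partial
    unit_seqs <- character(n_units)
    partial <- logical(n_units)
    for (i in seq_len(n_units)) {
      u <- diverge(template, spec$inter_unit_divergence)
      if (has_partial && i == n_units) {
        u <- substr(u, 1L, as.integer(round(spec$unit_length / 2)))
        partial[i] <- TRUE
      }
      unit_seqs[i] <- u
    }
    flank5 <- random_dna(spec$flank5_length, 0.5)
    flank3 <- random_dna(spec$flank3_length, 0.5)

    prefix <- ""
    distractor <- NULL
    if (spec$include_inverted_distractor) {
      dunit <- revcomp(diverge(template, spec$inter_unit_divergence))
      spacer <- random_dna(spec$distractor_offset, 0.5)
      prefix <- paste0(dunit, spacer)
      distractor <- c(start = 0L, end = nchar(dunit))
    }
    pre_len <- nchar(prefix)
    f5 <- c(start = pre_len, end = pre_len + spec$flank5_length)
    pos <- f5[["end"]]
    starts <- integer(n_units); ends <- integer(n_units)
    for (i in seq_len(n_units)) {
      starts[i] <- pos
      pos <- pos + nchar(unit_seqs[i])
      ends[i] <- pos
    }
    f3 <- c(start = pos, end = pos + spec$flank3_length)
    full <- paste0(prefix, flank5, paste(unit_seqs, collapse = ""), flank3)

    structure(list(
      full_sequence = full,
      flank5 = f5, flank3 = f3,
      units = data.frame(index = seq_len(n_units), start = starts,
                         end = ends, partial = partial,
                         sequence = unit_seqs,
                         stringsAsFactors = FALSE),
      distractor = distractor,
      unit_template = template,
      spec = spec), class = "array_truth")
  })
}

#' @export
print.array_truth <- function(x, ...) {
  cat("<array_truth> ", nchar(x$full_sequence), " bp: ",
      x$spec$n_copies, " x ", x$spec$unit_length, " bp units, flanks ",
      x$spec$flank5_length, "/", x$spec$flank3_length, " bp",
      if (!is.null(x$distractor)) ", inverted distractor", "\n", sep = "")
  invisible(x)
}

#' Flank sequences of a truth locus
#' @param truth an [build_array()] result.
#' @return list with `flank5` and `flank3` sequence strings.
#' @export
truth_flanks <- function(truth) {
  s <- truth$full_sequence
  list(flank5 = substr(s, truth$flank5[["start"]] + 1L, truth$flank5[["end"]]),
       flank3 = substr(s, truth$flank3[["start"]] + 1L, truth$flank3[["end"]]))
}

#' Truth intervals as a BED-shaped data frame
#' @param truth an `array_truth`.
#' @param chrom chromosome/contig name to use.
#' @return data frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open).
#' @export
truth_to_bed <- function(truth, chrom = "locus") {
  rows <- list(
    data.frame(chrom = chrom, start = truth$flank5[["start"]],
               end = truth$flank5[["end"]], name = "flank5",
               score = 0L, strand = "+", stringsAsFactors = FALSE),
    data.frame(chrom = chrom, start = truth$units$start,
               end = truth$units$end,
               name = ifelse(truth$units$partial,
                             paste0("unit", truth$units$index, "_partial"),
                             paste0("unit", truth$units$index)),
               score = 0L, strand = "+", stringsAsFactors = FALSE),
    data.frame(chrom = chrom, start = truth$flank3[["start"]],
               end = truth$flank3[["end"]], name = "flank3",
               score = 0L, strand = "+", stringsAsFactors = FALSE))
  if (!is.null(truth$distractor))
    rows <- c(rows, list(data.frame(
      chrom = chrom, start = truth$distractor[["start"]],
      end = truth$distractor[["end"]], name = "distractor",
      score = 0L, strand = "-", stringsAsFactors = FALSE)))
  do.call(rbind, rows)
}

#' Corrupt a sequence with indel-dominated random errors
#'
#' Per position, independently: deletion with `deletion_rate`; otherwise
#' substitution to a random different base with `substitution_rate`; and an
#' insertion of a uniform random base after the position with
#' `insertion_rate`. The expected edit distance to the input is about
#' `(p_del + p_sub + p_ins) * length`. Uses the current RNG stream.
#'
#' @param seq DNA string.
#' @param model an [error_model()].
#' @return The corrupted sequence.
#' @export
corrupt <- function(seq, model) {
  validate_error_model(model)
  stopifnot(nchar(seq) > 0)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  u <- runif(n)
  v <- runif(n)
  del <- u < model$deletion_rate
  sub <- !del & u < model$deletion_rate + model$substitution_rate
  ns <- sum(sub)
  if (ns > 0) {
    shift <- sample.int(3L, ns, replace = TRUE)
    orig <- match(ch[sub], BASES)
    orig[is.na(orig)] <- sample.int(4L, sum(is.na(orig)), replace = TRUE)
    ch[sub] <- BASES[(orig - 1L + shift) %% 4L + 1L]
  }
  ins <- v < model$insertion_rate
  insvec <- character(n)
  if (any(ins)) insvec[ins] <- sample(BASES, sum(ins), replace = TRUE)
  ch[del] <- ""
  paste(paste0(ch, insvec), collapse = "")
}

#' Simulate noisy long reads from a truth locus
#'
#' Each read starts at a uniformly random position on either strand — the
#' start is the read's 5' end on its own strand, so minus-strand reads
#' extend leftward in forward coordinates and both molecule ends receive
#' coverage. Lengths are drawn log-normal (sdlog 0.55, meanlog set so the
#' mean matches `read_length_mean`), truncated at `read_length_max` and at
#' the molecule end; each read is then corrupted by [corrupt()]. Read ids
#' encode the true forward-strand interval (0-based half-open,
#' pre-corruption) and strand.
#'
#' @param truth an `array_truth`.
#' @param model an [error_model()]; its `seed` makes the call
#'   deterministic.
#' @param n_reads number of reads (>= 1).
#' @return list of [seq_record] objects.
#' @export
sample_reads <- function(truth, model, n_reads) {
  validate_error_model(model)
  stopifnot(n_reads >= 1)
  mol <- truth$full_sequence
  L <- nchar(mol)
  sdlog <- 0.55
  meanlog <- log(model$read_length_mean) - sdlog^2 / 2
  with_seed(model$seed, {
    out <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      len <- round(rlnorm(1, meanlog, sdlog))
      len <- max(30, min(len, model$read_length_max))
      pos <- sample.int(L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      if (strand == "+") {
        start <- pos
        end <- min(L, pos + len)
      } else {
        start <- max(0L, pos + 1L - len)
        end <- pos + 1L
      }
      raw <- substr(mol, start + 1L, end)
      if (strand == "-") raw <- revcomp(raw)
      id <- sprintf("read%05d|start=%d|end=%d|strand=%s",
                    i, start, end, strand)
      out[[i]] <- seq_record(id, corrupt(raw, model))
    }
    out
  })
}

#' Parse the ground-truth coordinates encoded in simulated read ids
#' @param ids character vector of read ids from [sample_reads()].
#' @return data frame with `id`, `start`, `end`, `strand`.
#' @export
parse_read_truth <- function(ids) {
  m <- regmatches(ids, regexec(
    "start=(\\d+)\\|end=(\\d+)\\|strand=([+-])", ids))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("parse_read_truth: ids lack encoded coordinates")
  data.frame(id = ids,
             start = as.integer(vapply(m, `[`, "", 2L)),
             end = as.integer(vapply(m, `[`, "", 3L)),
             strand = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}
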