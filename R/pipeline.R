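# End-to-end orchestration: simulate (or load) reads, select anchored
# reads, build the anchored MSAs, call consensus sequences, run the repeat
# analyses and QC, and write a run directory with a machine-readable
# summary. Re-running with the same config is byte-identical.

#' Build a pipeline configuration
#'
#' Either simulate a locus (`spec`/`model`/`n_reads`) or analyze existing
#' files (`reads`, `flank5`, `flank3` paths, plus a `probe` FASTA for the
#' repeat analyses).
#'
#' @param spec an [array_spec()] (simulate mode).
#' @param model an [error_model()] (simulate mode).
#' @param n_reads number of reads to simulate.
#' @param reads,flank5,flank3,probe input file paths (file mode; `probe`
#'   is optional in simulate mode, where the truth unit template is used).
#' @param threshold,min_depth,stop_window consensus parameters, see
#'   [call_consensus()].
#' @param min_identity,min_anchor_cov,seed_length anchor parameters, see
#'   [select_anchored_reads()].
#' @param band MSA band half-width, see [build_msa()].
#' @param scoring alignment scoring, see [default_scoring()].
#' @param motifs optional named IUPAC motif vector for [scan_motifs()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, model = NULL, n_reads = 60L,
                            reads = NULL, flank5 = NULL, flank3 = NULL,
                            probe = NULL,
                            threshold = 0.14, min_depth = 3L,
                            stop_window = 50L,
                            min_identity = 0.85, min_anchor_cov = 0.6,
                            seed_length = 13L, band = 200L,
                            scoring = default_scoring(),
                            motifs = NULL) {
  simulate <- !is.null(spec)
  if (simulate && is.null(model)) model <- error_model()
  if (!simulate && (is.null(reads) || is.null(flank5) || is.null(flank3)))
    stop("pipeline_config: give either a simulation spec or reads + flanks")
  structure(list(
    simulate = simulate, spec = spec, model = model,
    n_reads = as.integer(n_reads),
    reads = reads, flank5 = flank5, flank3 = flank3, probe = probe,
    threshold = threshold, min_depth = as.integer(min_depth),
    stop_window = as.integer(stop_window),
    min_identity = min_identity, min_anchor_cov = min_anchor_cov,
    seed_length = as.integer(seed_length), band = as.integer(band),
    scoring = check_scoring(scoring), motifs = motifs),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- if (!is.null(x$spec)) unclass(x$spec)
  x$model <- if (!is.null(x$model)) unclass(x$model)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- if (!is.null(x$spec)) do.call(array_spec, x$spec)
  model <- if (!is.null(x$model)) do.call(error_model, x$model)
  do.call(pipeline_config, c(
    list(spec = spec, model = model),
    x[setdiff(names(x), c("spec", "model", "simulate"))]))
}

config_md5 <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "wt")
  writeLines(header, con)
  close(con)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}

#' Run the anchored-consensus pipeline end to end
#'
#' Stages: simulate (or load) → select anchored reads → anchored MSA per
#' group → threshold consensus → repeat analysis → QC. All stage outputs
#' land in `out_dir`; `summary.yaml` holds read statistics, the
#' anchored-subread report, the pairwise unit-comparison table and the
#' recovered copy number. Every TSV carries a header line with the seed
#' and the config MD5; identical configs give byte-identical runs.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir output directory (created; must not contain a previous
#'   summary unless `overwrite`).
#' @param overwrite allow writing into an existing run directory.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # startup validation: fail before creating any output
  if (!config$simulate) {
    for (f in c(config$reads, config$flank5, config$flank3, config$probe))
      if (!file.exists(f)) stop("run_pipeline: missing input file '", f, "'")
  }
  if (file.exists(file.path(out_dir, "summary.yaml")) && !overwrite)
    stop("run_pipeline: '", out_dir, "' already holds a run; ",
         "set overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  md5 <- config_md5(config)
  seed <- if (config$simulate) config$spec$seed else NA_integer_
  hdr <- paste0("# anchorcons seed=", seed, " config_md5=", md5)

  truth <- NULL
  if (config$simulate) {
    truth <- stage("simulate", {
      tr <- build_array(config$spec)
      rds <- sample_reads(tr, config$model, config$n_reads)
      write_fasta(list(seq_record("truth", tr$full_sequence)),
                  file.path(out_dir, "truth.fa"))
      write_bed(truth_to_bed(tr), file.path(out_dir, "truth.bed"))
      fl <- truth_flanks(tr)
      write_fasta(list(seq_record("flank5", fl$flank5)),
                  file.path(out_dir, "flank5.fa"))
      write_fasta(list(seq_record("flank3", fl$flank3)),
                  file.path(out_dir, "flank3.fa"))
      write_fastq(rds, file.path(out_dir, "reads.fastq"))
      list(truth = tr, reads = rds, flank5 = fl$flank5, flank3 = fl$flank3,
           probe = tr$unit_template)
    })
  } else {
    truth <- stage("load", {
      rds <- if (grepl("\\.(fq|fastq)(\\.gz)?$", config$reads))
        read_fastq(config$reads) else read_fasta(config$reads)
      probe <- if (!is.null(config$probe))
        read_fasta(config$probe)[[1]]$seq else NULL
      list(truth = NULL, reads = rds,
           flank5 = read_fasta(config$flank5)[[1]]$seq,
           flank3 = read_fasta(config$flank3)[[1]]$seq,
           probe = probe)
    })
  }

  sel <- stage("select", {
    s <- select_anchored_reads(truth$reads, truth$flank5, truth$flank3,
                               min_identity = config$min_identity,
                               min_anchor_cov = config$min_anchor_cov,
                               seed_length = config$seed_length,
                               scoring = config$scoring)
    write_anchored(s, file.path(out_dir, "sel"))
    write_tsv_with_header(s$report, file.path(out_dir, "sel.report.tsv"),
                          hdr)
    s
  })

  consensi <- list()
  for (g in c("flank5", "flank3")) {
    if (length(sel[[g]]) == 0L) next
    mm <- stage(paste0("msa_", g),
                build_msa(sel[[g]], scoring = config$scoring,
                          band = config$band))
    write_msa(mm, file.path(out_dir, paste0("aln.", g, ".afa")))
    cs <- stage(paste0("consensus_", g),
                call_consensus(mm, threshold = config$threshold,
                               min_depth = config$min_depth,
                               stop_window = config$stop_window))
    write_consensus(cs, file.path(out_dir, paste0("cons.", g, ".fa")),
                    id = paste0("consensus_", g),
                    profile_path = file.path(out_dir,
                                             paste0("cons.", g, ".tsv")))
    consensi[[g]] <- cs
  }

  analysis <- stage("analyze", {
    out <- list(copies = NULL, comparisons = NULL, motifs = NULL)
    target <- if (!is.null(truth$truth)) truth$truth$full_sequence
              else if (!is.null(consensi$flank5)) consensi$flank5$sequence
    if (!is.null(truth$probe) && !is.null(target) && nchar(target) > 0) {
      seg <- segment_units(target, truth$probe)
      write_bed(segmentation_to_bed(seg), file.path(out_dir, "units.bed"))
      out$copies <- count_copies(seg)
      iv <- seg$intervals
      full <- iv[!iv$partial, , drop = FALSE]
      if (nrow(full) >= 2L) {
        units <- setNames(
          substring(target, full$start + 1L, full$end),
          paste0("unit", seq_len(nrow(full))))
        pick <- unique(c(1L, nrow(full)))
        cmp <- compare_unit_set(units[pick])
        write_tsv_with_header(cmp, file.path(out_dir, "unit_comparisons.tsv"),
                              hdr)
        out$comparisons <- cmp
        if (!is.null(config$motifs)) {
          mo <- scan_motifs(units, config$motifs)
          write_tsv_with_header(mo$hits, file.path(out_dir, "motif_hits.tsv"),
                                hdr)
          out$motifs <- mo
        }
      }
    }
    out
  })

  qc <- stage("qc", {
    rs <- read_stats(truth$reads)
    write_tsv_with_header(
      data.frame(n_reads = rs$n_reads, n_bases = rs$n_bases,
                 mean_length = rs$mean_length, n50_length = rs$n50_length,
                 max_length = rs$max_length),
      file.path(out_dir, "read_stats.tsv"), hdr)
    rs
  })

  summary <- list(
    seed = seed, config_md5 = md5,
    read_stats = list(n_reads = qc$n_reads, n_bases = qc$n_bases,
                      mean_length = qc$mean_length,
                      n50_length = qc$n50_length,
                      max_length = qc$max_length),
    anchored = sel$report,
    copies = analysis$copies,
    consensus_lengths = lapply(consensi, `[[`, "called_length"))
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(summary)
}
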