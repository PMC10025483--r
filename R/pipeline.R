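# Orchestration of the analysis stages over files on disk, mirroring the
# subcommands of the thin command-line wrapper (inst/cli/mirpare.R):
# simulate -> identify -> diff -> degradome -> target -> qpcr -> report.
# Every threshold actually applied is recorded in the returned run log.

#' Default run configuration
#'
#' The pipeline thresholds: minimum count for conserved-miRNA analysis
#' (10 in at least one library), log2 fold-change threshold (0.6),
#' significance level (0.05), minimum degradome tag length (14 nt),
#' maximum duplex penalty (7.5), and maximum read/mature length
#' difference (4 nt).
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed RNG seed used by the simulate stage.
#' @return Named list of thresholds and paths.
#' @export
run_config <- function(out_dir = tempfile("mirpare_run"), seed = 1L) {
  list(out_dir = out_dir, seed = seed,
       min_count = 10L, fc_threshold = 0.6, alpha = 0.05,
       min_tag_len = 14L, penalty_max = 7.5, max_length_diff = 4L,
       target_delta = 1.0)
}

log_msg <- function(log, ...) c(log, paste0(...))

#' Run the full pipeline on synthetic data
#'
#' Generates all inputs with the synthetic-data module, then runs
#' identification, differential testing for both contrasts, degradome
#' mapping, target scoring against both degradome libraries, qPCR
#' integration, and the final report tables.
#'
#' @param config List from [run_config()].
#' @param sim_config A [simulation_config()]; defaults to the study-design
#'   defaults with `config$seed`.
#' @param n_score_mirnas Number of planted miRNAs to carry through target
#'   scoring (scoring is the most expensive stage; `Inf` scores all).
#' @return List with the per-stage results: `counts`, `assignments`,
#'   `diff_drought`, `diff_rehydration`, `summary`, `profiles_ak`,
#'   `profiles_as`, `target_hits`, `qpcr`, `report_paths`, `log`.
#' @export
run_pipeline <- function(config = run_config(),
                         sim_config = simulation_config(seed = config$seed),
                         n_score_mirnas = 20L) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)

  # simulate
  srna <- simulate_srna_libraries(sim_config,
                                  dir = file.path(config$out_dir, "srna"))
  degr <- simulate_degradome(sim_config, srna$truth,
                             dir = file.path(config$out_dir, "degradome"))
  log <- log_msg(log, "simulate: seed=", sim_config$seed,
                 " n_mirnas=", sim_config$n_mirnas)

  # identify: collapse, filter, match, collapse isomiRs
  reads <- lapply(srna$fastq, function(p) read_fastq(p)$sequence)
  mat <- collapse_reads(reads)
  mat <- filter_min_count(mat, config$min_count)
  log <- log_msg(log, "identify: min_count=", config$min_count,
                 " sequences_kept=", nrow(mat))
  reference <- stats::setNames(srna$truth$mature_set$sequence,
                               srna$truth$mature_set$mirna_name)
  asn <- assign_mirnas(mat, reference,
                       max_length_diff = config$max_length_diff)
  asn <- collapse_isomirs(asn, mat)
  counts <- canonical_counts(asn, mat)
  log <- log_msg(log, "identify: max_length_diff=", config$max_length_diff,
                 " mirnas=", nrow(counts))

  # differential, both contrasts
  diff_d <- nb_wald(counts, srna$sample_sheet, c("drought", "control_1"),
                    fc_threshold = config$fc_threshold, alpha = config$alpha)
  diff_r <- nb_wald(counts, srna$sample_sheet, c("rehydration", "control_2"),
                    fc_threshold = config$fc_threshold, alpha = config$alpha)
  log <- log_msg(log, "diff: fc_threshold=", config$fc_threshold,
                 " alpha=", config$alpha)
  summ <- restoration_summary(
    stats::setNames(diff_d$call, diff_d$mirna_name),
    stats::setNames(diff_r$call, diff_r$mirna_name))

  # degradome mapping, both libraries
  prof <- lapply(degr$tags, function(tg) {
    map_five_prime_ends(filter_tags(tg, config$min_tag_len),
                        degr$transcripts)
  })
  log <- log_msg(log, "degradome: min_tag_len=", config$min_tag_len,
                 " mapped_ak=", attr(prof$ak, "mapped_placements"),
                 " mapped_as=", attr(prof$as, "mapped_placements"))

  # target scoring against the control-library profiles
  score_set <- utils::head(srna$truth$mature_set,
                           min(n_score_mirnas, nrow(srna$truth$mature_set)))
  hits <- do.call(rbind, lapply(seq_len(nrow(score_set)), function(i) {
    score_targets(score_set$sequence[i], degr$transcripts, prof$ak,
                  penalty_max = config$penalty_max,
                  delta = config$target_delta,
                  mirna_name = score_set$mirna_name[i])
  }))
  log <- log_msg(log, "target: penalty_max=", config$penalty_max,
                 " delta=", config$target_delta,
                 " hits=", if (is.null(hits)) 0L else nrow(hits))

  # qPCR integration: targets anticorrelated with their planted miRNAs
  pc <- srna$truth$planted_calls
  fcs <- data.frame(gene = paste0("tgt_", pc$mirna_name),
                    fc_drought = 2^(-pc$log2fc_drought),
                    stringsAsFactors = FALSE)
  fcs <- utils::head(fcs, min(n_score_mirnas, nrow(fcs)))
  ct <- simulate_ct_tables(sim_config, fcs)
  qres <- do.call(rbind, lapply(seq_len(nrow(fcs)), function(k) {
    fc <- ddct_fold_change(ct, fcs$gene[k], c("drought", "control_1"),
                           srna$sample_sheet)
    mcall <- pc$call_drought[k]
    data.frame(gene = fc$gene, mirna_name = pc$mirna_name[k],
               mirna_call = mcall, fc_raw = fc$fc_raw,
               fc_signed = fc$fc_signed, p = fc$p,
               correlation = correlation_class(mcall, fc$fc_signed, fc$p,
                                               config$alpha),
               stringsAsFactors = FALSE)
  }))

  # report
  paths <- write_report(config$out_dir, summ, diff_d, diff_r, hits, qres)
  log <- log_msg(log, "report: ", length(paths), " tables written")

  list(counts = counts, assignments = asn,
       diff_drought = diff_d, diff_rehydration = diff_r,
       summary = summ, profiles_ak = prof$ak, profiles_as = prof$as,
       target_hits = hits, qpcr = qres, truth = srna$truth,
       targets = degr$targets, report_paths = paths, log = log)
}

#' Write the report tables of a run
#'
#' Emits the summary cross-tabulation (up/down/unchanged per contrast plus
#' the common row), the per-miRNA results of both contrasts, the target
#' hit table, and the miRNA/target anticorrelation table.
#'
#' @param out_dir Output directory.
#' @param summary [restoration_summary()] list.
#' @param diff_drought,diff_rehydration [nb_wald()] result tables.
#' @param hits Target hit table (may be `NULL`).
#' @param qpcr Anticorrelation table (may be `NULL`).
#' @return Named character vector of written paths.
#' @export
write_report <- function(out_dir, summary, diff_drought, diff_rehydration,
                         hits = NULL, qpcr = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(summary = file.path(out_dir, "summary_table.tsv"))
  st <- summary_table(summary)
  st <- cbind(contrast = rownames(st), st)
  write_tsv(st, paths[["summary"]])

  merged <- merge(diff_drought, diff_rehydration, by = "mirna_name",
                  suffixes = c("_drought", "_rehydration"))
  paths[["per_mirna"]] <- file.path(out_dir, "per_mirna_results.tsv")
  write_tsv(merged, paths[["per_mirna"]])

  if (!is.null(hits) && nrow(hits)) {
    paths[["targets"]] <- file.path(out_dir, "target_hits.tsv")
    write_tsv(hits, paths[["targets"]])
  }
  if (!is.null(qpcr) && nrow(qpcr)) {
    paths[["anticorrelation"]] <- file.path(out_dir, "anticorrelation.tsv")
    write_tsv(qpcr, paths[["anticorrelation"]])
  }
  paths
}
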