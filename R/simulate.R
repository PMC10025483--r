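# Synthetic-data generator reproducing the statistical structure the
# analysis assumes: 12 small-RNA libraries (3 replicates x 4 conditions)
# with NB-distributed counts and planted condition effects, planted isomiR
# variants, two degradome libraries with tag pile-ups at canonical cleavage
# positions, and Ct tables consistent with planted target fold changes.

BASES <- c("A", "C", "G", "T")

#' Mature products of the barley miR172b precursor
#'
#' The two strands of the miR172b duplex (5p targets trehalose-6-phosphate
#' synthase, 3p targets AP2-like transcription factors), shipped as named
#' sequence fixtures for simulations and worked examples.
#'
#' @export
MIR172B <- c(
  "hvu-miR172b-5p" = "GCAGCACCACCAAGATTCACA",
  "hvu-miR172b-3p" = "AGAATCTTGATGATGCTGCAT"
)

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len[min(i, length(len))], replace = TRUE),
          collapse = "")
  }, character(1))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

#' Default planted condition effects
#'
#' Plants the drought/rehydration response pattern of the assumed design:
#' 11 miRNAs up and 38 down in drought; 9 up and 16 down in rehydration,
#' of which 5 up and 11 down are shared with drought, so that 6 drought-up
#' and 27 drought-down miRNAs are restored by rewatering.
#'
#' @param n_mirnas Number of simulated miRNAs (at least 58 for the full
#'   pattern; fewer miRNAs truncate it).
#' @param magnitude Absolute planted log2 fold change, default 2.
#' @return data.frame with columns `mirna_index`, `contrast`, `log2fc`.
#' @export
default_planted_effects <- function(n_mirnas, magnitude = 2) {
  fx <- rbind(
    data.frame(mirna_index = 1:11, contrast = "drought", log2fc = magnitude),
    data.frame(mirna_index = 12:49, contrast = "drought", log2fc = -magnitude),
    data.frame(mirna_index = 1:5, contrast = "rehydration", log2fc = magnitude),
    data.frame(mirna_index = 12:22, contrast = "rehydration",
               log2fc = -magnitude),
    data.frame(mirna_index = 50:53, contrast = "rehydration",
               log2fc = magnitude),
    data.frame(mirna_index = 54:58, contrast = "rehydration",
               log2fc = -magnitude)
  )
  fx[fx$mirna_index <= n_mirnas, , drop = FALSE]
}

#' Simulation configuration
#'
#' Bundles all generator parameters with defaults matching the assumed
#' study conditions: 150 conserved miRNAs over 12 libraries (3 replicates
#' of each of the 4 watering conditions), NB counts with dispersion 0.1,
#' planted effects of |log2FC| = 2 in the pattern of
#' [default_planted_effects()], a 10% isomiR rate, degradome tag pile-ups
#' at planted cleavage sites, and Ct noise of 0.2 cycles.
#'
#' @param seed Integer RNG seed; every generator output is deterministic
#'   under it.
#' @param n_mirnas Number of simulated mature miRNAs.
#' @param n_background_seqs Number of low-abundance background sequences.
#' @param n_transcripts Number of simulated transcripts.
#' @param transcript_len_range Transcript length range in nt.
#' @param planted_effects data.frame (`mirna_index`, `contrast`, `log2fc`)
#'   of condition effects; `NULL` plants nothing.
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param mean_count_range Range of baseline miRNA mean counts.
#' @param isomir_rate Fraction of each miRNA's reads emitted as a 3'
#'   length variant.
#' @param degradome_peak_fraction Fraction of a planted target's tags
#'   starting exactly at the cleavage position.
#' @param degradome_background_tags Uniform background tags per transcript
#'   and library.
#' @param degradome_tags_per_target Tags attributed to each planted target
#'   per library before condition scaling.
#' @param ct_noise_sd Gaussian noise on simulated Ct values, in cycles.
#' @param include_mir172 Ship the two miR172b mature sequences as the
#'   first two simulated miRNAs.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_mirnas = 150L,
                              n_background_seqs = 300L, n_transcripts = 100L,
                              transcript_len_range = c(300L, 800L),
                              planted_effects = default_planted_effects(n_mirnas),
                              dispersion = 0.1,
                              mean_count_range = c(20, 500),
                              isomir_rate = 0.1,
                              degradome_peak_fraction = 0.5,
                              degradome_background_tags = 50L,
                              degradome_tags_per_target = 200L,
                              ct_noise_sd = 0.2,
                              include_mir172 = TRUE) {
  stopifnot(dispersion > 0, isomir_rate >= 0, isomir_rate <= 1,
            degradome_peak_fraction >= 0, degradome_peak_fraction <= 1,
            diff(transcript_len_range) >= 0, diff(mean_count_range) >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# 12-library sample sheet of the 3 x 4 design.
design_sample_sheet <- function() {
  data.frame(
    library_id = paste0(rep(c("C1", "D", "C2", "R"), each = 3), "_", 1:3),
    condition = rep(CONDITIONS, each = 3),
    replicate = rep(1:3, 4),
    stringsAsFactors = FALSE
  )
}

#' Simulate the miRNA count matrix of the 12-library design
#'
#' Draws per-sequence, per-library counts from NB(mean * 2^effect,
#' dispersion), where the planted effect applies in the libraries of the
#' affected treatment condition. Background sequences get low means drawn
#' below the conserved-miRNA detection floor.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (matrix, rows = sequences), `sample_sheet`,
#'   and `truth` (list with `mature_set`, `planted_calls`, `base_means`).
#' @export
simulate_count_matrix <- function(config) {
  set.seed(config$seed)
  ss <- design_sample_sheet()
  n <- config$n_mirnas
  mir_names <- sprintf("sim-miR%03d", seq_len(n))
  mir_seqs <- random_seq(n, rep(21L, n))
  if (config$include_mir172 && n >= 2L) {
    mir_names[1:2] <- names(MIR172B)
    mir_seqs[1:2] <- unname(MIR172B)
  }
  while (anyDuplicated(mir_seqs)) {
    dup <- which(duplicated(mir_seqs))
    mir_seqs[dup] <- random_seq(length(dup), rep(21L, length(dup)))
  }
  names(mir_seqs) <- mir_names

  base <- exp(stats::runif(n, log(config$mean_count_range[1L]),
                           log(config$mean_count_range[2L])))
  lfc <- matrix(0, nrow = n, ncol = 4L,
                dimnames = list(mir_names, CONDITIONS))
  fx <- config$planted_effects
  if (!is.null(fx) && nrow(fx)) {
    stopifnot(all(fx$contrast %in% c("drought", "rehydration")))
    for (k in seq_len(nrow(fx))) {
      lfc[fx$mirna_index[k], fx$contrast[k]] <- fx$log2fc[k]
    }
  }
  mu <- base * 2^lfc[, as.character(ss$condition), drop = FALSE]

  nb <- config$n_background_seqs
  bg_seqs <- unique(random_seq(nb, sample(20:24, nb, replace = TRUE)))
  bg_seqs <- setdiff(bg_seqs, mir_seqs)
  bg_mu <- matrix(stats::runif(length(bg_seqs), 1, 8),
                  nrow = length(bg_seqs), ncol = 12L)

  allmu <- rbind(mu, bg_mu)
  counts <- matrix(stats::rnbinom(length(allmu), mu = allmu,
                                  size = 1 / config$dispersion),
                   nrow = nrow(allmu),
                   dimnames = list(c(mir_seqs, bg_seqs), ss$library_id))
  call_of <- function(x) ifelse(x >= 0.6, "up",
                                ifelse(x <= -0.6, "down", "unchanged"))
  truth <- list(
    mature_set = data.frame(mirna_name = mir_names, sequence = mir_seqs,
                            stringsAsFactors = FALSE, row.names = NULL),
    planted_calls = data.frame(
      mirna_name = mir_names,
      call_drought = call_of(lfc[, "drought"]),
      call_rehydration = call_of(lfc[, "rehydration"]),
      log2fc_drought = lfc[, "drought"],
      log2fc_rehydration = lfc[, "rehydration"],
      stringsAsFactors = FALSE, row.names = NULL),
    base_means = stats::setNames(base, mir_names)
  )
  list(counts = counts, sample_sheet = ss, truth = truth)
}

# One fixed 3' isomiR variant per miRNA: extension by one templated-looking
# random nucleotide or a 1-2 nt trim, chosen deterministically per miRNA.
isomir_variant <- function(seq, which) {
  switch(which,
         paste0(seq, sample(BASES, 1L)),
         substr(seq, 1L, nchar(seq) - 1L),
         substr(seq, 1L, nchar(seq) - 2L))
}

#' Simulate the 12 small-RNA libraries as FASTQ files
#'
#' Expands a simulated count matrix into per-library FASTQ reads. At
#' `isomir_rate`, reads of each miRNA are emitted as a fixed 3' length
#' variant of the mature sequence instead of the mature sequence itself.
#' Byte-identical outputs are produced for identical configs.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return List with `fastq` (named paths), `sample_sheet_path`,
#'   `sample_sheet`, and `truth` (the [simulate_count_matrix()] truth plus
#'   `isomirs`, the planted variant per miRNA).
#' @export
simulate_srna_libraries <- function(config, dir = tempfile("srna")) {
  sim <- simulate_count_matrix(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- sim$sample_sheet
  mat <- sim$counts
  mir_seqs <- sim$truth$mature_set$sequence
  variant_kind <- sample(1:3, length(mir_seqs), replace = TRUE)
  variants <- vapply(seq_along(mir_seqs), function(i) {
    isomir_variant(mir_seqs[i], variant_kind[i])
  }, character(1))

  paths <- stats::setNames(file.path(dir, paste0(ss$library_id, ".fastq")),
                           ss$library_id)
  for (lib in ss$library_id) {
    cnt <- mat[, lib]
    reads <- character(0)
    for (i in seq_along(cnt)) {
      if (cnt[i] == 0L) next
      seqc <- rownames(mat)[i]
      n_iso <- 0L
      j <- match(seqc, mir_seqs)
      if (!is.na(j) && config$isomir_rate > 0) {
        n_iso <- round(config$isomir_rate * cnt[i])
      }
      reads <- c(reads, rep(seqc, cnt[i] - n_iso),
                 if (n_iso > 0L) rep(variants[j], n_iso))
    }
    recs <- data.frame(
      read_id = paste0(lib, "_", seq_along(reads)),
      sequence = reads,
      quality = strrep("I", nchar(reads)),
      stringsAsFactors = FALSE
    )
    write_fastq(recs, paths[[lib]])
  }
  ss_path <- file.path(dir, "sample_sheet.tsv")
  write_tsv(ss, ss_path)
  truth <- sim$truth
  truth$isomirs <- data.frame(mirna_name = sim$truth$mature_set$mirna_name,
                              variant = variants, stringsAsFactors = FALSE)
  list(fastq = paths, sample_sheet_path = ss_path, sample_sheet = ss,
       truth = truth)
}

#' Simulate degradome libraries and the transcript set
#'
#' Builds random transcripts, embeds for each planted target the reverse
#' complement of its miRNA (a perfect cleavable site), and emits two tag
#' libraries -- "ak" (control) and "as" (drought). Per planted target and
#' library, `degradome_peak_fraction` of its tags (binomially sampled)
#' start exactly at the canonical cleavage position (the nucleotide paired
#' to miRNA position 10), the rest start uniformly; each transcript also
#' receives uniform background tags. The drought library's target tag
#' counts are scaled by the miRNA's planted drought fold change, so
#' cleavage intensity follows miRNA abundance. All tags are 20 nt copies
#' of the transcript sense strand.
#'
#' @param config A [simulation_config()].
#' @param truth Truth list from [simulate_count_matrix()] (or
#'   [simulate_srna_libraries()]); planted targets are created for the
#'   first `min(n_mirnas, n_transcripts)` miRNAs.
#' @param dir Output directory; `NULL` skips file output.
#' @return List with `transcripts` (named vector), `tags` (list `ak`,
#'   `as`), `targets` (data.frame `mirna_name`, `transcript_id`,
#'   `site_start`, `cleavage_position`), and, when `dir` is given, the
#'   written `fasta` / `fastq` paths.
#' @export
simulate_degradome <- function(config, truth, dir = NULL) {
  set.seed(config$seed + 1000L)
  tag_len <- 20L
  ntx <- config$n_transcripts
  lens <- sample(config$transcript_len_range[1L]:config$transcript_len_range[2L],
                 ntx, replace = TRUE)
  tx_ids <- sprintf("TX%04d", seq_len(ntx))
  txs <- stats::setNames(random_seq(ntx, lens), tx_ids)

  mature <- truth$mature_set
  n_tgt <- min(nrow(mature), ntx)
  targets <- data.frame(mirna_name = character(), transcript_id = character(),
                        site_start = integer(), cleavage_position = integer(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_tgt)) {
    mir <- mature$sequence[i]
    L <- nchar(mir)
    site <- revcomp(mir)
    len <- nchar(txs[[i]])
    start <- sample(seq(tag_len + 1L, len - L - tag_len), 1L)
    substr(txs[[i]], start, start + L - 1L) <- site
    targets <- rbind(targets, data.frame(
      mirna_name = mature$mirna_name[i], transcript_id = tx_ids[i],
      site_start = start, cleavage_position = start + (L - 10L),
      stringsAsFactors = FALSE))
  }

  lfc_d <- stats::setNames(truth$planted_calls$log2fc_drought,
                           truth$planted_calls$mirna_name)
  tags <- list(ak = character(0), as = character(0))
  for (lib in names(tags)) {
    out <- character(0)
    for (k in seq_len(nrow(targets))) {
      tx <- txs[[targets$transcript_id[k]]]
      len <- nchar(tx)
      mult <- if (lib == "as") {
        2^max(min(lfc_d[[targets$mirna_name[k]]], 2), -2)
      } else 1
      n <- round(config$degradome_tags_per_target * mult)
      if (n < 1L) next
      n_peak <- stats::rbinom(1L, n, config$degradome_peak_fraction)
      cp <- targets$cleavage_position[k]
      starts <- c(rep(cp, n_peak),
                  sample(seq_len(len - tag_len + 1L), n - n_peak,
                         replace = TRUE))
      out <- c(out, substring(tx, starts, starts + tag_len - 1L))
    }
    for (id in tx_ids) {
      len <- nchar(txs[[id]])
      nbk <- config$degradome_background_tags
      if (nbk > 0L) {
        starts <- sample(seq_len(len - tag_len + 1L), nbk, replace = TRUE)
        out <- c(out, substring(txs[[id]], starts, starts + tag_len - 1L))
      }
    }
    tags[[lib]] <- out
  }

  res <- list(transcripts = txs, tags = tags, targets = targets)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    res$fasta <- file.path(dir, "transcripts.fasta")
    write_fasta(txs, res$fasta)
    res$fastq <- stats::setNames(file.path(dir, c("ak.fastq", "as.fastq")),
                                 c("ak", "as"))
    for (lib in c("ak", "as")) {
      recs <- data.frame(read_id = paste0(lib, "_", seq_along(tags[[lib]])),
                         sequence = tags[[lib]],
                         quality = strrep("I", nchar(tags[[lib]])),
                         stringsAsFactors = FALSE)
      write_fastq(recs, res$fastq[[lib]])
    }
    write_tsv(targets, file.path(dir, "planted_targets.tsv"))
  }
  res
}

#' Simulate qPCR Ct tables from planted fold changes
#'
#' The reference gene sits at a constant Ct; each target gene's Ct is
#' offset from the reference by a gene-specific baseline and shifted by
#' -log2(fold change) in the treated condition, with Gaussian noise of
#' `ct_noise_sd` cycles on every well. Three replicates per condition.
#'
#' @param config A [simulation_config()].
#' @param planted_fcs data.frame with columns `gene`, `fc_drought` and
#'   optionally `fc_rehydration` (raw fold changes vs the matched
#'   control).
#' @param path Optional TSV output path.
#' @return Ct table data.frame (`gene`, `library_id`, `ct`,
#'   `is_reference`).
#' @export
simulate_ct_tables <- function(config, planted_fcs, path = NULL) {
  set.seed(config$seed + 2000L)
  ss <- design_sample_sheet()
  ref_ct <- 20
  noise <- function(n) stats::rnorm(n, 0, config$ct_noise_sd)
  rows <- data.frame(gene = "ARF1-like", library_id = ss$library_id,
                     ct = ref_ct + noise(12L), is_reference = TRUE,
                     stringsAsFactors = FALSE)
  for (k in seq_len(nrow(planted_fcs))) {
    base_dct <- stats::runif(1, 2, 8)
    lfc <- stats::setNames(rep(0, 4L), CONDITIONS)
    lfc["drought"] <- log2(planted_fcs$fc_drought[k])
    if ("fc_rehydration" %in% names(planted_fcs)) {
      lfc["rehydration"] <- log2(planted_fcs$fc_rehydration[k])
    }
    ct <- ref_ct + base_dct - lfc[as.character(ss$condition)] + noise(12L)
    rows <- rbind(rows, data.frame(gene = planted_fcs$gene[k],
                                   library_id = ss$library_id, ct = ct,
                                   is_reference = FALSE,
                                   stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  if (!is.null(path)) write_tsv(rows, path)
  rows
}
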