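small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 81, n_mirnas = 12, n_background_seqs = 20,
         n_transcripts = 8, transcript_len_range = c(200, 400),
         mean_count_range = c(50, 200), degradome_tags_per_target = 100,
         degradome_background_tags = 10),
    list(...))
  do.call(simulation_config, args)
}

test_that("the generator is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_srna_libraries(small_cfg(), dir = d1)
  s2 <- simulate_srna_libraries(small_cfg(), dir = d2)
  for (lib in names(s1$fastq)) {
    expect_identical(readLines(s1$fastq[[lib]]), readLines(s2$fastq[[lib]]))
  }
  g1 <- simulate_degradome(small_cfg(), s1$truth)
  g2 <- simulate_degradome(small_cfg(), s2$truth)
  expect_identical(g1$tags, g2$tags)
  expect_identical(g1$transcripts, g2$transcripts)
})

test_that("planted effects drive downstream differential calls", {
  fx <- data.frame(mirna_index = 1, contrast = "drought", log2fc = 3)
  cfg <- simulation_config(seed = 82, n_mirnas = 10, n_background_seqs = 0,
                           planted_effects = fx, isomir_rate = 0,
                           mean_count_range = c(200, 200))
  sim <- simulate_count_matrix(cfg)
  ref <- setNames(sim$truth$mature_set$sequence,
                  sim$truth$mature_set$mirna_name)
  mat <- filter_min_count(sim$counts, 10)
  asn <- collapse_isomirs(assign_mirnas(mat, ref), mat)
  counts <- canonical_counts(asn, mat)
  res <- nb_wald(counts, sim$sample_sheet, c("drought", "control_1"))
  expect_equal(res$call[res$mirna_name == sim$truth$mature_set$mirna_name[1]],
               "up")
})

test_that("isomiR planting is recovered and absent at rate zero", {
  cfg0 <- small_cfg(isomir_rate = 0)
  s0 <- simulate_srna_libraries(cfg0, dir = withr::local_tempdir())
  reads <- unique(unlist(lapply(s0$fastq, function(p) read_fastq(p)$sequence)))
  mat <- collapse_reads(lapply(s0$fastq, function(p) read_fastq(p)$sequence))
  mat <- filter_min_count(mat, 10)
  # every abundant sequence is a planted mature or background sequence;
  # all matures are recovered
  expect_true(all(s0$truth$mature_set$sequence %in% rownames(mat)))
})

test_that("degradome pile-ups land at planted cleavage positions", {
  # peak fraction 1 and no background: a single spike
  cfg1 <- small_cfg(degradome_peak_fraction = 1,
                    degradome_background_tags = 0)
  sim <- simulate_count_matrix(cfg1)
  deg <- simulate_degradome(cfg1, sim$truth)
  prof <- map_five_prime_ends(deg$tags$ak, deg$transcripts)
  for (k in seq_len(nrow(deg$targets))) {
    tgt <- deg$targets[k, ]
    raw <- prof[[tgt$transcript_id]]$raw
    # tags are copied from the planted transcript, so the cleavage
    # position carries (at least) the full planted pile-up
    expect_gte(raw[tgt$cleavage_position], 100 * 0.9)
    aln <- list(site_start = tgt$site_start,
                site_end = tgt$site_start + 20,
                predicted_cleavage = tgt$cleavage_position)
    v <- validate_cleavage(aln, prof[[tgt$transcript_id]])
    expect_true(v$validated)
  }
})

test_that("the peak fraction behaves binomially", {
  cfg <- small_cfg(degradome_peak_fraction = 0.5, n_transcripts = 2,
                   n_mirnas = 2, degradome_tags_per_target = 1000,
                   degradome_background_tags = 0)
  sim <- simulate_count_matrix(cfg)
  deg <- simulate_degradome(cfg, sim$truth)
  tgt <- deg$targets[1, ]
  peak_tag <- substr(deg$transcripts[[tgt$transcript_id]],
                     tgt$cleavage_position, tgt$cleavage_position + 19)
  n_peak <- sum(deg$tags$ak == peak_tag)
  # within the 99% binomial interval around 500
  interval <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_peak, interval[1])
  expect_lte(n_peak, interval[2])
})

test_that("noise-free Ct tables reproduce planted fold changes exactly", {
  cfg <- small_cfg(ct_noise_sd = 0)
  fcs <- data.frame(gene = c("g2", "g025"), fc_drought = c(2, 0.25))
  ct <- simulate_ct_tables(cfg, fcs)
  ss <- data.frame(library_id = unique(ct$library_id),
                   condition = rep(CONDITIONS, each = 3),
                   replicate = rep(1:3, 4))
  f2 <- ddct_fold_change(ct, "g2", c("drought", "control_1"), ss)
  expect_equal(f2$fc_raw, 2)
  f025 <- ddct_fold_change(ct, "g025", c("drought", "control_1"), ss)
  expect_equal(f025$fc_raw, 0.25)
  expect_equal(f025$fc_signed, -4)
})

test_that("noisy Ct recovery is unbiased and consistent with propagation", {
  # per-well noise sd 0.2 over 3 replicates propagates to a ddCt error of
  # sd sqrt(4 * 0.2^2 / 3) ~= 0.23 cycles; recovery must be unbiased on
  # the log2 scale with nearly all genes inside 3 sd
  cfg <- small_cfg(ct_noise_sd = 0.2)
  set.seed(83)
  fcs <- data.frame(gene = paste0("g", 1:100),
                    fc_drought = exp(runif(100, log(0.2), log(5))))
  ct <- simulate_ct_tables(cfg, fcs)
  ss <- data.frame(library_id = unique(ct$library_id),
                   condition = rep(CONDITIONS, each = 3),
                   replicate = rep(1:3, 4))
  err <- vapply(seq_len(100), function(k) {
    fc <- ddct_fold_change(ct, fcs$gene[k], c("drought", "control_1"), ss)
    log2(fc$fc_raw) - log2(fcs$fc_drought[k])
  }, numeric(1))
  # the reference gene's noise is shared across genes, so the mean error
  # does not shrink with the number of genes: it inherits the reference
  # offset, sd sqrt(2 * 0.2^2 / 3) ~= 0.163 cycles
  sd_pred <- sqrt(4 * 0.2^2 / 3)
  sd_shared <- sqrt(2 * 0.2^2 / 3)
  expect_lt(abs(mean(err)), 3 * sd_shared)
  expect_gte(mean(abs(err) <= 3 * sd_pred), 0.95)
})
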