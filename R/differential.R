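# Negative-binomial Wald differential-accumulation testing with
# median-of-ratios normalization, the |log2FC| >= 0.6 & adjusted p <= 0.05
# classification, and the summary cross-tabulations (per-contrast calls,
# restoration after rewatering, pri-miRNA vs mature-miRNA relation).

#' Median-of-ratios library size factors
#'
#' The pseudo-reference for each sequence is its geometric mean across
#' libraries, computed over rows with all counts positive; the size factor
#' of a library is the median, over those rows, of count / reference.
#'
#' @param matrix Count matrix (sequences x libraries).
#' @return Named numeric vector of positive size factors, one per library.
#' @export
size_factors <- function(matrix) {
  pos <- matrix[apply(matrix, 1L, function(r) all(r > 0)), , drop = FALSE]
  if (nrow(pos) == 0L) {
    stop("no sequence has positive counts in every library; ",
         "a pseudo-reference fallback over nonzero rows would be required")
  }
  logref <- rowMeans(log(pos))
  apply(pos, 2L, function(col) exp(stats::median(log(col) - logref)))
}

# Per-row NB dispersion: method-of-moments on normalized counts with the
# shot-noise term removed, floored at the across-row central value and at
# `floor`. The central floor stabilizes the 4-df per-row estimate.
estimate_dispersion <- function(q, groups, sf, floor = 1e-8) {
  lev <- unique(groups)
  n1 <- sum(groups == lev[1L]); n2 <- sum(groups == lev[2L])
  v1 <- apply(q[, groups == lev[1L], drop = FALSE], 1L, stats::var)
  v2 <- apply(q[, groups == lev[2L], drop = FALSE], 1L, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- rowMeans(q)
  shot <- mu * mean(1 / sf)
  araw <- pmax((s2 - shot) / mu^2, floor)
  araw[!is.finite(araw)] <- floor
  central <- stats::median(araw[mu > 1])
  if (!is.finite(central)) central <- floor
  pmax(araw, central, floor)
}

#' Negative-binomial Wald test for one contrast
#'
#' For each sequence: counts are normalized by median-of-ratios size
#' factors; the per-row NB dispersion is estimated by method of moments
#' (floored at the across-row median and at 1e-8); the log2 fold change is
#' the ratio of mean normalized counts with a pseudo-count of 0.5; its
#' standard error comes from the NB delta method; the Wald statistic is
#' referred to the standard normal two-sidedly and p-values are
#' Benjamini-Hochberg adjusted over all tested rows.
#'
#' @param matrix Count matrix (sequences x libraries).
#' @param sample_sheet data.frame mapping `library_id` to `condition`
#'   (see [read_sample_sheet()]); must cover all matrix columns.
#' @param contrast Character vector `c(treatment, control)`; the reported
#'   log2 fold change is treatment over control.
#' @param fc_threshold,alpha Classification thresholds passed to
#'   [classify()].
#' @return data.frame with columns `mirna_name`, `base_mean`, `log2fc`,
#'   `se`, `p`, `padj`, `call`.
#' @export
nb_wald <- function(matrix, sample_sheet, contrast,
                    fc_threshold = 0.6, alpha = 0.05) {
  stopifnot(length(contrast) == 2L)
  ss <- validate_sample_sheet(sample_sheet)
  miss <- setdiff(contrast, as.character(ss$condition))
  if (length(miss)) stop("condition absent from sample sheet: ",
                         paste(miss, collapse = ", "))
  libs_t <- ss$library_id[ss$condition == contrast[1L]]
  libs_c <- ss$library_id[ss$condition == contrast[2L]]
  if (length(libs_t) < 2L || length(libs_c) < 2L) {
    stop("at least 2 replicates per condition are required")
  }
  sub <- matrix[, c(libs_c, libs_t), drop = FALSE]
  sf <- size_factors(sub)
  q <- sweep(sub, 2L, sf, "/")
  groups <- rep(c("control", "treatment"), c(length(libs_c), length(libs_t)))

  m_c <- rowMeans(q[, groups == "control", drop = FALSE])
  m_t <- rowMeans(q[, groups == "treatment", drop = FALSE])
  log2fc <- log2(m_t + 0.5) - log2(m_c + 0.5)

  alpha_d <- estimate_dispersion(q, groups, sf)
  # Var of a normalized-count mean: (mu/harmonic-ish size + alpha mu^2)/n,
  # propagated through log2(mean + 0.5) by the delta method.
  n_c <- length(libs_c); n_t <- length(libs_t)
  inv_sf_c <- mean(1 / sf[seq_len(n_c)])
  inv_sf_t <- mean(1 / sf[n_c + seq_len(n_t)])
  var_c <- (m_c * inv_sf_c + alpha_d * m_c^2) / n_c
  var_t <- (m_t * inv_sf_t + alpha_d * m_t^2) / n_t
  se <- sqrt(var_c / (m_c + 0.5)^2 + var_t / (m_t + 0.5)^2) / log(2)
  se[se == 0 | !is.finite(se)] <- NA_real_

  z <- log2fc / se
  p <- ifelse(is.na(z), 1, 2 * stats::pnorm(-abs(z)))
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(mirna_name = rownames(matrix),
                    base_mean = rowMeans(q),
                    log2fc = log2fc, se = se, p = p, padj = padj,
                    stringsAsFactors = FALSE)
  out$call <- classify(out$log2fc, out$padj,
                       fc_threshold = fc_threshold, alpha = alpha)
  rownames(out) <- NULL
  out
}

#' Classify log2 fold changes into up / down / unchanged
#'
#' A sequence is called `up` when log2FC >= `fc_threshold` and the
#' significance value is <= `alpha`, `down` when log2FC <= -`fc_threshold`
#' under the same significance condition, `unchanged` otherwise. Both
#' boundaries are inclusive.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param padj Numeric vector of (adjusted) p-values, or a logical vector
#'   of per-element significance flags.
#' @param fc_threshold Fold-change threshold on the log2 scale, default 0.6.
#' @param alpha Significance level, default 0.05 (ignored when `padj` is
#'   logical).
#' @return Character vector over `{"up", "down", "unchanged"}`.
#' @export
classify <- function(log2fc, padj, fc_threshold = 0.6, alpha = 0.05) {
  stopifnot(fc_threshold > 0, alpha > 0)
  sig <- if (is.logical(padj)) padj else padj <= alpha
  sig[is.na(sig)] <- FALSE
  ifelse(sig & log2fc >= fc_threshold, "up",
         ifelse(sig & log2fc <= -fc_threshold, "down", "unchanged"))
}

#' Classify the packaged printed fold-change table
#'
#' Applies the classification rule to the packaged 58-row fixture, in which
#' significance is carried as star classes rather than p-values: any star
#' class (`p05`, `p01`, `p001`) counts as significant, `ns` does not.
#'
#' @param fixture data.frame from [load_table2_fixture()].
#' @param fc_threshold Log2 fold-change threshold, default 0.6.
#' @return data.frame with columns `mirna_name`, `call_drought`,
#'   `call_rehydration`.
#' @export
classify_table2 <- function(fixture, fc_threshold = 0.6) {
  data.frame(
    mirna_name = fixture$mirna_name,
    call_drought = classify(fixture$log2fc_drought,
                            fixture$p_class_drought != "ns", fc_threshold),
    call_rehydration = classify(fixture$log2fc_rehydration,
                                fixture$p_class_rehydration != "ns",
                                fc_threshold),
    stringsAsFactors = FALSE
  )
}

#' Restoration and common-call summary across the two contrasts
#'
#' A miRNA changed by drought is "restored" when rewatering returns it to
#' unchanged; a call is "common" when identical and non-unchanged in both
#' contrasts.
#'
#' @param drought_calls,rehydration_calls Named character vectors of calls
#'   over the same miRNA name universe.
#' @return List with counts `n_up_drought`, `n_down_drought`,
#'   `n_unchanged_drought`, `n_up_rehyd`, `n_down_rehyd`,
#'   `n_unchanged_rehyd`, `n_common_up`, `n_common_down`,
#'   `n_common_unchanged`, `n_restored_up`, `n_restored_down`.
#' @export
restoration_summary <- function(drought_calls, rehydration_calls) {
  if (is.null(names(drought_calls)) || is.null(names(rehydration_calls)) ||
      !setequal(names(drought_calls), names(rehydration_calls))) {
    stop("call sets must be named over the same miRNA universe")
  }
  r <- rehydration_calls[names(drought_calls)]
  d <- drought_calls
  list(
    n_up_drought = sum(d == "up"),
    n_down_drought = sum(d == "down"),
    n_unchanged_drought = sum(d == "unchanged"),
    n_up_rehyd = sum(r == "up"),
    n_down_rehyd = sum(r == "down"),
    n_unchanged_rehyd = sum(r == "unchanged"),
    n_common_up = sum(d == "up" & r == "up"),
    n_common_down = sum(d == "down" & r == "down"),
    n_common_unchanged = sum(d == "unchanged" & r == "unchanged"),
    n_restored_up = sum(d == "up" & r == "unchanged"),
    n_restored_down = sum(d == "down" & r == "unchanged")
  )
}

#' Summary table of per-contrast and common calls
#'
#' Lays out a [restoration_summary()] as a 3-row table (drought,
#' rehydration, common) by 3 columns (up, down, unchanged).
#'
#' @param summary List from [restoration_summary()].
#' @return data.frame with rownames drought / rehydration / common.
#' @export
summary_table <- function(summary) {
  data.frame(
    up = c(summary$n_up_drought, summary$n_up_rehyd, summary$n_common_up),
    down = c(summary$n_down_drought, summary$n_down_rehyd,
             summary$n_common_down),
    unchanged = c(summary$n_unchanged_drought, summary$n_unchanged_rehyd,
                  summary$n_common_unchanged),
    row.names = c("drought", "rehydration", "common")
  )
}

#' Cross-tabulate pri-miRNA against mature-miRNA accumulation calls
#'
#' Counts, over the names common to both call sets, how pri-miRNA
#' accumulation changes relate to the cognate mature miRNA changes. The
#' `unchanged` label is accepted as a synonym of `const`. Names outside the
#' intersection are dropped; their number is attached as attribute
#' `n_dropped`.
#'
#' @param pri_calls,mirna_calls Named character vectors over
#'   `{"up", "down", "const"}` (or `"unchanged"`).
#' @return 3x3 integer matrix, rows = pri-miRNA call, columns = miRNA call.
#' @export
primirna_crosstab <- function(pri_calls, mirna_calls) {
  lev <- c("up", "down", "const")
  norm <- function(x) {
    x[x == "unchanged"] <- "const"
    stopifnot(all(x %in% lev))
    x
  }
  common <- intersect(names(pri_calls), names(mirna_calls))
  n_drop <- length(pri_calls) + length(mirna_calls) - 2L * length(common)
  tab <- table(factor(norm(pri_calls[common]), levels = lev),
               factor(norm(mirna_calls[common]), levels = lev))
  out <- matrix(as.integer(tab), 3L, 3L, dimnames = list(pri = lev, mirna = lev))
  attr(out, "n_dropped") <- n_drop
  out
}
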