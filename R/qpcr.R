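# qPCR relative quantification (2^-ddCt), the signed fold-change
# convention, printed fold-increase worked examples, and miRNA/target
# anticorrelation classification.

#' Read a Ct table
#'
#' @param path TSV with columns `gene`, `library_id`, `ct`, `is_reference`.
#' @return Validated data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(ct)
}

#' Validate a Ct table
#'
#' @param ct data.frame with columns `gene`, `library_id`, `ct`,
#'   `is_reference`.
#' @return The validated data.frame, `is_reference` coerced to logical.
#' @export
validate_ct_table <- function(ct) {
  need <- c("gene", "library_id", "ct", "is_reference")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  ct$is_reference <- as.logical(ct$is_reference)
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  refs <- unique(ct$gene[ct$is_reference])
  if (length(refs) != 1L) {
    stop("exactly one reference gene is required, found ", length(refs))
  }
  ct
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per condition, the gene's mean Ct is normalized to the reference gene's
#' mean Ct (dCt); the treated-minus-control difference of these (ddCt)
#' gives the raw fold change 2^-ddCt. Significance is a two-tailed
#' two-sample t-test on the per-replicate dCt values, with replicates
#' paired to the reference through the shared library.
#'
#' @param ct_records Ct table (see [validate_ct_table()]).
#' @param gene Target gene name.
#' @param contrast Character vector `c(treated, control)` of conditions.
#' @param sample_sheet data.frame mapping `library_id` to `condition`.
#' @return List with `gene`, `contrast`, `fc_raw`, `fc_signed`, `p`.
#' @export
ddct_fold_change <- function(ct_records, gene, contrast, sample_sheet) {
  ct <- validate_ct_table(ct_records)
  ss <- validate_sample_sheet(sample_sheet)
  ref_gene <- unique(ct$gene[ct$is_reference])
  if (!gene %in% ct$gene) stop("gene not in Ct table: ", gene)
  cond_of <- stats::setNames(as.character(ss$condition), ss$library_id)

  dct_for <- function(cond) {
    libs <- ss$library_id[ss$condition == cond]
    g <- ct[ct$gene == gene & ct$library_id %in% libs, ]
    r <- ct[ct$gene == ref_gene & ct$library_id %in% libs, ]
    if (nrow(g) < 2L || nrow(r) < 2L) {
      stop("at least 2 replicates per condition are required for ", cond)
    }
    common <- intersect(g$library_id, r$library_id)
    if (length(common) < 2L) stop("missing reference gene measurements")
    stats::setNames(g$ct[match(common, g$library_id)] -
                      r$ct[match(common, r$library_id)], common)
  }
  dct_t <- dct_for(contrast[1L])
  dct_c <- dct_for(contrast[2L])
  ddct <- mean(dct_t) - mean(dct_c)
  fc_raw <- 2^(-ddct)
  # zero-variance replicates (noise-free synthetic data) degenerate the
  # t statistic; equal means then give p = 1, unequal means p = 0
  p <- if (stats::sd(dct_t) == 0 && stats::sd(dct_c) == 0) {
    as.numeric(!isTRUE(all.equal(mean(dct_t), mean(dct_c))))
  } else {
    stats::t.test(dct_t, dct_c, var.equal = TRUE)$p.value
  }
  list(gene = gene, contrast = contrast, fc_raw = fc_raw,
       fc_signed = signed_fc(fc_raw), p = p)
}

#' Signed fold-change convention
#'
#' Raw fold changes below 1 are recalculated as -1/FC so that up- and
#' downregulation have symmetric magnitudes around +/-1; values of at
#' least 1 pass through unchanged.
#'
#' @param fc_raw Positive raw fold change (vectorized).
#' @return Signed fold change with |value| >= 1.
#' @export
signed_fc <- function(fc_raw) {
  if (any(fc_raw <= 0)) stop("fc_raw must be positive")
  ifelse(fc_raw >= 1, fc_raw, -1 / fc_raw)
}

#' Integer fold increase of a measurement over its control
#'
#' Ratio of treated over control, rounded to the nearest integer (half
#' away from zero), as printed for hormone-content comparisons.
#'
#' @param treated,control Positive measurements (vectorized).
#' @return Integer fold increase.
#' @export
fold_increase <- function(treated, control) {
  if (any(control <= 0)) stop("control must be positive")
  r <- treated / control
  as.integer(sign(r) * floor(abs(r) + 0.5))
}

#' Classify a miRNA/target pair as negatively correlated or not
#'
#' A target is negatively correlated with its cognate miRNA in a contrast
#' when the miRNA is up and the target's signed fold change is negative,
#' or the miRNA is down and the target's signed fold change exceeds 1 --
#' in either case with target significance at most `alpha`.
#'
#' @param mirna_call miRNA call: `"up"`, `"down"` or `"unchanged"`.
#' @param fc_signed Target signed fold change in the same contrast.
#' @param p Target significance.
#' @param alpha Significance level, default 0.05.
#' @return `"negatively_correlated"` or `"not_correlated"` (vectorized).
#' @export
correlation_class <- function(mirna_call, fc_signed, p, alpha = 0.05) {
  neg <- (mirna_call == "up" & fc_signed < 0 & p <= alpha) |
         (mirna_call == "down" & fc_signed > 1 & p <= alpha)
  ifelse(neg, "negatively_correlated", "not_correlated")
}
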