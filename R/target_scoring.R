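# miRNA:mRNA duplex alignment with position-weighted penalties, the 0-18
# compliance score combining alignment quality with degradome cleavage-site
# rank, best-target selection and canonical cleavage-position validation.

# Pairing state of miRNA base m against target (mRNA sense) base t:
# Watson-Crick match, G:U wobble (either orientation, U == T), or mismatch.
pair_state <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
        (m == "C" & t == "G") | (m == "G" & t == "C")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "match", ifelse(gu, "gu_wobble", "mismatch"))
}

# Position weights over miRNA positions 1..L: mismatch 1, wobble 0.5,
# match 0, doubled in the core region (positions 2-13).
position_weight <- function(state, pos, core = 2:13,
                            mismatch = 1, wobble = 0.5) {
  w <- ifelse(state == "mismatch", mismatch,
              ifelse(state == "gu_wobble", wobble, 0))
  w * ifelse(pos %in% core, 2, 1)
}

#' Align a miRNA against every ungapped window of a transcript
#'
#' Scans each window of the transcript of the miRNA's length against the
#' miRNA (antiparallel, so miRNA position 1 pairs with the 3'-most window
#' position). Per-position penalties are: Watson-Crick match 0, G:U wobble
#' 0.5, mismatch 1, doubled for miRNA positions 2-13 (the 5' core region,
#' which includes the seed and the cleavage-determining center). Windows
#' with total penalty at most `penalty_max` are reported. The predicted
#' cleavage coordinate is the transcript nucleotide paired to miRNA
#' position 10 (AGO slices the target 5' of it, between the nucleotides
#' opposite miRNA positions 10 and 11).
#'
#' @param mirna miRNA sequence, 18-26 nt (RNA or DNA alphabet).
#' @param transcript Transcript sequence (DNA alphabet, sense strand).
#' @param penalty_max Maximum reported penalty, default 7.5.
#' @param mirna_name,transcript_id Optional labels carried into the output.
#' @return data.frame with columns `mirna_name`, `transcript_id`,
#'   `site_start`, `site_end` (1-based inclusive), `penalty`,
#'   `predicted_cleavage`, and `states` (per-miRNA-position pairing states
#'   1..L encoded as a string of `M` match, `W` wobble, `X` mismatch);
#'   zero rows when the transcript is shorter than the miRNA or no window
#'   passes.
#' @export
align_duplex <- function(mirna, transcript, penalty_max = 7.5,
                         mirna_name = "mirna", transcript_id = "tx") {
  mirna <- gsub("U", "T", toupper(mirna), fixed = TRUE)
  transcript <- gsub("U", "T", toupper(transcript), fixed = TRUE)
  L <- nchar(mirna)
  stopifnot(L >= 18L, L <= 26L)
  tlen <- nchar(transcript)
  empty <- data.frame(mirna_name = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      penalty = numeric(), predicted_cleavage = integer(),
                      states = character(), stringsAsFactors = FALSE)
  if (tlen < L) return(empty)
  nw <- tlen - L + 1L
  mchars <- strsplit(mirna, "")[[1L]]
  tchars <- strsplit(transcript, "")[[1L]]
  penalty <- numeric(nw)
  states <- matrix("", nrow = nw, ncol = L)
  for (i in seq_len(L)) {
    tb <- tchars[(L - i) + seq_len(nw)]   # target base opposite miRNA pos i
    st <- pair_state(mchars[i], tb)
    states[, i] <- st
    penalty <- penalty + position_weight(st, i)
  }
  keep <- which(penalty <= penalty_max)
  if (!length(keep)) return(empty)
  code <- c(match = "M", gu_wobble = "W", mismatch = "X")
  data.frame(
    mirna_name = mirna_name, transcript_id = transcript_id,
    site_start = keep, site_end = keep + L - 1L,
    penalty = penalty[keep],
    predicted_cleavage = keep + (L - 10L),
    states = apply(states[keep, , drop = FALSE], 1L,
                   function(s) paste(code[s], collapse = "")),
    stringsAsFactors = FALSE
  )
}

#' Render a duplex alignment as a 3-line text block
#'
#' Target site 5'->3' on top, pairing line (`|` match, `o` wobble, space
#' mismatch) in the middle, miRNA written 3'->5' below.
#'
#' @param alignment One row of [align_duplex()] output.
#' @param mirna The miRNA sequence used in the alignment.
#' @param transcript The transcript sequence.
#' @return Character vector of three lines.
#' @export
render_duplex <- function(alignment, mirna, transcript) {
  mirna <- gsub("U", "T", toupper(mirna), fixed = TRUE)
  L <- nchar(mirna)
  site <- substr(toupper(transcript), alignment$site_start, alignment$site_end)
  st <- strsplit(alignment$states, "")[[1L]]
  # transcript position j within the site pairs miRNA position L - j + 1
  bars <- vapply(seq_len(L), function(j) {
    switch(st[L - j + 1L], M = "|", W = "o", X = " ")
  }, character(1))
  c(paste0("5' ", site, " 3'  (", alignment$transcript_id, ")"),
    paste0("   ", paste(bars, collapse = "")),
    paste0("3' ", paste(rev(strsplit(mirna, "")[[1L]]), collapse = ""),
           " 5'  (", alignment$mirna_name, ")"))
}

# Rank-category penalty: best cleavage site of the transcript contributes
# nothing, lower-ranked sites progressively more, absent degradome support
# the maximum of 3.
rank_penalty <- function(site_rank, has_support) {
  ifelse(!has_support | is.na(site_rank), 3,
         ifelse(site_rank == 1, 0,
                ifelse(site_rank <= 3, 1,
                       ifelse(site_rank <= 10, 2, 3))))
}

#' Compliance score of a candidate target site
#'
#' Combines the duplex alignment penalty with the degradome rank of the
#' predicted cleavage site: `2 * min(penalty, 7.5)` plus a rank-category
#' penalty (rank 1: 0; ranks 2-3: 1; ranks 4-10: 2; rank above 10 or no
#' degradome support: 3). The score therefore spans 0 (perfect duplex,
#' top-ranked cleavage site) to 18 (worst admissible duplex, no support);
#' lower is better.
#'
#' @param penalty Nonnegative duplex alignment penalty.
#' @param site_rank Competition rank of the predicted cleavage position in
#'   the transcript's profile (`NA` when unsupported).
#' @param has_support Whether the cleavage position has degradome signal.
#' @param penalty_cap Cap on the alignment penalty contribution, default
#'   7.5.
#' @return Numeric score in `[0, 18]`, vectorized over the inputs.
#' @export
compliance_score <- function(penalty, site_rank = NA_integer_,
                             has_support = !is.na(site_rank),
                             penalty_cap = 7.5) {
  if (any(penalty < 0)) stop("penalty must be nonnegative")
  if (any(!is.na(site_rank) & site_rank < 1)) stop("site_rank must be >= 1")
  2 * pmin(penalty, penalty_cap) + rank_penalty(site_rank, has_support)
}

#' Select the best-scoring targets per miRNA
#'
#' Sorts candidate hits by compliance score, ascending, and reports for
#' every miRNA all hits within `delta` of its best score (ties are
#' co-best by construction).
#'
#' @param hits data.frame with at least `mirna_name` and `compliance`.
#' @param delta Score window above the per-miRNA minimum, default 1.0.
#' @return data.frame of selected hits, sorted by miRNA then score.
#' @export
select_best_targets <- function(hits, delta = 1.0) {
  if (!nrow(hits)) return(hits)
  parts <- lapply(split(hits, hits$mirna_name), function(h) {
    h <- h[order(h$compliance), , drop = FALSE]
    h[h$compliance <= h$compliance[1L] + delta, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Validate a predicted cleavage site against a degradome profile
#'
#' Checks whether a local maximum of the raw profile inside the target
#' site lies within `window` nucleotides of the predicted cleavage
#' position. The reported offset is the signed distance from the predicted
#' position to the highest peak within the site.
#'
#' @param alignment One row of [align_duplex()] output (or any list with
#'   `site_start`, `site_end`, `predicted_cleavage`).
#' @param profile A [transcript_profile()] covering the site.
#' @param window Tolerated distance in nucleotides, default 1.
#' @return List with `validated` (logical) and `offset` (signed integer,
#'   `NA` when the site has no signal).
#' @export
validate_cleavage <- function(alignment, profile, window = 1L) {
  lo <- alignment$site_start
  hi <- alignment$site_end
  stopifnot(lo >= 1L, hi <= profile$length)
  raw <- profile$raw
  pos <- lo:hi
  is_peak <- vapply(pos, function(p) {
    if (raw[p] == 0L) return(FALSE)
    left <- if (p > 1L) raw[p - 1L] else -1L
    right <- if (p < profile$length) raw[p + 1L] else -1L
    raw[p] >= left && raw[p] >= right
  }, logical(1))
  peaks <- pos[is_peak]
  if (!length(peaks)) return(list(validated = FALSE, offset = NA_integer_))
  top <- peaks[which.max(raw[peaks])]
  list(validated = any(abs(peaks - alignment$predicted_cleavage) <= window),
       offset = as.integer(top - alignment$predicted_cleavage))
}

#' Score candidate targets of a miRNA against transcripts and degradome
#'
#' End-to-end helper for one miRNA: aligns against every transcript,
#' looks up the degradome support and competition rank of each predicted
#' cleavage position in the per-transcript profiles, and attaches the
#' compliance score.
#'
#' @param mirna miRNA sequence.
#' @param transcripts Named character vector of transcript sequences.
#' @param profiles Named list of [transcript_profile()] objects (one per
#'   transcript), e.g. from [map_five_prime_ends()]; may be `NULL` for a
#'   support-free scan.
#' @param penalty_max,delta Passed to [align_duplex()] /
#'   [select_best_targets()]; `delta = Inf` reports all hits.
#' @param mirna_name Label for the output.
#' @return data.frame of hits with `site_rank`, `raw_support` and
#'   `compliance` columns, sorted by score.
#' @export
score_targets <- function(mirna, transcripts, profiles = NULL,
                          penalty_max = 7.5, delta = Inf,
                          mirna_name = "mirna") {
  hits <- do.call(rbind, lapply(names(transcripts), function(id) {
    align_duplex(mirna, transcripts[[id]], penalty_max = penalty_max,
                 mirna_name = mirna_name, transcript_id = id)
  }))
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      penalty = numeric(), predicted_cleavage = integer(),
                      states = character(), site_rank = integer(),
                      raw_support = integer(), compliance = numeric(),
                      stringsAsFactors = FALSE))
  }
  hits$site_rank <- NA_integer_
  hits$raw_support <- 0L
  for (j in seq_len(nrow(hits))) {
    prof <- profiles[[hits$transcript_id[j]]]
    if (is.null(prof)) next
    cp <- hits$predicted_cleavage[j]
    hits$raw_support[j] <- prof$raw[cp]
    if (prof$raw[cp] > 0L) {
      rs <- rank_sites(prof)
      hits$site_rank[j] <- rs$rank[rs$position == cp]
    }
  }
  hits$compliance <- compliance_score(hits$penalty, hits$site_rank)
  select_best_targets(hits, delta = delta)
}
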