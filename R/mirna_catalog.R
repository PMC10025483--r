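# Building the sequence x library count matrix and assigning conserved
# miRNA identities by exact containment matching against a mature reference.

#' Collapse per-library reads into a count matrix
#'
#' Tallies each distinct read sequence per library. Total counts are
#' conserved: every column sum equals the number of input reads of that
#' library.
#'
#' @param reads Named list, one character vector of (adapter-trimmed) read
#'   sequences per library; names are library IDs.
#' @return Integer matrix, rows = distinct sequences (rownames), columns =
#'   library IDs.
#' @export
collapse_reads <- function(reads) {
  stopifnot(is.list(reads), !is.null(names(reads)))
  empty <- vapply(reads, length, integer(1)) == 0L
  if (any(empty)) {
    warning("empty librar", if (sum(empty) > 1) "ies: " else "y: ",
            paste(names(reads)[empty], collapse = ", "))
  }
  seqs <- sort(unique(unlist(reads, use.names = FALSE)))
  mat <- matrix(0L, nrow = length(seqs), ncol = length(reads),
                dimnames = list(seqs, names(reads)))
  for (lib in names(reads)) {
    if (!length(reads[[lib]])) next
    tab <- table(reads[[lib]])
    mat[names(tab), lib] <- as.integer(tab)
  }
  mat
}

#' Keep sequences reaching a minimum count in at least one library
#'
#' Retains exactly the rows whose maximum count across libraries is at
#' least `threshold` (inclusive boundary); the default of 10 is the usual
#' noise floor for conserved-miRNA identification from replicated
#' small-RNA libraries.
#'
#' @param matrix Integer count matrix (sequences x libraries).
#' @param threshold Minimum count, default 10.
#' @return The filtered matrix.
#' @export
filter_min_count <- function(matrix, threshold = 10L) {
  stopifnot(threshold >= 1L)
  matrix[apply(matrix, 1L, max) >= threshold, , drop = FALSE]
}

#' Match a read against a mature miRNA reference
#'
#' A read matches a mature reference sequence when the shorter of the two
#' is an exact substring of the longer (zero substitutions anywhere) and
#' the length difference is at most `max_length_diff`. Longer and shorter
#' reads are both accepted; internal mismatches never are.
#'
#' @param sequence A single DNA read sequence.
#' @param reference Named character vector of mature miRNA sequences
#'   (DNA alphabet; use [read_fasta()] for miRBase-style files).
#' @param max_length_diff Maximum |read length - mature length|, default 4.
#' @return data.frame with columns `sequence`, `mirna_name`, `length_diff`
#'   (= |read| - |mature|, may be negative), sorted by |length_diff| then
#'   reference ID; zero rows when nothing matches.
#' @export
match_reference <- function(sequence, reference, max_length_diff = 4L) {
  if (!length(reference)) stop("empty mature reference")
  if (anyDuplicated(names(reference))) stop("duplicate reference IDs")
  stopifnot(length(sequence) == 1L)
  ld <- nchar(sequence) - nchar(reference)
  cand <- which(abs(ld) <= max_length_diff)
  hit <- vapply(cand, function(i) {
    if (ld[i] >= 0L) grepl(reference[i], sequence, fixed = TRUE)
    else grepl(sequence, reference[i], fixed = TRUE)
  }, logical(1))
  cand <- cand[hit]
  out <- data.frame(sequence = rep(sequence, length(cand)),
                    mirna_name = names(reference)[cand],
                    length_diff = ld[cand],
                    stringsAsFactors = FALSE)
  out[order(abs(out$length_diff), out$mirna_name), , drop = FALSE]
}

#' Assign every matrix sequence to its best-matching miRNA
#'
#' Runs [match_reference()] for each row of a count matrix and keeps, per
#' read, only the best-ranked match (smallest |length_diff|, ties broken by
#' reference ID). Reads matching several distinct miRNA names are therefore
#' assigned once; the number of such ambiguous reads is reported as an
#' attribute.
#'
#' @param matrix Count matrix from [collapse_reads()].
#' @param reference Named character vector of mature sequences.
#' @param max_length_diff Passed to [match_reference()].
#' @return data.frame of assignments (`sequence`, `mirna_name`,
#'   `length_diff`) with attribute `n_ambiguous`.
#' @export
assign_mirnas <- function(matrix, reference, max_length_diff = 4L) {
  hits <- lapply(rownames(matrix), match_reference, reference = reference,
                 max_length_diff = max_length_diff)
  n_amb <- sum(vapply(hits, function(h) length(unique(h$mirna_name)) > 1L,
                      logical(1)))
  best <- do.call(rbind, lapply(hits, function(h) h[seq_len(min(1L, nrow(h))), ]))
  if (is.null(best)) {
    best <- data.frame(sequence = character(), mirna_name = character(),
                       length_diff = integer(), stringsAsFactors = FALSE)
  }
  attr(best, "n_ambiguous") <- n_amb
  rownames(best) <- NULL
  best
}

#' Collapse isomiRs to one canonical sequence per miRNA
#'
#' Among all read sequences assigned to the same miRNA name (the mature
#' form plus its length variants), flags as canonical the sequence with the
#' highest total count across libraries; ties are broken by smaller
#' |length_diff|, then by lexicographically smallest sequence. Non-canonical
#' rows are excluded from downstream per-miRNA counts.
#'
#' @param assignments data.frame from [assign_mirnas()].
#' @param matrix Count matrix containing all assigned sequences as rows.
#' @return The assignments data.frame with added logical column
#'   `is_canonical`.
#' @export
collapse_isomirs <- function(assignments, matrix) {
  stopifnot(all(assignments$sequence %in% rownames(matrix)))
  totals <- rowSums(matrix)[assignments$sequence]
  assignments$is_canonical <- FALSE
  for (nm in unique(assignments$mirna_name)) {
    i <- which(assignments$mirna_name == nm)
    ord <- order(-totals[i], abs(assignments$length_diff[i]),
                 assignments$sequence[i])
    assignments$is_canonical[i[ord[1L]]] <- TRUE
  }
  assignments
}

#' Per-miRNA count matrix of canonical sequences
#'
#' Convenience: subset a count matrix to canonical assignments and relabel
#' rows by miRNA name.
#'
#' @param assignments Output of [collapse_isomirs()].
#' @param matrix Count matrix.
#' @return Integer matrix, rows = miRNA names.
#' @export
canonical_counts <- function(assignments, matrix) {
  can <- assignments[assignments$is_canonical, , drop = FALSE]
  out <- matrix[can$sequence, , drop = FALSE]
  rownames(out) <- can$mirna_name
  out
}

#' Mean expression over the six libraries of one contrast
#'
#' The mean accumulation of a miRNA is computed over the six libraries of a
#' contrast pair: the three control replicates plus the three treatment
#' replicates (control_1 + drought, or control_2 + rehydration).
#'
#' @param counts Numeric count vector for one sequence, named by library.
#' @param libraries Exactly six library IDs.
#' @return Arithmetic mean of the six counts.
#' @export
mean_expression <- function(counts, libraries) {
  if (length(libraries) != 6L) {
    stop("mean expression is defined over exactly 6 libraries")
  }
  if (!all(libraries %in% names(counts))) stop("unknown library ID")
  mean(counts[libraries])
}
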