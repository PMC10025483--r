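# Readers and writers for the plain-text formats used throughout the
# pipeline: 4-line FASTQ, FASTA, tab-separated tables, the sample sheet of
# the 3 replicates x 4 conditions design, and the packaged printed-table
# fixtures.

#' Experimental conditions of the drought/rehydration design
#'
#' The four conditions of the watering regime: a control sampled alongside
#' the drought-stressed plants (`control_1`), the drought sample itself,
#' a second control sampled alongside the rewatered plants (`control_2`),
#' and the rehydration sample taken 6 h after rewatering.
#'
#' @export
CONDITIONS <- c("control_1", "drought", "control_2", "rehydration")

#' Read a 4-line-record FASTQ file
#'
#' Parses an uncompressed FASTQ file and returns its records in file order.
#' RNA input is tolerated: `U` bases are normalized to `T` on load, so all
#' sequences handled downstream are in the DNA alphabet.
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `read_id`, `sequence`, `quality`.
#'   Sequence and quality strings of each record have equal length.
#' @details Malformed records (missing header `@`, missing `+` separator,
#'   length mismatch between sequence and quality, or characters outside
#'   `A,C,G,T,N,U`) raise an error naming the 1-based record index.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error: line count ", length(lines),
         " is not a multiple of 4 in '", path, "'")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seqs <- toupper(lines[4L * idx - 2L])
  plus <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("FASTQ parse error at record ", bad[1L],
                        ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("FASTQ parse error at record ", bad[1L],
                        ": separator line does not start with '+'")
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) stop("FASTQ parse error at record ", bad[1L],
                        ": sequence and quality lengths differ")
  bad <- which(grepl("[^ACGTNU]", seqs))
  if (length(bad)) stop("FASTQ parse error at record ", bad[1L],
                        ": sequence contains characters outside {A,C,G,T,N,U}")

  data.frame(read_id = sub("^@", "", hdr),
             sequence = gsub("U", "T", seqs, fixed = TRUE),
             quality = qual, stringsAsFactors = FALSE)
}

#' Write a 4-line-record FASTQ file
#'
#' Inverse of [read_fastq()]: `write_fastq` followed by `read_fastq` is the
#' identity on well-formed DNA records.
#'
#' @param records data.frame with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(records)))
  if (any(nchar(records$sequence) != nchar(records$quality))) {
    stop("sequence and quality lengths differ")
  }
  out <- character(4L * nrow(records))
  idx <- seq_len(nrow(records))
  out[4L * idx - 3L] <- paste0("@", records$read_id)
  out[4L * idx - 2L] <- records$sequence
  out[4L * idx - 1L] <- "+"
  out[4L * idx] <- records$quality
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()]. Sequence names are
#' truncated at the first whitespace; `U` is normalized to `T` so miRBase
#' mature RNA references load into the DNA alphabet.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA sequence ", which(bad)[1L],
         " contains characters outside {A,C,G,T,N,U}")
  }
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA sequence IDs")
  seqs
}

#' Write a named character vector to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Trim a 3'-adapter from a read
#'
#' Truncates each sequence at the leftmost exact occurrence of the adapter's
#' first 6 nt (the full adapter if it is exactly 6 nt). A read in which the
#' adapter is not found is returned unchanged. Trimmed results shorter than
#' `min_len` (and empty input reads) are discarded, encoded as `NA`.
#'
#' @param sequence Character vector of DNA reads.
#' @param adapter Adapter sequence, at least 6 nt.
#' @param min_len Minimum surviving length, default 14 nt; survivors must be
#'   at least this long (inclusive).
#' @return Character vector of the same length; `NA` marks discarded reads.
#' @export
trim_adapter <- function(sequence, adapter, min_len = 14L) {
  stopifnot(nchar(adapter) >= 6L, min_len >= 1L)
  probe <- toupper(substr(adapter, 1L, 6L))
  sequence <- toupper(sequence)
  out <- sequence
  hit <- regexpr(probe, sequence, fixed = TRUE)
  has <- hit > 0L
  out[has] <- substr(sequence[has], 1L, hit[has] - 1L)
  out[is.na(out) | nchar(out) < min_len] <- NA_character_
  out
}

#' Read and validate a sample sheet
#'
#' The sample sheet describes the library design: one row per small-RNA
#' library with its condition and replicate number. A full run uses 12
#' libraries (3 replicates x 4 conditions).
#'
#' @param path TSV file with header columns `library_id`, `condition`,
#'   `replicate`.
#' @return data.frame with `condition` as a factor over [CONDITIONS].
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(ss)
}

#' Validate a sample-sheet data.frame
#'
#' @param ss data.frame with columns `library_id`, `condition`, `replicate`.
#' @return The validated data.frame, `condition` coerced to factor.
#' @export
validate_sample_sheet <- function(ss) {
  need <- c("library_id", "condition", "replicate")
  if (!all(need %in% names(ss))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ss$library_id)) stop("duplicate library_id in sample sheet")
  bad <- setdiff(unique(ss$condition), CONDITIONS)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (any(ss$replicate < 1 | ss$replicate != round(ss$replicate))) {
    stop("replicate must be a positive integer")
  }
  ss$condition <- factor(ss$condition, levels = CONDITIONS)
  ss
}

# Map printed significance stars to class labels.
star_to_class <- function(x) {
  x <- trimws(x)
  map <- c("ns", "p05", "p01", "p001")
  n <- nchar(x)
  if (any(n > 3) || any(grepl("[^*]", x))) {
    stop("fixture-integrity error: unmappable significance mark")
  }
  map[n + 1L]
}

# Normalize printed decimal commas ("-1,93") to points and parse.
parse_printed_number <- function(x) {
  as.numeric(gsub(",", ".", trimws(x), fixed = TRUE))
}

#' Load the packaged per-miRNA drought/rehydration fold-change table
#'
#' A 58-row table of conserved miRNAs differentially accumulated in drought
#' and/or rehydration: per miRNA the printed log2 fold change and
#' significance-star class for both contrasts. Printed decimal commas are
#' normalized to points on load and star marks are mapped to classes
#' (`ns`, `p05`, `p01`, `p001`).
#'
#' @param path Path to the fixture TSV; defaults to the copy shipped with
#'   the package.
#' @return data.frame with columns `mirna_name`, `log2fc_drought`,
#'   `p_class_drought`, `log2fc_rehydration`, `p_class_rehydration`.
#' @export
load_table2_fixture <- function(path = system.file("extdata",
                                                   "mirna_de_table.tsv",
                                                   package = "mirpare")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("mirna_name", "log2fc_drought", "sig_drought",
            "log2fc_rehydration", "sig_rehydration")
  if (!all(need %in% names(raw))) {
    stop("fixture-integrity error: missing columns")
  }
  if (nrow(raw) != 58L) {
    stop("fixture-integrity error: expected 58 rows, found ", nrow(raw))
  }
  out <- data.frame(
    mirna_name = raw$mirna_name,
    log2fc_drought = parse_printed_number(raw$log2fc_drought),
    p_class_drought = star_to_class(raw$sig_drought),
    log2fc_rehydration = parse_printed_number(raw$log2fc_rehydration),
    p_class_rehydration = star_to_class(raw$sig_rehydration),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$log2fc_drought) || anyNA(out$log2fc_rehydration)) {
    stop("fixture-integrity error: unparseable fold change")
  }
  out
}

#' Load the packaged abscisic-acid content measurements
#'
#' Printed ABA contents (ng per g fresh weight) for the four conditions of
#' the watering-regime design, used by the fold-increase worked example.
#'
#' @param path Path to the fixture TSV; defaults to the packaged copy.
#' @return data.frame with columns `condition`, `aba_ng_g_fw`.
#' @export
load_aba_fixture <- function(path = system.file("extdata", "aba_content.tsv",
                                                package = "mirpare")) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "aba_ng_g_fw") %in% names(out)))
  out
}

#' Write a data.frame as a TSV file
#'
#' @param x data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
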