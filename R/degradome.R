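# Degradome (PARE) tag processing: length filtering, exact transcriptome
# mapping of tag 5' ends, per-transcript cleavage profiles with three
# t-plot views, and competition-ranked cleavage sites.

#' Filter degradome tags by minimum length
#'
#' Keeps adapter-trimmed tags at least `min_len` nucleotides long
#' (inclusive boundary, default 14 nt); survivors pass unchanged.
#'
#' @param tags Character vector of tag sequences.
#' @param min_len Minimum tag length, default 14.
#' @return Character vector of surviving tags, order preserved.
#' @export
filter_tags <- function(tags, min_len = 14L) {
  tags[!is.na(tags) & nchar(tags) >= min_len]
}

#' Map tag 5' ends onto transcripts
#'
#' Places every tag at every exact, zero-mismatch, forward-strand
#' occurrence of the tag inside any transcript (all occurrences are
#' counted, with no fractional weighting). Each placement increments the
#' profile of the transcript at the occurrence's 1-based start position --
#' the coordinate of the tag's 5' end, which for PARE tags marks the
#' cleavage site.
#'
#' @param tags Character vector of tag sequences (one element per
#'   sequenced tag; duplicates are counted with their multiplicity).
#' @param transcripts Named character vector of transcript sequences.
#' @param library_id Label stored on each profile.
#' @return Named list of [transcript_profile()] objects, one per
#'   transcript, with attributes `mapped_placements`, `unmapped_tags`, and
#'   `total_tags`.
#' @export
map_five_prime_ends <- function(tags, transcripts, library_id = "lib") {
  if (anyDuplicated(names(transcripts))) stop("duplicate transcript IDs")
  subj <- Biostrings::DNAStringSet(transcripts)
  tab <- table(tags)
  profiles <- lapply(transcripts, function(tx) integer(nchar(tx)))
  mapped_tags <- logical(length(tab))
  placements <- 0L
  for (k in seq_along(tab)) {
    tag <- names(tab)[k]
    mult <- as.integer(tab[k])
    hits <- Biostrings::vmatchPattern(tag, subj, fixed = TRUE)
    starts <- Biostrings::startIndex(hits)
    for (i in seq_along(starts)) {
      st <- starts[[i]]
      if (is.null(st) || !length(st)) next
      mapped_tags[k] <- TRUE
      placements <- placements + length(st) * mult
      id <- names(transcripts)[i]
      for (s in st) profiles[[id]][s] <- profiles[[id]][s] + mult
    }
  }
  out <- lapply(names(transcripts), function(id) {
    transcript_profile(id, profiles[[id]], library_id)
  })
  names(out) <- names(transcripts)
  attr(out, "mapped_placements") <- placements
  attr(out, "unmapped_tags") <- sum(as.integer(tab)[!mapped_tags])
  attr(out, "total_tags") <- length(tags)
  out
}

#' Construct a per-transcript cleavage profile
#'
#' @param transcript_id Transcript identifier.
#' @param raw Integer vector of tag 5'-end counts per 1-based transcript
#'   position; its length is the transcript length.
#' @param library_id Degradome library the profile comes from.
#' @return An object of class `transcript_profile`.
#' @export
transcript_profile <- function(transcript_id, raw, library_id = "lib") {
  stopifnot(is.numeric(raw), all(raw >= 0))
  structure(list(transcript_id = transcript_id, length = length(raw),
                 raw = as.integer(raw), library_id = library_id),
            class = "transcript_profile")
}

#' @export
print.transcript_profile <- function(x, ...) {
  cat("transcript_profile ", x$transcript_id, " [", x$library_id, "]: ",
      x$length, " nt, ", sum(x$raw), " placements at ",
      sum(x$raw > 0), " positions\n", sep = "")
  invisible(x)
}

#' T-plot views of a cleavage profile
#'
#' Computes, per transcript position, the three standard t-plot views:
#' the raw tag count, the per-million normalization against the mapped
#' library total, and the average-based view (count divided by the mean
#' count over all transcript positions; all-zero profiles give zeros).
#'
#' @param profile A [transcript_profile()].
#' @param library_total Total mapped placements of the library; must be at
#'   least the profile's own placement count and positive.
#' @return data.frame with columns `position`, `raw`, `per_million`,
#'   `average_based`, one row per transcript position.
#' @export
tplot_views <- function(profile, library_total) {
  if (library_total <= 0) stop("library_total must be positive")
  if (library_total < sum(profile$raw)) {
    stop("library_total smaller than the profile's mapped placements")
  }
  m <- mean(profile$raw)
  data.frame(
    position = seq_len(profile$length),
    raw = profile$raw,
    per_million = profile$raw * 1e6 / library_total,
    average_based = if (m > 0) profile$raw / m else rep(0, profile$length)
  )
}

#' Competition-ranked cleavage sites of a profile
#'
#' Positions with nonzero counts are ranked by count, descending, with
#' competition ranking: equal counts share a rank, and the next-lower
#' count gets rank 1 + (number of positions with a strictly greater
#' count).
#'
#' @param profile A [transcript_profile()].
#' @return data.frame with columns `position`, `count`, `rank`, ordered by
#'   rank then position; zero-count positions are omitted.
#' @export
rank_sites <- function(profile) {
  pos <- which(profile$raw > 0)
  cnt <- profile$raw[pos]
  rk <- vapply(cnt, function(c) 1L + sum(cnt > c), integer(1))
  out <- data.frame(position = pos, count = cnt, rank = rk)
  out[order(out$rank, out$position), , drop = FALSE]
}

#' Export a t-plot table
#'
#' Writes the nonzero positions of a profile as a TSV with columns
#' `position`, `raw`, `per_million`, `average_based`, `rank`.
#'
#' @param profile A [transcript_profile()].
#' @param library_total Mapped library total for the per-million view.
#' @param path Output path.
#' @return The exported data.frame, invisibly.
#' @export
export_tplot <- function(profile, library_total, path) {
  views <- tplot_views(profile, library_total)
  ranks <- rank_sites(profile)
  out <- merge(views[views$raw > 0, , drop = FALSE],
               ranks[, c("position", "rank")], by = "position")
  out <- out[order(out$position), , drop = FALSE]
  write_tsv(out, path)
  invisible(out)
}
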