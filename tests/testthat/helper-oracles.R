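# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-derivations, separate from the package's code
# paths.

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(len) paste(sample(BASES4, len, replace = TRUE),
                                collapse = "")

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Leftmost-occurrence adapter trimming by exhaustive scan over all start
# positions.
oracle_trim <- function(seq, adapter, min_len) {
  if (nchar(seq) == 0) return(NA_character_)
  probe <- substr(adapter, 1, 6)
  k <- nchar(probe)
  hit <- NA_integer_
  for (s in seq_len(max(nchar(seq) - k + 1, 0))) {
    if (substr(seq, s, s + k - 1) == probe) { hit <- s; break }
  }
  out <- if (is.na(hit)) seq else substr(seq, 1, hit - 1)
  if (nchar(out) < min_len) NA_character_ else out
}

# All exact occurrence start positions of a pattern in a subject.
oracle_occurrences <- function(pattern, subject) {
  k <- nchar(pattern)
  n <- nchar(subject)
  if (k > n) return(integer(0))
  which(vapply(1:(n - k + 1),
               function(s) substr(subject, s, s + k - 1) == pattern,
               logical(1)))
}

# Character-by-character duplex penalty of one window, independent of the
# package's vectorized scanner. Window starts at `s` on the transcript.
oracle_window_penalty <- function(mirna, transcript, s) {
  L <- nchar(mirna)
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(transcript, "")[[1]]
  total <- 0
  for (i in 1:L) {
    tb <- t[s + L - i]
    mb <- m[i]
    comp <- c(A = "T", C = "G", G = "C", T = "A")[[mb]]
    w <- if (tb == comp) 0
         else if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) 0.5
         else 1
    if (i >= 2 && i <= 13) w <- 2 * w
    total <- total + w
  }
  total
}

# Competition ranking by sort-and-count.
oracle_ranks <- function(counts) {
  vapply(counts, function(c) 1L + sum(counts > c), integer(1))
}

# Plant a single-defect (mismatch or wobble) into a perfect target site at
# miRNA position `i`, returning the modified site (5'->3' transcript
# orientation). `kind` is "mismatch" or "wobble".
plant_defect <- function(mirna, i, kind = "mismatch") {
  site <- strsplit(revcomp_chr(mirna), "")[[1]]
  L <- nchar(mirna)
  j <- L - i + 1  # site index paired with miRNA position i
  mb <- strsplit(mirna, "")[[1]][i]
  comp <- c(A = "T", C = "G", G = "C", T = "A")[[mb]]
  if (kind == "wobble") {
    # G:U wobble exists only for miRNA G (target T) or miRNA T (target G)
    stopifnot(mb %in% c("G", "T"))
    site[j] <- if (mb == "G") "T" else "G"
  } else {
    # any base that is neither the complement nor a wobble partner
    cand <- setdiff(BASES4, comp)
    if (mb == "G") cand <- setdiff(cand, "T")
    if (mb == "T") cand <- setdiff(cand, "G")
    site[j] <- cand[1]
  }
  paste(site, collapse = "")
}
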