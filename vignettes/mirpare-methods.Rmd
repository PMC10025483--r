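---
title: "Methods: small RNA and degradome analysis of drought-responsive miRNAs"
author: "mirpare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA and degradome analysis of drought-responsive miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpare)
```

# Scope

`mirpare` implements the computational side of a conserved-miRNA drought and
rehydration study: twelve small-RNA libraries (3 biological replicates of
each of `control_1`, `drought`, `control_2`, `rehydration`) are collapsed
into a count matrix, conserved miRNAs are identified against a mature
reference, differential accumulation is tested per contrast
(drought vs control_1, rehydration vs control_2), degradome (PARE) tags
locate cleavage sites on transcripts, duplex alignment plus cleavage-site
rank produce a 0--18 compliance score per candidate target, and qPCR Ct
tables are folded in through 2^-ddCt with an anticorrelation call per
miRNA/target pair. A deterministic generator produces synthetic inputs with
the same statistical structure, so the full pipeline runs and is tested
without any external download.

# Conserved-miRNA identification

Reads are adapter-trimmed by truncation at the leftmost exact occurrence of
the adapter's first 6 nt. Trimming kits differ and the relevant published
constraint is the survivor rule, so the trimmer is deliberately the simplest
deterministic rule; the adapter sequence is a run parameter, and survivors
must be at least 14 nt (inclusive). Distinct sequences are tallied per
library, and only sequences reaching 10 counts in at least one of the 12
libraries are carried forward.

A read is assigned to a mature miRNA when the shorter of the two is an
exact substring of the longer -- zero substitutions anywhere, length
differences tolerated. Because no mismatches are allowed, exact substring
search is equivalent to a short-read BLAST with post-filtering, and is
deterministic. The length-difference bound defaults to 4 nt, which keeps
any variant inside the 20--24 nt small-RNA window around a canonical 21-mer;
it is a configuration knob. A read contained in several reference entries
is assigned only to its best match (smallest absolute length difference,
ties by reference ID); the number of cross-family ambiguous reads is
reported so a curator can inspect them.

IsomiR handling is automated: among all sequences assigned to one miRNA
name, the sequence with the highest total count across libraries is flagged
canonical (ties: smaller length difference, then lexicographically smallest
sequence). This is a reproducible proxy for manual curation, which in
practice keeps the dominant variant.

# Differential accumulation

Counts are normalized with median-of-ratios size factors: the reference for
each sequence is its geometric mean across libraries (rows containing any
zero are excluded), and a library's factor is the median ratio of its
counts to that reference. The test is a negative-binomial Wald test per
sequence:

* log2 fold change = `log2(mean_t + 0.5) - log2(mean_c + 0.5)` on
  normalized means; the 0.5 pseudo-count handles zero rows. The threshold
  classification uses this unshrunk estimate.
* dispersion `alpha` (variance `mu + alpha mu^2`) is estimated per row by
  method of moments after removing the shot-noise term, then floored at
  the across-row median of these estimates and at 1e-8. With three
  replicates per group the raw per-row estimate has only four degrees of
  freedom and systematically underestimates dispersion for many rows,
  which makes a plug-in Wald test anticonservative; flooring at the
  central value is the classic "maximum" sharing mode of early NB
  differential-expression engines and restores near-nominal type-I error
  (verified by the seeded 2000-row null simulation in the test suite).
* the standard error comes from the NB delta method through
  `log2(mean + 0.5)`, the Wald statistic is referred to the standard
  normal two-sidedly, and p-values are Benjamini--Hochberg adjusted.

This is a deliberately self-contained engine, not a drop-in for a full
empirical-Bayes implementation: there is no dispersion-trend shrinkage, no
independent filtering, and no outlier handling. The classification rule is
`up` when log2FC >= 0.6 and adjusted p <= 0.05, `down` symmetrically, both
boundaries inclusive; adjusted p is used because that is what the testing
procedure reports (a raw-p mode is available by passing raw p-values to
`classify()`). A miRNA changed in drought and unchanged after rewatering is
counted as restored; identical non-unchanged calls in both contrasts are
common.

The packaged 58-row printed fold-change table carries significance stars
rather than p-values; when classifying it, any star class counts as
significant. Its printed decimal-comma entry loads as a proper negative
number, a transcription quirk normalized at load time.

# Degradome profiles and t-plots

Tags at least 14 nt long are mapped to transcripts by exact, zero-mismatch,
forward-strand substring search; every occurrence is counted (multi-mapping
tags are counted at each placement, with no fractional weighting -- the
literal reading of an exhaustive zero-mismatch short-read mapping). The
1-based start coordinate of each placement -- the tag's 5' end -- increments
the transcript profile; for PARE tags this coordinate is the cleavage
diagnostic. Three views are computed per profile: raw counts; per-million
(raw x 1e6 / mapped library total -- the normalization constant is the
field's convention since the original analysis does not define one); and
average-based (raw / mean over all transcript positions, zero profiles
mapping to zeros). Nonzero positions are ranked by count with competition
ranking (ties share a rank; the next rank is 1 + number of strictly greater
counts). Reverse-strand hits are ignored: PARE tags are sense-strand by
construction.

# Target scoring

Every ungapped transcript window of the miRNA's length is scored against
the miRNA (antiparallel): Watson--Crick match 0, G:U wobble 0.5, mismatch
1, all doubled for miRNA positions 2--13. This is an Allen-style
complementarity penalty whose core-region doubling covers the seed and the
central, cleavage-determining nucleotides; gapped (bulged) duplexes are
excluded so that an exhaustive brute-force oracle over all windows stays
feasible, and the per-position weights are configuration constants.
Windows with penalty <= 7.5 are candidate sites. The predicted cleavage
coordinate is the transcript nucleotide paired to miRNA position 10 (AGO
slices 5' of it, between positions 10 and 11).

The compliance score of a site is

    2 * min(penalty, 7.5) + rank_penalty

with rank penalty 0 for the transcript's top-ranked cleavage site, 1 for
ranks 2--3, 2 for ranks 4--10, and 3 for lower ranks or no degradome
support. The score therefore spans exactly 0 (perfect duplex at the
dominant cleavage site) to 18 (worst admissible duplex, no support), lower
is better, and it is monotone both in the alignment penalty and in the rank
category. The internal weighting of the original published score is not
public; this scheme reproduces the printed range and ordering semantics,
but per-target values are not expected to match the original supplementary
tables numerically. Per miRNA, all hits within 1.0 of the best score are
reported as co-best. A predicted site is validated when a local maximum of
the raw profile inside the site lies within 1 nt of the predicted cleavage
coordinate.

# qPCR integration

Relative expression uses 2^-ddCt: per condition, replicate dCt values pair
the target and reference gene through the shared library; the
treated-minus-control difference of the mean dCt gives the fold change.
Significance is a two-tailed two-sample t-test on the replicate dCt values
(the standard choice for this design; testing the fold change itself would
discard the pairing). Zero-variance replicate sets -- which occur for
noise-free synthetic data -- degenerate the t statistic; the convention is
p = 1 for equal means and p = 0 otherwise. Perfect amplification
efficiency (doubling per cycle) is assumed throughout.

Raw fold changes below 1 are reported as -1/FC, so magnitudes are
symmetric around +/-1; exactly 1 maps to +1 (the boundary is folded into
the identity branch). Printed hormone-content comparisons use the plain
treated/control ratio rounded half away from zero. A target is negatively
correlated with its miRNA when the miRNA is up and the target's signed FC
is negative, or the miRNA is down and the target's signed FC exceeds 1,
with target significance at most 0.05 -- the target test alone decides
significance.

# The synthetic-data generator

The generator emulates the study conditions, and its defaults are those
conditions:

* 150 miRNAs (random 21-mers; the first two are the real miR172b-5p/-3p
  mature sequences) over the 12-library 3x4 design, NB counts with
  dispersion 0.1 -- a typical replicate-level overdispersion for small-RNA
  libraries -- and baseline means log-uniform on 20--500.
* planted effects of |log2FC| = 2 reproducing the published pattern:
  11 drought-up, 38 drought-down, 9 rehydration-up, 16 rehydration-down,
  with 5 up and 11 down common, so 6 up and 27 down are restored.
* a 10% isomiR rate, emitted as one fixed 3' length variant (+1, -1 or -2
  nt) per miRNA.
* 100 transcripts of 300--800 nt; each planted target embeds the exact
  reverse complement of its miRNA, and two degradome libraries ("ak"
  control, "as" drought) draw, per target, a binomial
  `degradome_peak_fraction` of its 20-nt tags exactly at the cleavage
  position, the rest uniformly, plus uniform background tags per
  transcript; the drought library's target tag counts scale with the
  miRNA's planted drought fold change.
* Ct tables with the reference gene at a constant Ct and target genes
  offset by a gene-specific baseline minus log2(planted FC) in the treated
  condition, independent Gaussian noise (sd 0.2 cycles) on every well.

Everything is deterministic under the config seed. The generator does not
emulate sequencing errors (substitutions would contradict the
zero-substitution matching contract by design), ligation or PCR biases,
positional adapter artifacts, pri-miRNA dynamics, or amplification-
efficiency variation in qPCR. Passing tests on this synthetic structure
therefore demonstrate correctness of the algorithms under the assumed
statistical model, not robustness to the technical artifacts of real
libraries.

One propagation fact is worth recording because it bounds what ddCt
recovery tests can demand: with independent per-well noise of sd 0.2
cycles and three replicates, the ddCt estimate has standard deviation
`sqrt(4 * 0.2^2 / 3) ~= 0.23` cycles, while a +/-15% band on the fold
change corresponds to only about +/-0.20 cycles -- so a single gene lands
inside that band only about two-thirds of the time, and the reference
gene's noise is shared across genes, so averaging over genes does not
remove it. The test suite therefore checks calibration (unbiasedness and
3-sigma coverage) rather than a 15% band.

# Numerical choices and problem sizes

Coordinates are 1-based inclusive on the transcript sense strand
everywhere user-facing. U is normalized to T at every boundary, so all
internal sequence handling is in the DNA alphabet. Ties at classification
boundaries are inclusive by construction. The test suite exercises the NB
engine at 1,800--2,000 rows with three replicates per group, the duplex
aligner against an exhaustive per-window oracle on transcripts up to 500
nt, end-to-end target recovery on 100 planted miRNA/transcript pairs at
degradome peak fraction 0.3, and ddCt recovery on 100 genes -- sizes chosen
so each statistical check has enough resolution to detect a real defect
while the whole suite stays quick to run.

# Known limitations

* The NB engine is intentionally simplified; borderline rows near the
  0.6/0.05 thresholds can be called differently than by a full
  empirical-Bayes implementation.
* Ungapped duplex scanning misses bulged target sites.
* Multi-transcript tags are counted at every placement, which can inflate
  profiles of repetitive transcripts.
* The compliance score reproduces range and ordering, not the original
  per-target numbers.
* No novel-miRNA discovery, precursor folding, or genome mapping; the
  mature reference defines the identifiable universe.
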