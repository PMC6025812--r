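---
title: "ampliphase: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliphase: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliphase)
```

## The problem

Double-barcoded amplicon sequencing pools many samples × loci into one
paired-end Illumina run; after demultiplexing, each read pair carries a
sample (taxon) and locus annotation in its header.  For phylogenomic work
in groups with frequent whole-genome duplication — many plant genera are a
mixture of diploids, high polyploids and accessions of unknown ploidy —
the question at each single-copy locus is not just "what is the consensus
sequence" but "which allelic haplotypes does this individual carry, and in
how many copies".  Consensus callers discard exactly that within-individual
variation.  `ampliphase` takes annotated FASTQ pairs to phased per-locus
haplotype calls in three file-to-file stages, so any stage can be replaced
by an external tool.

## Stage 1: preprocessing

**Trimming.** Each mate is scanned with a sliding window of width
`w = max(1, floor(0.1 * len))`.  The 5' cut sits at the first window whose
mean PHRED reaches the threshold (default Q20), refined to the first base
at or after the window start that itself meets the threshold; the 3' cut
is the mirror image.  Reads shorter than `min_length` (default 100 bp)
after trimming are dropped.  The refinement step matters: with a pure
window rule a read of 120 bp at Q30 followed by 30 bp at Q2 would keep
five bases of the bad tail (the last passing window ends at position 125);
the base-level refinement cuts at 120, which is the behaviour a
window-trimmer user expects.

**Merging.** The reverse-complemented second mate is searched for a
3'(R1)/5'(R2) overlap of at least `min_overlap` (default 10) bases;
candidates are ranked by mismatch fraction (ties to the longest overlap)
and accepted at `max_mismatch_frac` (default 0.25).  Conflicting bases
take the higher PHRED score, ties keeping R1.  Pairs with no acceptable
overlap — long amplicons, or aggressive trimming — are **artificially
joined** as `R1 + N×10 + revcomp(R2)` so both mates stay together through
clustering; `N` matches any base in every downstream comparison.  If only
one mate survives trimming it is emitted alone rather than discarded,
maximising data retention.  Read accounting is exact:
`input = discarded + merged + N-joined + single-survivor`.

**Per-locus error.** For each locus, mean PHRED within each retained
trimmed mate is averaged across mates and converted to an error rate
`eps = 10^(-Qbar/10)`, clamped to [1e-6, 0.5].  Error rates are estimated
*after* trimming, so only bases that actually enter clustering inform
`eps`.  Uniform Q20 gives the familiar 1%.

## Stage 2: clustering and chimera filtering

Identity between two sequences is global (Needleman–Wunsch) alignment
identity — matches over alignment columns, terminal gap columns excluded,
`N` wild — under match +1 / mismatch −1 / gap −2.  The aligner runs in a
diagonal band that widens until a certificate proves the banded optimum
unrestricted-optimal (any path leaving a band of half-width *b* pays at
least `|n−m| + 2(b+1)` gap characters), so results are exact, not
heuristic.  Greedy clustering scans records in decreasing abundance
(ties lexicographic); each record joins the **best**-identity centroid at
or above the round's threshold, or founds a new centroid.  Best-hit (not
first-hit) assignment makes the outcome robust to order among
equal-abundance records.  A word-count prefilter (shared 8-mers) skips
alignments that provably cannot reach the threshold; it changes nothing
about which centroid wins, only how fast the loss is established, and is
verified against a brute-force oracle in the test suite.

Rounds default to identity thresholds (0.997, 0.995, 0.990, 0.997) with a
chimera-filter pass before each clustering pass.  These numbers are
package defaults, documented and overridable — users reproducing a
particular published pipeline should pass that pipeline's schedule
explicitly.  Clustering is always per taxon within a locus: haplotypes are
called per individual, and cross-taxon merging would destroy the
per-individual cluster sizes the likelihood model needs.

**Chimera model.** A centroid is flagged as a PCR chimera when two
parents, each at least `abundance_skew` (default 2×) its size, explain it
piecewise: some breakpoint gives prefix identity ≥ `chimera_identity`
(default 0.99) to one parent and suffix identity ≥ the same to the other,
while no single parent reaches that identity full-length.  Two additional
requirements of at least 3 *diagnostic* positions per side (positions
matching that side's parent but not the other) are imposed.  Without
them, degenerate breakpoints a few bases from either end flag ordinary
error-bearing reads — in simulations at 2% haplotype divergence the naive
rule discards 2–5% of genuine reads.  Flagged sizes are reported, never
redistributed, so `Σ kept + Σ flagged = Σ input` holds exactly per round.

## Stage 3: haplotype inference

Clusters identical up to gaps are merged first (survivor = fewer gap/N
characters; sizes added): an N-joined cluster and a fully merged cluster
of the same haplotype must not be counted as two alleles.  This requires
equal-length (aligned) clusters; `crunch(realign = TRUE)` runs the
internal center-star aligner (center = maximal summed identity, ties to
longest then lexicographic; pairwise alignments merged by gap
propagation), optionally followed by column cleaning, which drops columns
whose informative-character occupancy is strictly below the threshold
(`clean = 0.33` keeps a column present in 1 of 3 rows, drops 1 of 4).

**Known ploidy K.** With size-sorted cluster counts `n_1 ≥ … ≥ n_m`, a
dosage configuration is an integer partition `(k_1 ≥ … ≥ k_j)` of K —
for a tetraploid: (4), (3,1), (2,2), (2,1,1), (1,1,1,1).  Under
configuration k with error rate eps, the first j clusters are real with
expected proportions `p_i = (1−eps)·k_i/K`, the remaining m−j share the
error mass eps uniformly (when j = m the error mass is renormalised
away).  The multinomial kernel `Σ n_i log p_i` ranks configurations; the
argmax is returned, ties preferring fewer distinct haplotypes, then a
larger leading dosage.  Since clusters are sorted, no more than the K
largest can ever be real, which keeps the enumeration tiny even at high
ploidy.  Output haplotypes carry their copy numbers (summing to K), or one
copy each under `unique_only`.

**Unknown ploidy.** Hypothesis h (h = 0…m) states that the h largest
clusters are real (`p_i = (1−eps)/h`) and the rest are errors
(`p_i = eps/(m−h)`); h = 0 and h = m are the uniform 1/m edge cases.
Starting from h = 1, h+1 is accepted while the relative increase
`(LL(h+1) − LL(h)) / |LL(h)|` reaches the cutoff (default 10%).  The
relative increase is computed on the log-likelihood scale: at realistic
read counts raw likelihoods underflow to zero, so a raw-scale ratio is not
computable, and the log-scale ratio is the natural well-defined analogue.
h = 0 is evaluated and reported but never selected — an individual with
reads has at least one haplotype.  This scan is deliberately conservative:
with one dominant cluster and a long tail of small ones it calls few
haplotypes, which is the designed behaviour when nothing bounds the
haplotype count.

**Haploid mode** returns the single largest cluster (ties to the
lexicographically smallest sequence) — a clustering-based alternative to
consensus calling, also appropriate for organellar loci.

## The synthetic-data generator

`sim_config()` states the world the test suite lives in: ~550 bp
amplicons read as 300 bp pairs (a guaranteed ≥ 50 bp overlap), 200 read
pairs per taxon × locus, per-base error 0.005 (≈ Q23, mid-range for
amplicon MiSeq data), 2% haplotype divergence, and a default dosage of
`(ceil(K/2), floor(K/2))`.  Chimeras are single-breakpoint two-parent
recombinants with a uniform breakpoint — exactly the model the filter
tests.  Non-overlapping pairs are produced by shortening both mates so no
acceptable overlap exists.  Quality strings are integer PHRED values
jittered ±2 around `round(−10·log10(eps))`, so the per-read mean equals
the target in expectation and the locus-error table is directly
checkable.  The generator does **not** emulate per-cycle Illumina error
profiles, indel sequencing errors, primer artefacts, or abundance bias
between alleles; a green recovery test therefore establishes correctness
of the inference machinery under its own model, not robustness to every
real-world artefact.

## Numerical and design choices

- All tie-breaks (cluster order, centroid assignment, survivor choice,
  partition argmax, haploid ties) are explicit, so runs are
  bit-reproducible; the pipeline log records version, resolved
  configuration and input digests.
- eps outside (0,1) is clamped into [1e-6, 0.5] with a warning; a cluster
  probability of zero yields −Inf, never an exception.
- Files are written atomically (temp + rename); FASTQ is Sanger PHRED+33
  (+64 selectable).
- Config files are JSON rather than TOML: the R ecosystem this package
  targets ships a JSON parser everywhere, and hand-rolling a TOML reader
  would be a liability.
- The center-star aligner is O(k²) in the number of cluster sequences and
  is meant for the tens of clusters per taxon × locus this pipeline
  produces, not for large MSAs; an external aligner can be substituted at
  the file level between stages.

## Known limitations

Allelic PCR bias is not modelled: the multinomial expects reads in
proportion to dosage, so strong amplification bias can shift the inferred
partition.  Ploidy itself is never estimated — the unknown-ploidy scan
counts well-supported haplotypes, which lower-bounds but does not identify
K.  Indel sequencing errors are not simulated, and the gap-identical
merge deliberately discards indel variation that separates otherwise
identical clusters.
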