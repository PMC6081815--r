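---
title: "Methods: viral population ecology and virus-host linkage in virolink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viral population ecology and virus-host linkage in virolink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

virolink implements the computational ecology that sits downstream of
metagenome assembly and binning in sediment virus studies: clustering viral
contigs into populations, estimating their abundance across samples,
predicting which microbial genomes they infect, profiling
sulfate-reducer/methanogen marker genes, and testing community-level
structure. This vignette explains the models, parameter choices and
numerical decisions; it is the package's record of *why* things are the way
they are.

## Viral populations (vOTUs)

Two contigs belong to the same viral population when their average
nucleotide identity (ANI) is at least 0.95 over at least 80% of the shorter
contig's length. `estimatePairwiseANI()` estimates ANI without a full
aligner: exact k-mer anchors (k = 15) shared by the two sequences are
grouped by diagonal, chained greedily (largest anchor support first,
non-overlapping spans), extended outward ungapped, and identity is counted
base-by-base over the chained spans. The aligned fraction uses the shorter
contig as denominator, following the community clustering standard; the
published threshold sentence does not say which contig's length is meant,
and the shorter-contig convention is the conservative one for fragmented
assemblies. The estimator is exact enough for thresholding: on indel-free
pairs up to 10% divergence it tracks global-alignment identity within 0.01
(checked in the test suite against `Biostrings::pairwiseAlignment`).

`clusterVOTUs()` uses greedy centroid clustering: contigs strictly longer
than 5000 bp are sorted by decreasing length (ties broken lexicographically
by id, making the procedure fully deterministic); each contig joins the
first existing seed it matches at both thresholds (inclusive), otherwise it
founds a new population. The seed, being processed first, is always the
longest member. On community-sized inputs the greedy result coincides with
the transitive closure of the all-pairs graph at the same thresholds; the
acceptance suite asserts this equivalence on 50 contigs in 12 families.

Abundance is reads-per-kilobase-per-million in the form
`mapped_reads * 1e9 / (total_reads * contig_length)`, computed for the
population's representative contig only. Pooling member placements would
double-count reads that map equally well to several near-identical members;
a flag to pool is deliberately not provided because members are by
construction >= 95% identical to the seed. Presence gating: a population
counts as present in a sample only when reads cover at least 75% of the
representative's length (inclusive at exactly 0.75, since the rule is
"at least"); RPKM is zeroed where absent, so the reported matrix is exactly
the ungated matrix times the presence mask. Whether the RPKM denominator is
per-sample QC'd totals or mapped reads is configurable; the default is
QC'd totals, which is what per-sample sequencing-depth normalization wants.

Shannon diversity is the natural-log form on relative abundances of present
populations; an all-absent sample has undefined diversity and is reported
as `NA` rather than 0, because "no community" and "one-member community"
must not collapse to the same value.

## Virally encoded metabolic genes

`screenMetabolicGenes()` applies four conjunctive criteria to gene
annotations: interior position (not among the first or last two genes on
the contig — prophage boundaries and contig ends are where host genes
contaminate assemblies), hallmark-bearing contig (at least one capsid,
tail, terminase or similar gene, so the contig is confidently viral),
product recurrence on at least three distinct viral contigs (a singleton is
more likely mis-annotation), and a host-metabolism-only product. The last
criterion cannot be derived from the data; it ships as a small allow-list
(`defaultAMGAllowList()`) that users should replace with their own
curation. No attempt is made to adjudicate borderline products
automatically.

## Virus-host linkage

Four independent evidence lines, integrated by union with per-method flags:

* **Prophage alignment screen** — consumes standard 12/13-column tabular
  alignment output and passes a hit when query coverage >= 0.75, identity
  >= 70%, bit score >= 50 and e-value <= 0.001, all inclusive. The aligner
  itself is external for real data; `scanProphagesExact()` (verbatim
  substring search on both strands) closes the loop for synthetic tests.
* **CRISPR spacers** — `detectCrisprArrays()` is a CRT-style detector: an
  exact 21-mer anchor recurring >= 4 times with gaps compatible with
  repeat (21-48 bp) + spacer (20-50 bp) geometry seeds a candidate; the
  repeat is extended while all copies agree unanimously; one copy may be
  degenerate (<= 1 mismatch to the consensus) and is recovered by a
  consensus rescan that also tolerates a broken anchor (a gap of two
  periods). Spacers then link hosts to viruses when they align end-to-end
  (no indels, either strand) with at most one mismatch
  (`matchSpacers()`); the score is the minimal mismatch count, verified in
  tests against an exhaustive sliding-window scan.
* **d2\*** — alignment-free dissimilarity on strand-summed 6-mer counts
  centered by their expectation under an order-2 Markov background fit to
  each sequence, normalized to [0, 1]; `<= 0.2` (inclusive) is a link.
  Words with zero background probability in either sequence are skipped —
  their centered counts are identically zero, and this convention keeps
  self-dissimilarity exactly 0. The implementation is verified against a
  literal brute-force version (explicit loops over all 4^6 words) to
  1e-10.
* **Markov likelihood** — each host genome trains an order-8 transition
  model with one pseudo-count per cell (`trainMarkovModel()`); a virus is
  scored by mean log-likelihood per base over the *circularized* contig
  (the first 8 bases are appended at the end). Circular scoring reflects
  that most phage genomes are circular or circularly permuted, and it buys
  two exact invariances: rotation of the contig and self-concatenation
  leave the score unchanged. Per virus, a Gaussian is fit to its scores
  across all candidate hosts and the p-value is the upper tail of the best
  score; `p < 0.001` (strict) emits a link whose reported taxonomy is the
  lowest common ancestor of the five best-scoring hosts. Truncated
  lineages constrain only the ranks they state. With fewer than three
  candidate models the Gaussian null is meaningless and the function
  refuses, pointing at d2* instead.

Threshold polarity follows the wording of each rule: "at least"/"minimum"
thresholds are inclusive, "p < 0.001" is strict, "<= 0.2" is inclusive.

## Marker-gene guild profiling

Hits (from external HMM searches, consumed as a table) are filtered by
minimum protein length — DsrA 302, DsrD 57, McrA 150 amino acids, inclusive
— and dsrA is additionally restricted to the reductive type, taken from an
input column because the reductive/oxidative split is a reference-tree
judgment, not something this package re-derives. Abundance is per-contig
RPKM with the same formula as vOTUs but no breadth gating (marker contigs
are typically well covered and the gating rule is specific to the viral
table). Heatmap clustering is euclidean/complete over contig profiles;
branch confidence is an ordinary bootstrap proportion over resampled
samples (rows). This is deliberately *not* the approximately-unbiased
multiscale bootstrap: ordinary proportions are simpler, well-defined at any
n, and the 0.95 flag threshold is kept; AU p-values are a documented
non-goal. Paired wetland comparisons use the two-sided paired t test.

## Community statistics

All permutation tests share three conventions: deterministic under a seed,
`p = (1 + #{perm >= obs}) / (1 + n_perm)` so the observed statistic is
always counted and the p-resolution is exactly `1/(n_perm+1)`, and ties at
the observed value count as exceedances (a 1e-12 tolerance guards floating
point).

* `brayCurtis()` — `sum|x-y| / sum(x+y)`; a pair of all-zero samples is an
  error, not a silent 0.
* `permanova()` — Anderson's among/within partition of squared
  dissimilarities, one factor, free label permutation (the reported
  analyses are single-factor); for n <= 8 an exhaustive mode enumerates
  all n! permutations and returns the exact p.
* `nmdsOrdination()` — nonmetric SMACOF: isotonic regression of
  configuration distances on dissimilarity ranks (primary ties averaged
  before the fit) alternates with Guttman-transform updates; Kruskal
  stress-1 is the objective; best of 20 starts (classical scaling plus
  random configurations); convergence when the stress change drops below
  1e-6. The majorization update makes stress non-increasing within a
  start, which the tests assert.
* `procrustesProtest()` — both configurations centered and scaled to unit
  sum of squares, optimal rotation by SVD; correlation = sqrt(1 - m2) =
  sum of singular values; significance by row permutation of the second
  configuration.
* `rdaForwardSelect()` — redundancy analysis as PCA of fitted values from
  multivariate least squares on standardized predictors; adjusted R^2 by
  the Ezekiel correction; a global permutation test with all predictors
  gates forward selection (no selection on a non-significant global test);
  entry is by lowest permutation p-value below alpha = 0.05 — p-value
  entry only, because the reference procedure's stepping criterion is not
  further specified; AIC stepping was considered and rejected to keep one
  documented rule. Collinear predictors are dropped with a warning;
  saturated fits (residual df <= 0) are refused.
* `pcaOrdination()` — z-scored variables, eigendecomposition; zero-variance
  variables dropped with a warning.

## The synthetic community generator

`makeCommunity()` generates the full study design: 2 wetlands x 3 depths
with replicate samples (12 samples by default), 20 host genomes, 12 viral
families totalling 50 clustering-eligible contigs (> 5 kb) plus 10 short
contigs (1.5-5 kb), 10 implanted prophages, 3 CRISPR arrays of 4 spacers
each, a marker-hit table, and a geochemistry matrix with a wetland effect.

Design choices that matter:

* **Codon-usage composition.** Host genomes (and the viral families they
  seed) are built by concatenating triplets drawn from a host-specific
  codon-usage distribution (Dirichlet over 64 triplets, concentration 0.5,
  tilted to a GC in 0.30-0.70). I.i.d. or low-order Markov sequences carry
  *no* signal beyond the order-2 d2* background — composition-based host
  prediction would be structurally impossible on them — whereas codon bias
  is exactly the phase-dependent k-mer structure those methods exploit in
  real genomes. The concentration was set so that true virus-host pairs
  fall in the d2* range reported for real pairs (~0.1-0.25) while
  unrelated pairs sit near 0.5.
* **Family geometry.** Members diverge from their parent by at most 2%
  substitutions, so within-family ANI stays >= ~96%; some parents are
  10-15%-diverged copies of an earlier parent, so the contig set spans
  0-15% divergence while families remain exactly the 95%-ANI clusters and
  clustering truth is unambiguous.
* **Implantation safety.** Prophage positions are drawn on the original
  host coordinates and applied in descending order per host, so a later
  implant cannot land inside and split an earlier one. CRISPR arrays go to
  hosts without prophages. Truth arrays use identical repeats; detector
  tolerance to degeneracy is tested separately.
* **Placements, not reads.** Read mapping is replaced by direct placement
  simulation: Poisson read counts with mean `depth * length / read_len`,
  uniform positions fully inside the contig. This keeps everything
  desk-scale and gives closed-form expectations (`RPKM ~ depth / read_len
  * 1e9 / total`, breadth `~ 1 - exp(-depth)`) that the tests check. A
  plain-text SAM adapter covers real mappings.
* **What is not emulated.** Sequencing error, quality scores, paired-end
  geometry, assembly artifacts, strain microdiversity within populations,
  uneven coverage (GC bias), partial prophage decay, and CRISPR repeat
  families. Passing tests therefore demonstrate correctness of the
  *computations* under a clean generative model, not robustness to every
  messiness of real data.

## Problem sizes and runtime

The test and verification workloads are sized for a single CPU: the
end-to-end demo uses the default community (~3-4 million placements) and
runs in about three minutes; clustering equivalence uses 50 contigs;
ANI and d2* oracle comparisons use 20 pairs each (0.6-2 kb); Markov
recovery uses 10 replicate communities of 20 hosts (30 kb) x 5 viruses
(10 kb); PERMANOVA calibration uses 500 null replicates of 12 samples at
199 permutations; bootstrap-support tests use 300-1000 resamples rather
than the 10000 a publication-grade heatmap would use (the default of
`clusterHeatmap()` is 1000; pass `n_boot = 10000` to reproduce the
publication setting).

## Known limitations

* The ANI estimator is anchor-based and ungapped; heavy indel divergence
  fragments the chain and underestimates the aligned fraction (it is meant
  for the >= 95%-identity regime the clustering thresholds operate in).
* The CRISPR detector requires one exact 21-mer anchor per (non-degenerate)
  repeat copy and at most one degenerate copy per array; heavily decayed
  arrays will be missed. Parameters are exposed in the configuration.
* The Markov-likelihood null (Gaussian across candidate hosts) inherits the
  composition of the candidate set: with few or highly similar hosts the
  p-values are optimistic. Cross-phylum predictions should be treated as
  hypotheses; the link table reports method provenance rather than
  adjudicating.
* PERMANOVA is single-factor with free permutation; there is no strata or
  interaction support (a documented non-goal).
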