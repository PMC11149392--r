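---
title: "Clique-filtered ortholog distances from RNA-seq assemblies: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clique-filtered ortholog distances from RNA-seq assemblies: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the estimator

RNA-seq is usually collected to quantify expression, but the assembled
transcripts also carry genotype information. Using them for genetic
distances runs into two obstacles: coding sequence is conserved, so the
signal between close relatives is small, and many genomes — polyploids
especially — contain paralogs and homeologs whose inclusion inflates
distances. The approach implemented here is deliberately conservative:
compare only genes for which *exactly one* ortholog can be identified in
*every* sample, and measure distance as the mismatch fraction over those
alignments.

Per sample, genes are ranked by k-mer coverage (a gene's coverage is the
maximum over its isotigs) and the top `n` are kept. For each ordered sample
pair, BLASTn runs in both directions; each HSP row carries bitscore, the
number of identical bases ι, the alignment length λ (columns), and the
total gap characters γ, so λ − γ is the number of aligned base pairs. The
reduction to a gene match table is: top-`N` HSPs per query gene by bitscore
(ties kept), re-orientation of both tables to sample-1/sample-2 roles,
retention of gene pairs occurring in both directions, best row per gene
pair, best row per sample-1 gene — ties kept at every stage, so no
arbitrary choices are made.

With more than two samples, pairwise match tables would use different gene
sets for different pairs. To make comparisons commensurable, a gene matches
graph is built with one vertex per (sample, gene) and one edge per
match-table gene pair. Components with fewer vertices than samples are
*small*; with at least as many, *large*; a component that is a clique with
exactly as many vertices as samples is *ideal*. Because no edge joins two
genes of one sample, such a clique necessarily has exactly one gene per
sample. Only match rows whose gene pair lies in an ideal component
contribute to

$$S = \frac{\sum_i \iota_i}{\sum_i (\lambda_i - \gamma_i)}, \qquad D = 1 - S.$$

An empty (filtered) match table leaves the statistic undefined; the package
raises an error rather than reporting 0, since "no comparable orthologs"
and "identical" must never be conflated.

## Parameters that matter

* `n` (genes per sample, default 50000): diminishing returns past the
  coverage plateau; sweeps over `n` are provided (`sweep_components()`).
* `N` (HSPs per query gene, default 1): 1 is the strictest reciprocal-best
  setting and the default study condition.
* `evalue_cutoff` (default 1e-99): stringent homology requirement for
  BLASTn; only this cutoff is imposed, all other BLAST parameters stay at
  tool defaults (megablast).
* `min_identity_fraction` (default 0.7, builtin aligner): the desk-scale
  analogue of the e-value cutoff — an alignment is reported only if at
  least 70% of its columns are identical. For typical transcript lengths
  this is comparable in stringency to the BLAST cutoff, which for a 500 bp
  alignment requires roughly three-quarters identity.
* `mode`: with two samples the distance is computed directly from the match
  table; with three or more, ideal filtering is the default (a flag forces
  graph filtering at s = 2, where the graph reduces to reciprocal pairs).
* Orientation: entry (i, j) with i earlier in the input order uses sample i
  as "sample 1". The statistic is not provably symmetric; the measured
  asymmetry is tested to stay well below the mean distance, and
  `symmetrize = "mean"` averages both orientations when exact symmetry is
  required (neighbor joining symmetrizes its input this way).

## The built-in aligner

The production HSP engine is external BLASTn. For desk-scale work and fully
deterministic tests the package ships its own global aligner: affine-gap
Needleman–Wunsch/Gotoh (match +2, mismatch −3, gap open 5, gap extend 2, N
neutral) with ι, λ, γ read off the optimal alignment and bitscore defined
as half the raw score. Two engineering choices keep it fast without
approximation:

* *Seeding.* Candidate isotig pairs must share exact 12-mers. At identity
  q a fraction q¹² of k-mers survives, so a pair at the 0.7 reporting
  threshold is expected to share about 0.014 per aligned position; the
  threshold is half that expectation (absolute floor 2), scaled by the
  shorter sequence's length. Sequences shorter than 48 bp bypass seeding.
  Like BLAST's seeding, this is a sensitivity heuristic: pairs close to the
  identity threshold can occasionally be missed; `seed_filter = FALSE`
  restores exhaustive all-vs-all alignment.
* *Banding with a certificate.* The DP runs in a band around the main
  diagonal and the band doubles until the result is provably optimal: a
  path leaving a band of half-width w must spend at least |n−m| + 2(w+1)
  gap characters, bounding its score by 2·min(n,m) − 5 − 2(|n−m| + 2w + 2).
  Once the banded score meets that bound no out-of-band alignment can beat
  it, so reported scores are always exact global optima (the test suite
  checks exact score agreement against `Biostrings::pairwiseAlignment` and
  a plain-R reference DP). Co-optimal alignments may differ in their ι/γ
  split; the reported statistics are those of one optimal alignment.

Substitutability is tested end to end: on high-identity synthetic inputs
the builtin and BLASTn distance matrices agree to well under 10⁻³ per
entry. They are not expected to agree exactly — BLAST reports local HSPs,
the builtin aligner global ones.

## The simulation framework

`simulate_transcriptomes()` generates the validation data: a birth–death
tree (birth 1, death 0.5 per lineage per unit time) grown forward from one
lineage and stopped the first time the extant count reaches `n_taxa`
(extinct lineages pruned; leaves are therefore contemporaneous, and the
final split can be recent, so very similar leaf pairs are a legitimate
outcome); root transcripts with i.i.d. uniform bases and lengths from a
log-normal (median 500 bp, sdlog 0.6, floor 200 bp — a transcript-length
spread with a long right tail resembling real assemblies, chosen because
the package bundles no external length table); and substitution-only HKY85
evolution (default κ = 3, uniform base frequencies — conventional defaults,
as neither value is dictated by the design) with the rate matrix normalized
so branch length × `site_rate` is the expected number of substitutions per
site. Transition matrices come from the eigendecomposition of the
π-symmetrized generator; the test suite checks pairwise divergence against
the closed-form matrix exponential and the transition/transversion balance
at large κ.

Each taxon's transcriptome is emitted with rnaSPAdes-style headers, one
isotig per gene, and log-uniform coverage values on [1, 1000], so header
parsing and top-n selection are exercised end to end; the ortholog map and
the true tree are returned for scoring. All randomness flows from one seed
through named substreams (tree, lengths, roots, evolution, coverage), so
each stage is independently reproducible.

What the generator does *not* emulate: paralogy and homeology, alternative
splicing (one isotig per gene), indels, sequencing error, assembly
artifacts, or missing genes. Passing the simulation study therefore shows
that the pipeline recovers relatedness when its orthology assumptions hold;
it does not measure robustness to paralog confusion, which is exactly what
the ideal-component filter is designed to guard against on real data.

## Study conditions used in the tests

The validation study in the test suite and `scripts/acceptance.R` runs at
desk scale: 8 taxa and 300 transcripts (10 replicate seeds) for topology
recovery, 200 transcripts for the rate sweep (0.001/0.01/0.05, plus 0.1
for the collapse check), 150 transcripts for nested-prefix monotonicity,
and clone sets of 2–8 copies of a 200-gene transcriptome. These sizes keep
a full replicate under a minute with the builtin aligner while leaving
roughly 150–180 kb of aligned sequence per sample pair, enough that
distance noise (≈ 4·10⁻⁴ at D ≈ 0.02) is far below the structure being
recovered. Expected outcomes: clone distances exactly 0; neighbor-joining
trees topologically identical to the truth in at least 9 of 10 replicates
(an ultra-short internal branch can occasionally be unresolvable from
finite sequence); mean distance strictly increasing in the mutation rate;
near-total loss of ideal components at rate 0.1, where pairwise identity
(~59% between deep taxa) falls below any stringent homology cutoff.

## Numerical and degenerate-input choices

* Coverage ties at the selection boundary break by ascending gene ID, so
  selections are reproducible and nested in `n`.
* Bitscore ties are never broken: all tied rows survive each reduction and
  all contribute to the sums. `dedupe_ties = TRUE` collapses ties to the
  lexicographically smallest isotig pair for users worried about double
  counting; which convention the statistic "should" use is genuinely open,
  so both are provided.
* Neighbor joining breaks Q-criterion ties by the lowest index pair and
  keeps negative branch-length estimates as computed.
* PCoA drops negative-eigenvalue axes (their count is reported) and pads
  zero-variance axes with zero coordinates; an all-zero matrix yields
  all-zero coordinates.
* The Jaccard baseline canonicalizes k-mers over strands (lexicographic
  minimum of a k-mer and its reverse complement; default k = 21, both
  conventional choices since the baseline's original parameters are not
  fixed by the design). A pair whose filtered k-mer union is empty gets
  distance 1 with a warning rather than an error, so whole-matrix runs
  survive degenerate pairs; with two samples the ≥2-sample filter makes
  all distances 0, documented as a degenerate case.
* The fair subset-sweep strategy equalizes *measured* time per subset size
  using online running totals; the allocator details are a design choice
  (any allocation that equalizes expected time is acceptable).

## Known limitations

Distances are not proven to satisfy the metric axioms (symmetry and the
triangle inequality are open); the builtin aligner is intended for inputs
up to roughly a thousand isotigs per sample; the simulator omits the
processes listed above; and with very distantly related samples the ideal
set collapses to nothing, at which point the method reports an error rather
than a distance — by design, since the statistic is undefined without
comparable orthologs.
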