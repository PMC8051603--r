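---
title: "Detecting and dating paleopolyploidy with wgdkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating paleopolyploidy with wgdkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wgdkit reconstructs the polyploid history of a genome from three signals:
the layout of collinear (syntenic) gene blocks, the synonymous divergence
(Ks) of the duplicated gene pairs inside them, and the way duplicated gene
content has eroded since each duplication. This vignette describes the
models behind each stage, the tunable parameters and their defaults, what
the built-in simulator does and does not emulate, and the design decisions
taken where the methodology was genuinely open.

## Collinearity

Homologous gene pairs (BLAST-like tables) are first cleaned of large
families: a family is a connected component of the pair graph, and every
pair touching a component with more than `max_family_size = 30` genes is
removed. Large families are dominated by tandem arrays and mobile elements
whose anchors carry no positional signal.

Blocks are then chained per chromosome pair with a longest-chain dynamic
programme: anchors in a chain must increase strictly in rank on both
chromosomes (or increase/decrease for antiparallel, i.e. inverted, blocks),
and consecutive anchors may skip at most `max_gap = 50` intervening gene
ranks on either chromosome. The gap is measured on each chromosome
separately and both must pass. Chains are extracted greedily by descending
anchor count, ties broken by the smaller start rank, and the anchors of an
emitted block are removed before re-chaining, so no anchor is used twice.
A block is accepted when it has at least `min_anchors = 5` anchors — the
usual convention in the MCScanX family of tools; no statistical
significance model is layered on top, since the gap parameter is the
published constraint and significance would add a second, undocumented
filter.

On instances small enough for exhaustive search, the chain returned by the
dynamic programme is provably maximal (the test suite checks 200 random
instances against a depth-first enumeration oracle).

## Ka/Ks with the Nei–Gojobori counting method

Coding sequence pairs are aligned at the protein level (global alignment,
BLOSUM62) and the alignment is mapped back to codons; gapped codon columns,
codons containing ambiguous bases and terminal stops are removed, and an
internal stop is an error rather than a silent repair.

The estimator is the classic NG86 counting method. Each codon contributes
fractional synonymous sites: every one of its nine possible single-
nucleotide changes is classified synonymous or not, and the synonymous
fraction per position (0, 1/3, 2/3 or 1) is summed over positions and
averaged over the two sequences, so `S + N = 3 x codons` exactly. A change
that would create a stop codon counts as nonsynonymous — this is what keeps
the site identity exact. Codons differing at two or three positions are
scored by averaging the synonymous/nonsynonymous step counts over all
minimal mutation pathways; pathways passing through a stop codon are
excluded and the remaining ones reweighted (if every pathway is excluded,
the observed changes count as nonsynonymous). Proportions are corrected for
multiple hits with the Jukes–Cantor formula
`K = -(3/4) log(1 - (4/3) p)`; `pS >= 3/4` is flagged saturated and `Ks`
left undefined. The implementation is validated against Biopython's NG86
reference implementation to 1e-4 in the test suite, and the
`S = 10, N = 20, Ks ~ 0.1073` ten-codon glycine example is kept as a frozen
worked case.

The per-block statistic is the median anchor Ks (even counts: mean of the
central two); saturated anchors are excluded and counted.

## Ks densities and Gaussian peak models

A Ks distribution is summarised as a Gaussian-kernel density on a 512-point
grid over `[0, ks_ceiling]`, renormalised to unit trapezoid integral.
The ceiling defaults to 2.5: the oldest event of interest in eudicots (the
ancient triplication) sits well below this, and beyond it NG86 estimates
are saturation-dominated noise. The bandwidth defaults to Silverman's rule;
because the curve the original MATLAB workflow smoothed used an unstated
bandwidth, peak *positions* are robust to this choice but curve *shapes*
are not, and the bandwidth is exposed as a parameter.

Peak decomposition fits `sum_i w_i N(x; mu_i, sigma_i)` to the density
curve (not the raw values) by Levenberg–Marquardt least squares, with five
seeded multi-starts per component count plus one start grown from the best
(k−1)-component fit — the latter makes the best-fit R² non-decreasing in k.
The model selected is the smallest k whose coefficient of determination
reaches `r2_min = 0.95`, the standard acceptance rule for this kind of
curve decomposition; if no k reaches it the best fit is returned flagged.
Weights are unconstrained positive and the component sum is not forced to
integrate to one, mirroring interactive curve-fitting practice.

## Shared-event rate correction and dating

Lineages evolve at different synonymous rates, so an event shared by
several species leaves peaks at different Ks. The correction aligns each
lineage's shared-event peak onto a reference — the lineage with the
smallest Ks, i.e. the slowest clock — by the multiplicative factor
`f_s = mu_ref / mu_s`. A second step repeats this within a clade for the
youngest shared duplication (reference: the slowest ingroup lineage) and
composes multiplicatively with step one. For a Ks distribution *between*
two species, the geometric mean of the two lineage factors is applied.
This multiplicative peak-alignment is the simplest scheme consistent with
aligning distributions; order of peaks within a species is preserved by
construction, and re-deriving relative rates after correction returns zero
for every lineage (a self-consistency test).

Corrected peaks convert to ages as `T = Ks / (2r)`. The clock rate `r`
(synonymous substitutions per site per year) has **no default**: published
calibrations differ by a factor of two and silently picking one would bake
an arbitrary timescale into every result, so `date_event()` requires it
explicitly. Relative rates are reported as `(mu_s/mu_ref - 1) x 100`
percent.

## Fractionation statistics

The homology table anchors everything to one reference genome: rows are the
reference genes in chromosome-then-rank order, and each compared genome
gets as many columns as its expected homoeologous multiplicity (2 paralog
columns for a triplicated reference's own duplicates, 3 for a triplicated
genome, 4 for a genome carrying two WGDs — the published table layout's
total column count is not reproducible from its stated per-genome counts,
so the width here is simply the sum of configured multiplicities). All
anchors of one block occupy one column, so a column tracks one
homoeologous copy along the reference and runs of missing cells measure
within-copy fractionation. Blocks are placed into columns in reference-row
order with first-fit: fragments of one copy are disjoint intervals, so this
is interval-graph colouring and uses exactly the local homology depth;
blocks that fit no column (true overflow beyond the multiplicity) are
dropped and counted.

From the table: the **loss rate** is the dot fraction
`dots / (rows x multiplicity)`; the **homology depth** per reference gene
is its non-dot cell count (the modal depth recovers the 1:2/1:4-style
homology ratios); the **translocated fraction** is the share of best-hit
target genes absent from every column. **Deletion runs** are maximal dot
stretches strictly bordered by retained genes on the same reference
chromosome; runs touching a chromosome end are counted separately and
excluded, since their length is censored. Run lengths are fitted by the
geometric model `P(L = k) = (1 - p) p^(k-1)` with extension parameter `p`
(the probability a run grows by one more gene); the MLE is the closed form
`p = 1 - 1/mean(L)`, cross-checked against grid-search likelihood
maximisation in the tests. Both run-based counts and gene-based fractions
(share of run genes in runs of length ≤ 2) are emitted, because published
summaries of this kind mix the two conventions.

## Karyotype event algebra

Chromosomes are ordered lists of oriented ancestral segments with spans in
ancestral gene-rank units (breakpoints in event scripts are cumulative
positions in those units — the published trajectories draw breakpoints
pictorially, so gene-rank resolution is the natural discretisation).
Events: `WGT`/`WGD` replicate every non-satellite chromosome with
`a/b(/c)` suffixes; `X` exchanges distal arms at two breakpoints; `EJ`
joins two chromosomes end to end; `NCF` inserts one chromosome into
another; `INV` reverses a segment range; `LOSS` removes a satellite;
`REN` relabels. EJ and NCF each emit a gene-free, telomere-derived
satellite whose subsequent loss is what reduces the chromosome number —
satellites are excluded from chromosome counts. Every event conserves the
segment-content multiset except satellite loss (which, satellites being
gene-free, conserves gene content too); the test suite asserts this on
random event sequences.

The packaged trajectory script replays the eudicot-to-Apiaceae history:
7 proto-chromosomes triple to 21, fuse to 8 before the older WGD, double
to 16 and reduce to 10 before the younger WGD, then double to 20 and
reduce to 11. The node counts and the named A5+A1+A2 fusion follow the
published trajectory; the remaining breakpoints are illustrative, which the
file header states. The replay engine validates the script rather than
inferring it — automated trajectory search is out of scope.

Fusion timing is inferred by parsimony from homology co-occurrence: with
two WGDs after a candidate fusion, the fused ancestral combination should
appear on 4 extant chromosomes; between the WGDs, 2; after both, 1. Other
counts are flagged ambiguous, and the expected counts generalise to the
running product of the configured ploidy series. Candidate combinations
are the observed per-chromosome reference sets, counted by superset
containment (a chromosome showing {A, B, C} also exhibits {A, B}).

## Subgenomes and expression bias

For a genome with homology multiplicity 4, the four columns per reference
chromosome are labelled A1–A4 by descending retained-gene count (ties by
the dominant target chromosome name, so labels are reproducible).
Expression bias between duplicate copies uses the mean-FPKM log2 ratio per
condition plus a Welch t-test on log2(FPKM + 1) replicate values,
Benjamini–Hochberg adjusted across all pair x condition comparisons; a copy
is called biased only when `|log2FC| > 1` **and** adjusted `p < 0.05`,
mirroring common differential-expression cut-offs. The published analysis
names no test, so Welch-on-logs is adopted as the closest defensible
analogue without a count model; the pseudocount (default 1) is
configurable. Swapping the pair order swaps higher/lower labels exactly,
and under a null simulation the flagged fraction stays below the nominal
level (BH under the complete null is conservative).

## The simulator

`simulate_dataset()` evolves species from a common ancestor through a
configured event timeline (oldest first): WGT/WGD events duplicate gene
orders; each duplicated copy then loses genes in geometric-length runs
(extension parameter `fractionation_p`, default 0.6 — in the range
recovered from real homology tables) until a per-event retention target;
rearrangement scripts (the same DSL as the karyotype module) reshape
chromosomes; and a configurable fraction of genes is transposed to random
positions. Homolog-pair files contain all true pairs plus 5% spurious
pairs to stress the chaining filter. Everything is reproducible from the
mandatory seed, and the truth record traces every emitted gene to its
ancestral gene, every pair to its event of origin and model dS, and every
deletion to its run.

Sequence evolution is deliberately minimal: ancestral codons are drawn
from 4-fold degenerate codon families and substitutions are synonymous
only, Poisson per synonymous site at rate `r x multiplier`, so synonymous
divergence follows the Jukes–Cantor model exactly and the NG86 estimator
can be calibrated against the configured dS without a full codon
substitution model. Rate multipliers are whole-lineage properties: each
species' sequences evolve independently from the root ancestor at its own
multiplier, which is exactly the model the shared-event correction assumes.
The price is that *inter*-species sequence divergence is anchored at the
root rather than at the speciation time; inter-species Ks peaks are
therefore not meaningful in simulated data (the truth record carries the
model values), and no conclusion about them is drawn from passing tests.
Other things the simulator does not emulate: nonsynonymous change and
selection, tandem duplication, biased fractionation between subgenomes
(a bias knob exists but defaults off, since observed gene loss is close to
random), transposable elements, and assembly artefacts. Tests passing on
simulated data show the pipeline recovers its own model's parameters, not
that real genomes satisfy the model.

The default multi-species scenario (`paper_like_config()`) places a
triplication at 130 Mya and two WGDs at 70 and 36 Mya with whole-lineage
rate multipliers 1.0, 1.143 and 1.27 for the three ingroup lineages and a
slower outgroup, at clock rate 4.8e-9 subs/site/year — the event geometry
and rate spread of the Apiaceae analyses this package is patterned on.

## Numerical choices and problem sizes

Optimiser determinism comes from seeding the multi-start jitter (seed
parameter, default 1). Degenerate inputs are handled explicitly: KDE needs
at least 10 usable values; a block with no unsaturated anchor has undefined
median Ks (warning, not silent zero); an all-dot column has zero bordered
runs and one censored end-run; a zero-variance expression pair is called
by its means alone. Tie-breaks are always lexicographic or
smallest-start-rank so that every output is reproducible.

The shipped tests and the acceptance script run on deliberately desk-scale
problems — ancestors of 2 chromosomes x 150–400 genes, 100–250 codons per
gene, 1000-run histograms, 1000 expression pairs — chosen so each
statistical recovery claim has adequate power (peak means to ~0.01, rates
to a few percent, proportions to ~0.01) while the whole suite stays fast.
Genome-scale figures from real assemblies (tens of thousands of genes) are
structurally comparable but not reproduced at this scale.

## Known limitations

* NG86 ignores transition/transversion bias and codon frequencies; for
  real data with strong bias, Ks is underestimated relative to
  maximum-likelihood estimators (YN00/GY94 are out of scope by design).
* The rate correction is multiplicative peak alignment; it cannot capture
  rate changes *within* a lineage's history.
* Dating inherits all the uncertainty of the clock rate, which is why none
  is defaulted.
* The homology-table column assignment is greedy first-fit; pathological
  fragment interleavings beyond the declared multiplicity are dropped
  (logged) rather than re-optimised.
* The merge-timing rule assumes no secondary loss of whole homoeologous
  regions; heavily fractionated combinations can fall below the expected
  co-occurrence count and come out "ambiguous".
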