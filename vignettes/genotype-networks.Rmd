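---
title: "Genotype networks, epistasis and mutational accessibility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype networks, epistasis and mutational accessibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinet)
```

## The model

`epinet` analyzes the genotype–phenotype relationship of a quantitative
trait through a *genotype network*. The inputs are three tables: an
accession-by-locus matrix of single nucleotide characters (biallelic loci
only; multiallelic loci are rejected at load), a per-locus association
P-value for the trait, and a per-accession phenotype value. Given a P-value
cutoff, the alleles at all loci passing the cutoff are concatenated — in
ascending order of the (opaque) genomic locus label, identically for every
accession — into one aligned haplotype string per phenotyped accession.
Identical strings collapse into a single vertex whose phenotype is the
arithmetic mean over its member accessions; edges join vertices whose
strings differ at exactly one position. Vertices with no one-mutant
neighbor are recorded as isolates and excluded from graph statistics, so
every analyzed component has at least two vertices.

### Choosing the cutoff

String length trades off against connectivity: permissive cutoffs give
long, mostly unconnectable strings, stringent cutoffs collapse everything
into a handful of vertices. `sweep_cutoffs()` builds one network per grid
point (default −log₁₀ P ∈ {4.0, 4.5, …, 9.0}; the half-log grid matches the
±0.5 log-unit sensitivity step it exposes) and selects the cutoff whose
network has the largest per-component square count, because squares are the
unit of the epistasis analysis. Ties go to the larger largest component and
then to the more stringent cutoff — the two optima can disagree, and the
square count is the criterion that matters downstream; the stringent-side
tie-break is this package's own convention. Optional pre-filters: a
minor-allele-frequency filter (strictly-below-threshold loci are dropped; a
locus at exactly the threshold is retained) and a greedy LD pruner that
keeps the smallest-P representative of every cluster of loci with allelic
r² at or above a threshold. The pruner is a declared stand-in, not a
reconstruction of any specific published LD workflow, and both its
threshold and its use are configuration choices.

### The noise threshold δ

Phenotypes of accessions that are genetically identical at every
trait-associated locus still vary (measurement error,
micro-environment). For every vertex with at least three member
accessions, the coefficient of variation (sample SD with *n*−1 denominator,
divided by the mean) of the member phenotypes is computed; δ is the
unweighted mean of these CVs, and the contributing fraction of vertices is
reported. Two design points deserve emphasis:

* δ is dimensionless but is compared *directly* with absolute phenotype
  differences, which is the literal reading of the procedure this package
  implements. For phenotypes whose scale is far from 1 this makes δ a very
  small (or very large) threshold in phenotype units; `scale_delta()`
  exposes a mean-phenotype-scaled variant for sensitivity analyses, but the
  literal comparison is the default.
* Vertices with mean 0 have an undefined CV and are excluded with a
  warning. If no vertex qualifies, δ is unavailable and every δ-dependent
  analysis for that phenotype is skipped with a recorded reason rather than
  silently defaulted.

### Epistasis from squares

A square is a four-cycle `ab – Ab – AB – aB`: a focal genotype, two of its
one-mutant neighbors, and the corresponding double mutant. Squares are
enumerated exactly once each (orientation-free), including squares with
chords. By convention the vertex with the highest phenotype is labelled
`AB`; if that maximum is tied within the square (exact equality of
collapsed means — δ plays no role in this skip rule), the square is skipped
and tallied. `ab` is the vertex diagonal to `AB`; the labelling of the two
single mutants between themselves is arbitrary and provably does not affect
the result. The interaction strength is

$$\varepsilon = V_{AB} + V_{ab} - V_{Ab} - V_{aB},$$

and the additive expectation is the special case ε = 0. Classification:

* |ε| ≤ δ → **none** (ε is reported as zero: a conservative call).
* Otherwise, each mutation is tested for a sign change across backgrounds.
  Mutation A takes the steps `ab→Ab` and `aB→AB`; mutation B takes `ab→aB`
  and `Ab→AB`. A step whose |ΔV| ≤ δ has indeterminate sign and never
  counts as a change — again the conservative direction. Two sign changes →
  **reciprocal sign**; exactly one → **simple sign**; none → **magnitude**.

The boundary is |ε| ≤ δ, not a strict inequality: epistasis is called only
when |ε| *exceeds* δ. This matters exactly once — for noiseless additive
landscapes, where ε = 0 and δ = 0 must still classify as non-epistatic —
and is invisible for noisy data, where ties have probability zero. For the
same reason the threshold never drops below machine roundoff
(√ε_mach × the value scale): an exactly additive square built from effect
sizes like 1.2 that are not binary-representable would otherwise carry
|ε| ≈ 2×10⁻¹⁶ and misclassify at δ = 0.

Network-level tallies report counts and fractions per class, the skipped
squares, an "all epistatic" flag, and a not-analyzable status for networks
without squares. Only pairwise interactions are considered; higher-order
epistasis is out of scope.

### Accessibility of phenotypic extrema

Within the analyzed component (the largest, since all path statistics are
intra-component), the vertex with the strictly largest (or smallest) mean
phenotype is the target; a tied extremum makes the analysis ambiguous and
it is skipped with a record. For every other vertex, *all* equal-length
shortest paths to the target are enumerated (their count is verified
against a breadth-first geodesic count before materialization, and a
configurable cap — default 10⁶ paths — aborts loudly rather than sampling
silently). A path toward the maximum is accessible when every step
satisfies V_next − V_prev ≥ −δ: the direct composition of "monotonically
increases" with "values within δ are identical". δ-tolerated flat or
slightly dipping steps are allowed anywhere along the path, including the
final step into the extremum; a strict mode (every step must climb by more
than δ) is exposed for sensitivity. Reports give the per-source table, the
global accessible fraction, the mean path length, and accessible fractions
binned by path length ([1,2), [2,3), …). The same machinery with
`path_length_distribution()` yields the all-pairs path-length histogram.
Increasing δ can only open paths, never close them — a property the test
suite checks explicitly.

### Randomization null

The null model randomizes the *uncollapsed* aligned haplotype strings
column by column: each random string draws every position independently
from that column's empirical character distribution, preserving per-locus
allele composition while destroying between-locus associations. Each of
the replicates (default 10,000) is pushed through the same collapse/build
code as the observed data, recording the number of unique genotypes, the
square count, the largest component of size ≥ 2, and the maximum
normalized betweenness. Phenotypes are not permuted — the null concerns
topology only. Observed statistics are located in the null with an add-one
empirical P, P_upper = (1 + #{null ≥ obs}) / (n + 1), which cannot return
zero at finite replicates; the two-sided P is twice the smaller tail,
capped at one.

### Structure and phylogeny

Vertex betweenness is the fraction of all-pairs shortest paths through a
vertex, computed and normalized per component (raw betweenness divided by
(n−1)(n−2)/2). Modules come from Louvain modularity maximization
(resolution 1) on the largest component, made deterministic by seeding;
partitions whose modularity does not exceed zero are flagged as
structureless. The phenotype contrast between the two largest modules uses
a two-sided Wilcoxon rank-sum test, exact for group sizes up to 10 without
ties and normal-approximate with continuity correction otherwise.
Phylogenetic distance between accessions is measured two ways: the number
of internal nodes on the tip-to-tip path of a supplied Newick tree
(bootstrap labels tolerated, branch lengths ignored — a cherry pair is one
node apart), and the Hamming distance between full concatenated genotype
strings. Vertex-pair distances average over all member-accession cross
pairs, and the correlation with shortest-path length uses Kendall's tau-b,
the tie-corrected variant, because path lengths are heavily tied. No
multiple-testing correction is applied across phenotypes; output carries
the raw P.

## The synthetic generator

`simulate_panel()` draws each accession's allele independently per locus
('A' major, 'T' minor, minor with probability MAF — the network layer
treats characters opaquely) and computes the phenotype as baseline +
additive effects over carried minor alleles + interaction effects for
accessions carrying both minor alleles of a pair + Gaussian noise. Each
stochastic stage derives its own RNG stream from the master seed (genotypes
at offset 0, noise at offset 500009), so stages are independently
reproducible. `compute_association_pvalues()` is a two-sided Wilcoxon
rank-sum scan of phenotype by allele — a deliberately simple,
distribution-free stand-in for a mixed-model GWAS; the pipeline only needs
a P-value column with the right qualitative behavior, and no kinship or
structure correction is attempted. `plant_square()` and
`simulate_square_panel()` plant a single square of known class
(templates (0,1,1,2), (0,1,1,3), (0,−1,1,2), (1,0,0,2), scalable), with
accessions assigned round-robin so every planted haplotype has replicate
members for δ estimation; a baseline offset (default 10) keeps vertex
means, and hence CVs, well defined.

What the generator emulates: biallelic loci, realistic allele frequencies,
additive and pairwise-epistatic architectures, accession-level noise,
missing phenotypes. What it does not: linkage disequilibrium, population
structure and kinship confounding, genotyping error, polygenic backgrounds
of many small effects. Passing tests on planted panels therefore
demonstrate that the machinery recovers known architectures through the
whole pipeline — not that any particular biological dataset would yield
the same numbers.

### Preset design

Two pipeline presets define reference conditions. `"additive"`: 400
accessions, four causal loci of equal effect +1, 40 neutral loci,
MAF 0.45, no noise — its networks are 4-cubes whose squares all classify
as non-epistatic and whose shortest paths to the unique maximum are all
accessible. `"reciprocal-heavy"`: 1,000 accessions, two reciprocal-sign
pairs (β = −1 per locus, +4 rescue when both minor alleles of a pair
co-occur), MAF 0.49, noise SD 0.05 on a baseline of 10. The sizes are not
arbitrary: reciprocal sign epistasis intrinsically masks marginal
association signal, because a single mutant's phenotype coincides with
wild-type-side values (the rank-test AUC for a planted locus is ≈ 0.57 at
MAF 0.45 and, since the interaction scales with the additive effects,
growing the effect sizes does not help). Pushing the MAF toward 0.5 breaks
that coincidence and the larger panel gives the rank test enough power
that all four planted loci reliably clear the least stringent cutoff of
the sweep grid. This is a property of the masked-signal biology, not of
the detector: a marginal-effect scan is simply a weak instrument for
reciprocal sign architectures.

## Problem sizes and numerical choices

* Oracle-equivalence tests run 200 seeded random networks (≤ 60 vertices),
  checking edges against all-pairs Hamming comparison, square counts
  against the closed-walk identity C₄ = (tr A⁴ − 2m − 2Σdᵢ(dᵢ−1))/8,
  path sets against exhaustive depth-limited DFS, and betweenness against
  a geodesic-counting dynamic program.
* The classifier truth-table sweep uses 10⁵ random squares with δ drawn
  uniformly over each square's range, against an independent
  coarse-sign-pattern oracle.
* Planted-class recovery uses 400-accession panels at effect scale 20 ×
  noise SD, 100 replicates per class in the test suite (3 × 50 in the
  acceptance script).
* The acceptance script's null uses the full 10,000 replicates; unit and
  pipeline tests use reduced replicate counts (25–600) chosen to keep the
  statistical assertions sharp at test-suite scale.
* Tie-breaks are deterministic everywhere (locus id ordering, stringent
  cutoff preference, seeded Louvain), so a fixed seed reproduces every
  output file byte-identically.

## Known limitations

* The LD pruner is a greedy representative-picker, not a haplotype-aware
  method; with dense LD the retained locus set depends on the P-value
  ordering.
* δ is a single network-wide scalar; heteroskedastic phenotypes (noise
  growing with the mean) would be better served by per-vertex thresholds,
  which the literal procedure does not define.
* Shortest-path enumeration is exact and therefore exponential in the
  worst case; the cap makes this loud, but very square-dense networks of
  hundreds of vertices may require raising it deliberately or sampling
  externally.
* The association stand-in is marginal and uncorrected; its P-values are
  not exchangeable with mixed-model GWAS P-values, only qualitatively
  comparable.
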