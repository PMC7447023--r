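# epinet

Genotype networks, epistasis classification and mutational path
accessibility for quantitative phenotypes.

## The problem

A genome-wide association study (GWAS) of a quantitative trait yields a set
of loci whose alleles are statistically associated with the phenotype. For a
panel of inbred accessions, the alleles at those loci can be concatenated
into one short haplotype string per accession. `epinet` represents these
strings as a **genotype network**: each unique string is a vertex carrying
the mean phenotype of the accessions that share it, and two vertices are
joined by an edge when their strings differ at exactly one nucleotide. This
graph is an empirical sample of the trait's genotype–phenotype landscape,
and two of its local structures carry the biology:

* **Squares** (four-cycles `ab – Ab – AB – aB`) are the natural unit for
  pairwise epistasis. Orienting each square so that the double mutant `AB`
  is its unique phenotypic maximum, the interaction strength is

  ε = V_AB + V_ab − V_Ab − V_aB.

  Against a noise threshold δ — the mean coefficient of variation of
  phenotypes among accessions sharing a haplotype, estimated from vertices
  with at least three member accessions — each square is classified as
  **none** (|ε| ≤ δ), **magnitude**, **simple sign** (exactly one mutation
  reverses the sign of its effect across backgrounds), or **reciprocal
  sign** epistasis (both do, i.e. both single mutants sit below the wild
  type).

* **Accessible paths** quantify evolvability: a shortest mutational path to
  the network's unique phenotypic maximum (or minimum) is accessible when
  the phenotype never moves against the chosen direction by more than δ at
  any step. Sign epistasis — reciprocal sign in particular — is what closes
  such paths.

The package also provides column-composition randomization null models for
the network statistics, network-structure descriptors (normalized vertex
betweenness, Louvain modules with a rank-sum phenotype contrast between
them), phylogenetic tip distances (internal-node counts and nucleotide
differences) correlated against mutational path lengths, and a synthetic
GWAS-panel generator with planted additive and epistatic architectures that
gives every stage a known ground truth.

## Worked example

The `"reciprocal-heavy"` preset simulates 1,000 accessions genotyped at 44
biallelic loci, four of which form two reciprocal-sign pairs (additive
effect −1 per minor allele, rescued by a +4 interaction when both minor
alleles of a pair co-occur), with accession-level noise. The pipeline scans
association P-value cutoffs over 10⁻⁴…10⁻⁹, keeps the network whose
component is richest in squares, estimates δ, classifies every square and
enumerates every shortest path to the phenotypic maximum:

```r
library(epinet)
cfg <- pipeline_config(out_dir = "demo_run", simulate = "reciprocal-heavy",
                       null_reps = 200, seed = 1)
res <- run_pipeline(cfg)
res$network
#> <haplo_network> 16 unique genotypes (16 in analysis network, 0 isolates), 32 edges, 1 component(s), largest 16
res$delta
#> <noise_estimate> delta = 0.00508687 from 16 vertices (100.0% of genotypes)
res$epistasis
#> <epistasis_summary> 24 squares classified (delta = 0.005087), 0 skipped (tied max)
#>   none               8  (0.333)
#>   magnitude          8  (0.333)
#>   simple_sign        0  (0.000)
#>   reciprocal_sign    8  (0.333)
#>   epistatic fraction 0.667
res$accessibility$max
#> <accessibility_report> direction=max extremum=TTTT: 64 shortest paths, 0.188 accessible, mean length 3.06
```

Reading these numbers: the four causal loci survive the cutoff sweep, so the
16 possible four-locus haplotypes form a 4-dimensional hypercube (32 edges,
24 squares). The 8 squares that vary one of the two planted pairs are
recovered as reciprocal sign epistasis; squares mixing loci from different
pairs are additive up to noise. Because every path from the all-major
haplotype to the all-minor maximum must cross both fitness valleys, only
12/64 (18.8%) of shortest paths to the maximum are monotonically
accessible — against 100% for the `"additive"` preset, whose squares all
classify as non-epistatic.

The run directory contains one TSV per stage (`sweep.tsv`, `vertices.tsv`,
`epistasis_squares.tsv`, `accessibility_max.tsv` and its bins,
`null_summary.tsv`, `structure_vertices.tsv`, `summary.tsv`), a GraphML
export with betweenness/module vertex attributes, and `manifest.json`
recording config, derived stage seeds and any skipped analyses. Identical
seeds reproduce all outputs byte-identically.

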