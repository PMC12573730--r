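# invtad

Chromosomal inversions can suppress recombination between diverging
populations and thereby act as barriers to gene flow; independently, the
3D folding of chromosomes partitions genomes into topologically
associating domains (TADs) and A/B compartments. `invtad` is an R
package for asking, in one reproducible pipeline, how these two
observations connect in a pair of hybridising fish species (or any
similar two-species system with whole-genome alignments, population
resequencing and Hi-C):

1. **Do inversions behave as barriers to gene flow?** Windowed
   Weir–Cockerham F_ST and d_xy are computed separately for inverted and
   colinear regions of the genome, compared with the Brunner–Munzel rank
   test, and the ABBA–BABA D statistic (with block-jackknife Z scores)
   quantifies introgression per region class.
2. **Do inversion breakpoints coincide with 3D-structure boundaries?**
   A/B compartments are derived from KR-balanced contact matrices (sign
   of the leading eigenvector of the Pearson correlation matrix of the
   observed/expected matrix, oriented by GC content), TAD boundary sets
   are extracted from hierarchy-resolved TAD tables, and the distance
   from every inversion breakpoint to the nearest boundary is compared
   with an analytic random-placement expectation plus a permutation
   null.

The package is aimed at population genomicists who have: a
structural-variant VCF from a whole-genome aligner (IDs `INV<n>` for
inversions, `SYNAL<n>` for syntenic blocks), an all-sites genotype VCF
for four population groups (P1 allopatric, P2/P3 sympatric pair,
outgroup), binned Hi-C contact matrices, a TAD table, a GC track, gene
intervals and expression counts. A first-class synthetic-data generator
emulates all of these inputs with known ground truth, so every stage of
the pipeline is testable without the (large) real data.

## The statistics at the core

* **Weir–Cockerham F_ST (1984), two populations**: per-SNP variance
  components a, b, c from sample sizes, allele frequencies and observed
  heterozygosity; a window's value is Σa / Σ(a+b+c) (ratio of sums).
  Windows need ≥ 25 genotyped SNPs.
* **d_xy**: Σ over sites of between-group allele mismatches
  c₁(n₂−c₂) + (n₁−c₁)c₂ divided by Σ n₁n₂, over *all* genotyped sites —
  invariant sites count in the denominator, so an all-sites input is
  required. Windows need ≥ 2500 sites.
* **ABBA–BABA**: with derived-allele frequencies p₁..p₄,
  ABBA = (1−p₁)p₂p₃(1−p₄), BABA = p₁(1−p₂)p₃(1−p₄),
  D = Σ(ABBA−BABA)/Σ(ABBA+BABA); Z from a weighted delete-one block
  jackknife over contiguous SNP blocks.
* **Breakpoint–boundary enrichment**: observed fraction of breakpoints
  within one bin (25 kbp) of the nearest boundary versus the analytic
  expectation |∪ᵦ[b−r, b+r] ∩ allowed| / |allowed|, tested with a df-1
  chi-square and a uniform-placement permutation p-value.

## Worked example

```r
library(invtad)

cfg <- pipeline_config(
  simulate = list(n_chromosomes = 2, chrom_length = 6e6,
                  invariant_per_window = 0),
  seed = 701, n_perm = 199, outdir = tempfile())
res <- cmd_all(cfg)
res$enrichment[res$enrichment$frame == "ref" &
               res$enrichment$inversion_set == "gt_25kb",
               c("boundary_kind", "n", "k",
                 "observed_fraction", "expected_fraction", "perm_p")]
```

```
   boundary_kind  n  k observed_fraction expected_fraction perm_p
2            TAD 32 17           0.53125         0.2770833   0.01
4 AB_compartment 32  6           0.18750         0.1000000   0.11
```

17 of 32 large-inversion breakpoints (53.1%) fall within 25 kbp of a
TAD boundary against a 27.7% random expectation (permutation p =
0.01): the generator planted breakpoint–boundary association
(`beta = 0.5`) and the pipeline recovers it, while the compartment
cell stays near its null. The same run's text report
(`report.txt`) shows the companion popgen pattern — mean window F_ST
0.80 inside inversions vs 0.25 outside, and D = 0.035 (Z = 8.1) in
colinear regions vs D = −0.019 (Z = −1.1) inside inversions — i.e.
gene flow confined to colinear sequence.

The command-line wrapper does the same from a YAML config:

```sh
Rscript inst/cli/invtad.R all --config config.yaml --seed 7 --outdir out/
```

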