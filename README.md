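# famscan

Genome-wide characterization of plant UDP-glycosyltransferase (UGT) gene
families, as a tidyverse-style R package.

Plant UGTs (glycosyltransferase family 1) share a conserved 44-residue
C-terminal motif, the **PSPG box** (plant secondary product
glycosyltransferase box), which binds the UDP-sugar donor. Family surveys
in a new genome follow a standard recipe: confirm candidate proteins by
the PSPG box, compute protein statistics (length, average molecular
weight, isoelectric point), read exon–intron structure off the gene
models, number homologous intron **insertion events** by projecting each
intron's protein position through the family alignment (introns at the
same alignment column with the same codon **phase** — 0, 1 or 2 bases
into a codon — are one event, `I-1 … I-K`), cluster the family into
phylogenetic groups (A–P) with a neighbor-joining tree, and profile
expression as RPKM across tissues and developmental stages. `famscan`
implements every step as a composable, tested function, plus a seeded
simulator that generates whole synthetic families with planted ground
truth so the full pipeline can be validated end to end.

## The core computations

* **Motif scan** — a 44-column position-specific log-odds model built
  from a seed alignment, `log2(((n_ca + p·b_a)/(N + p))/b_a)` per column
  `c` and residue `a`; a protein is a family member when its best window
  in the last 150 residues reaches 60 % of the model's consensus score.
* **Protein statistics** — average molecular weight (residue masses +
  one water) and isoelectric point by bisection on the net-charge
  function under the Bjellqvist pKa set.
* **Intron phases** — an intron after `k` coding nucleotides has phase
  `k mod 3` and sits at protein residue `ceil((k+1)/3)` (phase 1/2) or
  `k/3` (phase 0); residues are projected to alignment columns to define
  insertion events.
* **Phylogeny** — uncorrected p-distances on pairwise-complete columns,
  classic neighbor joining (`Q(i,j) = (n−2)d(i,j) − R_i − R_j`) with
  deterministic tie-breaking, group assignment by nearest labeled
  reference in patristic distance.
* **Expression** — `RPKM = reads × 10^9 / (length_bp × library size)`,
  detection at ≥ 1 RPKM per tissue for the four-tissue Venn partition,
  per-gene z-scores clustered by average linkage on 1 − Pearson
  correlation for heatmap ordering, and peak-sample summaries.

## Worked example

Simulate a benchmark family (16 groups, ~120 genes, 10 planted intron
insertion events), then run the stages:

```r
library(famscan)
library(dplyr)

sim <- simulate_family(simulation_config(seed = 42))
sim
#> simulated family: 119 genes in 16 groups; 204 introns across 10 events

model <- build_pspg_model(sim$pspg_seeds)
model
#> PSPG-box log-odds model (44 columns, 12 seeds)
#> consensus score: 180.08 bits; hit threshold: 108.05 bits

identify_family(sim$proteins, model) |>
  select(protein_id, motif_start, motif_score, length, mw, pi) |>
  head(4)
#> # A tibble: 4 × 6
#>   protein_id motif_start motif_score length     mw    pi
#>   <chr>            <int>       <dbl>  <int>  <dbl> <dbl>
#> 1 gA01               383        164.    460 54163.  7.07
#> 2 gA02               390        164.    467 55409.  7.74
#> 3 gA03               387        164.    464 54805.  7.07
#> 4 gA04               387        164.    464 54824.  6.60

counts <- simulate_expression(sim)
vp <- venn_partition(rpkm_matrix(counts), threshold = 1)
tidy(vp) |> filter(n_genes > 0) |> head(6)
#> # A tibble: 6 × 2
#>   region               n_genes
#> 1 flavedo                    7
#> 2 albedo                     3
#> 3 SM                         5
#> 4 JS                         3
#> 5 flavedo+albedo+SM+JS      95
#> 6 none                       6
```

Every protein carries the planted motif near its C-terminus
(`motif_start` ≈ 385 of ~460 residues) with ~54 kDa predicted mass; most
genes are detected in all four fruit tissues (flavedo, albedo, segment
membrane, juice sacs) while the planted tissue-specific genes fall in
their single-tissue Venn regions and silent genes in `none`.

`run_pipeline()` chains all stages from files on disk
(FASTA/GFF3/TSV in, TSV/newick reports out); `write_simulation()` emits
a complete input bundle from a simulation. Result objects support
`tidy()`, `glance()` and `autoplot()`.

The package also ships the published intron-count distribution of the
pomelo UGT family (`ugt_intron_distribution()`);
`summarize_intron_distribution()` recomputes its marginals — 145 genes,
70 without introns, 75 with, 96 introns in total.

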