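---
title: "Methods: family identification, intron events, phylogeny and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family identification, intron events, phylogeny and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`famscan` characterizes a plant UDP-glycosyltransferase (UGT) gene
family genome-wide: membership by the 44-residue PSPG box, protein
statistics, intron phases and insertion events, neighbor-joining
phylogeny with group labels, and RPKM expression profiles. This
vignette documents the models behind each stage, the parameters that
matter, the numerical conventions, and what the synthetic benchmark
does and does not demonstrate.

## Membership by motif: the PSPG scoring model

Membership is decided by a single criterion: presence of the PSPG box
near the C-terminus. A gap-free alignment of 44-residue seed motifs is
turned into a position-specific log-odds matrix in bits,

$$S_{c,a} = \log_2 \frac{(n_{c,a} + p\,b_a)/(N + p)}{b_a},$$

with per-column residue counts $n_{c,a}$, pseudocount mass $p$
(default 1), and background frequencies $b_a$ (default uniform 1/20 —
protein-wide composition priors change little at this motif length and
uniform keeps the model free of dataset-specific tuning). A candidate
protein is scanned with a sliding 44-residue window over its last
`c_term_window = 150` residues; this window operationalizes "at the
C-terminus" while leaving room for the short tail that typically
follows the motif. The best window is a hit when its score reaches
`min_score`, by default 60 % of the model's own consensus score (the
column-maxima sum). Anchoring the threshold to the consensus makes it
adapt to the information content of whatever seed set is supplied; 60 %
sits far above what shuffled sequences attain (the test suite bounds
the false-positive rate at ≤ 1 % on 1000 composition-matched shuffles)
while tolerating substantial motif divergence. Ties between equal-score
windows go to the most C-terminal start. Non-standard residues score 0
(background odds). Proteins shorter than 44 residues yield no hit
rather than an error.

## Protein statistics

Molecular weight is the sum of average (not monoisotopic) residue
masses plus one water, matching the kDa-scale values protein-survey
tables report; `X` contributes the mean residue mass. The isoelectric
point solves net charge = 0 with the charge model
$$Q(\mathrm{pH}) = \sum_{\text{basic } i} \frac{n_i}{1 + 10^{\mathrm{pH} - pK_i}}
 - \sum_{\text{acidic } j} \frac{n_j}{1 + 10^{pK_j - \mathrm{pH}}},$$
counting D, E, C, Y side chains, H, K, R side chains and both termini
under the Bjellqvist pKa set (the set behind the classic ExPASy tool;
an EMBOSS set is selectable). $Q$ is strictly decreasing in pH, so
bisection on [0, 14] converges to the unique root; iteration continues
to a pH interval of 1e-7, after which the residual charge is verified
against the documented tolerance (1e-4 charge units). The tests compare
the bisection against an independent 1e-4-resolution grid search to
within 2e-4 pH.

## Introns: phases, alignment projection, insertion events

Gene models are CDS-only (introns within the coding region; UTR exons
are out of scope, consistent with the phase definitions below). All
coordinates are GFF3 convention, 1-based inclusive, kept in genome
orientation; transcript orientation is applied only when introns are
extracted (the segment list is walked right-to-left on the minus
strand). For an intron after $k$ coding nucleotides: phase $= k \bmod
3$ (0 between codons, 1 and 2 inside one), and the associated protein
residue is the codon containing the splice (phases 1–2) or immediately
preceding it (phase 0), i.e. $\lceil (k+1)/3 \rceil$ and $k/3$
respectively. Residues are projected to 1-based alignment columns by
counting non-gap characters.

Two introns belong to the same insertion event when their columns
differ by at most `tolerance` (default 0) *and* their phases are equal,
with single linkage inside that rule. Requiring equal phase encodes the
biological expectation that conserved introns keep their phase; a phase
shift implies an independent insertion. The tolerance default of 0 is
the strict choice appropriate for a trusted alignment; small positive
values absorb alignment jitter. Under tolerance > 0 a chain could claim
two introns of one gene; since one gene cannot carry one insertion
twice, such chains are split greedily in column order so that no event
contains two introns of a single gene. Events are ordered by median
column and labeled `I-1 … I-K`. Summary tables use the observed
distinct intron counts as classes (e.g. 0/1/2/3/8), mirroring how
family surveys print them.

## Phylogeny and group labels

Distances are uncorrected p-distances over pairwise-complete columns —
the minimal defensible choice when no substitution model is specified —
with a Poisson correction behind a flag; pairs sharing fewer than
`min_overlap = 30` columns are an error rather than a meaningless
number. Neighbor joining follows the classic agglomeration: join the
pair minimizing $Q(i,j) = (n-2)d_{ij} - R_i - R_j$, pendant lengths by
the two-point formulas, distances to the new node by
$(d_{ik}+d_{jk}-d_{ij})/2$. Ties in $Q$ break on the smallest index
pair under the current node ordering, so results are deterministic;
the unrooted result is stored rooted at the final join. Negative
pendant branches (possible on non-additive input) are clipped to zero
with the deficit moved to the sibling, the common display
normalization, disablable by flag. On additive matrices the
implementation recovers the generating tree exactly (topology and
branch lengths); the tests verify this on 200 random 4–12 leaf trees
and cross-check the topology against an independent implementation.

Group labels are read off proximity rather than clade monophyly: each
leaf takes the group of the nearest labeled reference in patristic
distance, ties going to the lexicographically smallest group label.
Published group structure ultimately comes from a drawn tree figure;
nearest-reference is the deterministic, testable surrogate, and it
degrades predictably — when a group's reference is absent its members
attach to the nearest remaining group instead of failing.

## Expression

RPKM uses the coding length in bp and the per-sample mapped-read total.
The analyzed matrix has one column per sample (replicate averaging, if
any, happens upstream). A gene is *detected* in a tissue when its
maximum RPKM across that tissue's stages reaches `threshold = 1`, a
conventional detection floor; the threshold is a flag because
"expressed" has no universal definition. The four-tissue Venn partition
assigns every gene to exactly one of the 15 tissue subsets or the
undetected class, so counts always conserve the gene total.

Heatmap ordering standardizes each gene to mean 0 and unit $(n-1)$
standard deviation (constant profiles become zero rows), then clusters
genes by average linkage on $1 -$ Pearson correlation, the default of
the classic expression-heatmap tools; Euclidean distance on z-scores is
available by flag. Degenerate rows get deterministic distances (1 to
any non-constant profile, 0 among themselves). Leaf order comes from a
deterministic dendrogram traversal — at each merge the subtree holding
the earlier input row leads — so reruns and row permutations give
reproducible orderings. The [−2, 2] display clip is plot metadata only;
stored z-scores are never clipped. Peak summaries take the per-gene
argmax sample with ties broken in the fixed sample order (flavedo <
albedo < SM < JS, stages 80 < 140 < 200 DAB); all-zero genes form a
separate no-peak class excluded from aggregates.

## The simulator: what it emulates, and what it does not

`simulate_family()` generates the study conditions the analysis
assumes: a two-level family (group ancestors evolved from a
motif-carrying root, genes from their ancestor) with substitutions and
indels applied in alignment space, so the true MSA exists by
construction. Defaults describe a UGT-like family: 16 groups of 5–10
genes (~120 total), a 459-residue root (the family's average protein
length) with the PSPG consensus ending 31 residues before the
C-terminus, 0.35 expected substitutions/site on group branches and 0.05
within groups, and a 20-fold reduced substitution rate inside the motif
(the PSPG box is the family's conserved core; indels avoid it
entirely). Ten insertion events are planted at fixed root positions
with fixed phases — predominantly phase 1 with a few phase 0 and one
phase 2, echoing the phase spectrum of real plant UGT families — and
carrier-group sets of varying breadth, one event being near-universal
like the deeply conserved intron real surveys find. Proteins are
back-translated with one fixed codon per residue (phases depend only on
codon boundaries), split at the planted splice sites, and placed on 9
chromosomes plus a small `chrUn` fraction (4 %), both strands,
intergenic spacers uniform in 500–2000 bp — deliberately compact, since
spacer length carries no signal for any stage. Expression plants three
classes (12 % tissue-specific, 4 % silent, the rest ubiquitous) with a
flavedo-biased peak-tissue distribution (49 %, stages 41/32/27 % within
flavedo) in RPKM space, converted to negative-binomial counts
(dispersion 8) through each gene's length and a per-sample library size
drawn from 8–12 million reads.

What the simulator does *not* emulate: alignment error (the true MSA is
supplied, so event recovery at tolerance 0 demonstrates the clustering
logic, not robustness to a realignment); rate heterogeneity beyond the
motif/non-motif split; codon-usage or splice-site realism; gene
conversion or horizontal transfer; replicate-level count noise or
batch effects. Passing the benchmark therefore shows the pipeline's
bookkeeping and inference are correct under its stated assumptions, not
that those assumptions hold for any particular real genome.

Benchmark problem sizes — ~120 genes, ~600 alignment columns, 12
samples — were chosen so the end-to-end run completes in seconds and
the full test suite in about a minute, while still exercising every
code path at family scale.

## Degenerate inputs and other conventions

Duplicate FASTA ids, `.` gaps, overlapping or touching CDS segments,
counts that are negative or non-integer, zero lengths or library
sizes, references missing from the tree, and saturated pairs under the
Poisson correction are all hard errors with named culprits. Proteins
shorter than the motif, single-segment genes, empty intron sets and
all-zero expression rows are valid inputs with defined results. The
published pomelo UGT intron-count distribution ships as plain text for
the marginal-arithmetic checks; the simulator provides everything else
programmatically, so the package contains no binary data.

## Known limitations

Group assignment ignores clade support (no bootstrap); the NJ tree is a
point estimate. p-distance underestimates divergence for distant pairs
unless the Poisson flag is set. The Venn partition's published
single-tissue counts depend on an unstated detection threshold, so only
the partition mechanics — conservation and threshold monotonicity — are
verifiable. RPKM is the profile statistic by design; no cross-sample
normalization (TPM/TMM) or differential testing is included.
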