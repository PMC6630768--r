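# darkproteome

Residue-level mapping and statistical analysis of the **dark proteome** —
the part of protein sequence space for which no 3D structure has been
observed experimentally or inferred by homology modelling. The package is
aimed at structural bioinformaticians who have per-residue structural
coverage for a set of proteins (from sequence-to-structure alignments or
from PDB cross-references in UniProt records) and want to quantify how much
of a proteome is still "in the dark", what distinguishes dark proteins
functionally, and where dark genes and dark tissues concentrate.

## The statistics at its core

**Darkness.** A residue is *non-dark* if it is covered by a structural
alignment interval under criterion A (aligned onto the ATOM record of a
matched structure) or criterion B (aligned onto a PDB entry cross-referenced
in the protein's UniProt record); all other residues are dark. Per protein,
the darkness score is

> D = (number of dark residues) / (protein length),

with D = 0 a *white* (PDB) protein, D = 1 a *dark* protein, and 0 < D < 1 a
*grey* protein containing dark regions. A proteome is partitioned on a
residue basis into dark-protein residues, dark regions and grey regions of
grey proteins, and white-protein (PDB) residues; the four percentages sum to
100 and *total darkness* is the sum of the first two.

**Annotation enrichment.** For every distinct description (DE) or sequence
feature (FT) annotation, a 2×2 presence/absence table of dark versus
non-dark proteins is tested with the two-sided Fisher exact test, and
p-values are adjusted by the Benjamini–Hochberg step-up
p_adj(k) = min(1, min_{j≥k} p_(j)·n/j) separately within the DE and FT
families; annotations with adjusted p ≤ α (default 1%) are reported with
the sample odds ratio and direction, and can be exported as significance
treemaps with cell area −log10(adjusted p).

**Autonomy.** With m(N) the number of interaction partners with combined
confidence score (STRING scale 0–999) strictly greater than N, a protein's
autonomy is 1 when m(0) = 0, 0 when m(900) ≠ 0, and otherwise
1 − N\*/1000 with N\* the smallest N at which m(N) = 0 (the protein's
maximum incident score).

**Dark gene clusters.** Per chromosome, proteins are ordered by the central
nucleotide of their gene (duplicated proteins keep their first occurrence)
and the longest run of consecutive dark proteins is scored against 1,000
random re-orderings of the labels; p is the fraction of re-orderings with an
equally long or longer run, so the per-chromosome false-positive floor is
1/1000.

**Dark tissues.** For each tissue, missing expression entries are
zero-filled, and the tissue's darkness is the ratio of dark residues among
the residues of the proteins with nonzero normalized intensity; tissues are
ranked by this ratio.

A seeded synthetic-data generator (`simulate_universe()`) emulates all five
input kinds with planted, recoverable structure — class fractions,
annotation odds ratios, interaction degree means, chromosomal dark runs and
tissue darkness targets — so the entire pipeline is testable end-to-end
without any external download.

## Worked example

```r
library(darkproteome)

spec <- universe_spec(n_proteins = 400, seed = 7)
sig <- planted_signals(
  enriched_annotations = data.frame(field = "DE",
    subcategory = "SUBCELLULAR LOCATION", text = "Cell membrane",
    odds_ratio = 8, prevalence_nondark = 0.05),
  clusters = data.frame(chromosome = "chr1", start_index = 5L, run_length = 8L),
  tissue_targets = data.frame(tissue = c("heart", "brain"),
                              target_dark_ratio = c(0.5, 0.2)))
bundle <- simulate_universe(spec, sig)

profiles <- darkness_profiles(bundle$proteins, bundle$coverage)
proteome_partition(profiles)
#> Proteome residue partition (%):
#>   dark proteins:  26.6
#>   dark regions:   24.7
#>   grey regions:   26.6
#>   PDB regions:    22.1
#>   total darkness: 51.3 (over 101757 residues)
```

About half of this synthetic eukaryote-like universe is dark: 26.6% of its
residues sit in fully dark proteins and another 24.7% in dark regions of
grey proteins. The planted annotation is recovered as over-represented in
dark proteins:

```r
dark <- dark_labels(profiles)
enrich(bundle$proteins, bundle$annotations, dark)
#> Annotation enrichment: 1 annotation(s) at adjusted p <= 0.01
#>   field          subcategory    annotation nondark_with dark_with odds_ratio
#> 1    DE SUBCELLULAR LOCATION Cell membrane           17        23      4.587
#>   total  fisher_p adjusted_p rank_k direction
#> 1    40 1.197e-05  1.197e-05      1      over
```

The planted run of 8 consecutive dark genes on chr1 is detected as
improbable under re-ordering (p = 0.002, i.e. 2 of 1,000 permutations
matched it), while the other chromosomes show nothing notable; the tissue
with the planted darkness target 0.5 tops the ranking; and dark proteins
have fewer high-confidence interaction partners than non-dark ones:

```r
find_dark_clusters(bundle$proteins, bundle$genes, dark,
                   links = bundle$links, sequences = bundle$sequences,
                   n_permutations = 1000, seed = 3)
#> Dark gene clusters over 4 chromosome(s):
#>   chromosome n_genes n_dark run_length p_perm
#> 1       chr1     104     30          8  0.002
#> 2       chr2     107     22          4  0.093
#> 3       chr3     113     36          4  0.553
#> 4       chr4      76     17          2  0.988

tissue_darkness(zero_fill(bundle$expression), profiles)
#> Tissue darkness ranking (presence weighting):
#>   rank tissue ratio_dark_residues n_expressed
#> 1    1  heart               0.531          88
#> 2    2  brain               0.146          91

dist <- autonomy_distribution(bundle$proteins, dark, bundle$links, 700)
#> median interactions (>700): dark 0.0 vs non-dark 3.0
```

`dp_config()` + `dp_run()` execute all stages in one call and write one TSV
per stage (darkness, partition, enrichment + treemap JSON, autonomy,
clusters, tissues) plus a run manifest with the parameter echo and seed.

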