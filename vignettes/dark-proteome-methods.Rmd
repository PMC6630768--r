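---
title: "Methods: mapping and analysing the dark proteome"
author: "darkproteome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping and analysing the dark proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkproteome)
```

## The model

The dark proteome is the part of protein sequence space with no observed or
homology-modelled 3D structure. The unit of analysis is the *residue*: a
residue of a protein is **non-dark** when at least one structural coverage
interval covers it, under either of two criteria — criterion A, alignment
onto the ATOM record of a matched structure, or criterion B, alignment onto
a PDB entry cross-referenced in the protein's own UniProt record. Coverage
under the two criteria is combined as a union: a residue covered by either
is non-dark. Everything else is dark.

Per protein of length $L$ with $d$ dark residues the darkness score is
$D = d/L$. The classification uses the exact endpoints, with no numeric
tolerance: $D = 0$ is a **white** (fully structurally covered, "PDB")
protein, $D = 1$ a **dark** protein, and $0 < D < 1$ a **grey** protein.
Inside grey proteins, maximal runs of consecutive dark residues are **dark
regions**; a single dark residue already counts as a region (no minimum run
length is imposed by default, although `dark_runs(min_length=)` exposes one
for sensitivity analysis).

A proteome is summarised by a four-way **residue partition**: the residues
of dark proteins, the dark residues of grey proteins, the covered residues
of grey proteins, and the residues of white proteins, each as a percentage
of the summed residue count. Under this residue-based reading — the only
one under which the four numbers are guaranteed to sum to 100 — the **total
darkness** of a proteome is exactly the sum of the first two components.
An alternative reading that mixes protein counts with residue counts does
not conserve mass and is not implemented.

## Annotation enrichment

Enrichment compares annotations between dark and non-dark proteins. The
dark set defaults to the strict $D = 1$ class versus all others
(`dark_labels(definition = "strict_D1")`); a threshold-based alternative is
available because the complement of "dark" is a modelling choice, not a
mathematical necessity.

Counting is protein-level presence/absence: each distinct
(field, subcategory, text) annotation contributes one 2×2 table, and a
protein counts at most once per annotation however many times the
annotation row is repeated. The two-sided Fisher exact p sums, over all
tables sharing the observed margins, the hypergeometric probabilities not
exceeding that of the observed table; ties are compared with a relative
tolerance of $1 + 10^{-7}$, the convention used by `stats::fisher.test`,
with which the implementation agrees and against which it is cross-checked.
The implementation enumerates the hypergeometric support directly, which
makes it vectorisable over hundreds of thousands of tables. The reported
ratio is the sample odds ratio $ad/bc$, with the degenerate conventions:
$+\infty$ when only the denominator vanishes, 1 when both cross-products
vanish.

Multiplicity is controlled by the Benjamini–Hochberg step-up
$p^{adj}_{(k)} = \min\!\big(1, \min_{j \ge k} p_{(j)} \, n / j\big)$,
computed via `stats::p.adjust(method = "BH")`, applied **separately within
the DE (description) and FT (feature) families**, because the two families
are reported as separate analyses with their own test counts. The
acceptance level defaults to $\alpha = 1\%$ on the adjusted p.
Subcategories that describe groups of near-identical proteins rather than
general properties (by default `SIMILARITY`) are removed before testing so
they neither appear in output nor inflate the correction burden.

Treemap export assigns each surviving annotation a cell area of
$-\log_{10}(p^{adj})$. Two numerical choices matter here: a readability
cutoff (figures typically use 50, 10 or 0) drops leaves with smaller areas,
and an adjusted p that underflows to exactly 0 maps to a configurable area
cap, default 320 — approximately $-\log_{10}$ of the smallest positive
double — so that areas stay finite.

## Autonomy

For a protein with partner-count function $m(N)$ — the number of distinct
partners with combined confidence score strictly greater than $N$, on the
integer grid $N \in [0, 900]$ of the 0–999 score scale — the autonomy score
is

$$\mathrm{Autonomy} = \begin{cases}
1 - N^*/1000 & \text{if } m(N^*) = 0 \text{ for some } N^* \in [0,900],\\
0 & \text{if } m(900) \neq 0,
\end{cases}$$

with $N^*$ the smallest such grid value. Three conventions were genuinely
open and are resolved as follows, documented because intermediate autonomy
values depend on them: the decimal notation "$1-(0.N)$" is read as
$1 - N/1000$ over the 0–999 score scale, which reproduces both anchor
cases (no interactions at any confidence ⇒ 1; interactions persisting
above 900 ⇒ 0); $m(N)$ counts partners with score *strictly greater* than
$N$, which makes $m(900) \neq 0$ equivalent to "a partner above 900"; and
on the integer grid $N^*$ then equals the protein's maximum incident score.
A consequence asserted exactly in the tests: autonomy lies in
$\{0\} \cup [0.1, 1]$ — scores up to 900 leave at least 0.1, anything above
drops to 0. The score is monotone non-increasing in the maximum incident
score, and adding a link can never increase it. Interaction-count
distributions are reported at the high-confidence cutoff (score > 700;
tiers: low < 400, medium 400–700, high > 700) split by dark label.

## Dark gene clusters

Per chromosome, all proteins — dark and non-dark — are ordered by the
central nucleotide of their encoding gene; runs are scanned over the dark
labels of that interleaved list. When gene duplication makes the same
protein appear at several positions of one chromosome, only the first
occurrence is kept. Exact position ties are broken lexicographically by
accession, making the order a deterministic function of the input; how the
original data's ties were broken is unknowable, so the rule is this
package's own.

The statistic is the length of the longest run of consecutive dark
proteins. Its p-value is the fraction of `n_permutations` (default 1,000)
uniform re-orderings of the chromosome's label vector whose longest run is
at least as long. The plain count/n estimate is the default, so the
smallest attainable nonzero p — the per-chromosome false-positive floor —
is $1/1000$; the conservative $(\text{count}+1)/(n+1)$ variant is available
via `plus_one = TRUE`. Permutations are seeded per chromosome (offset
substream from the run seed) and reproducible.

Cluster member summaries report protein length, the number of interaction
partners *within the same cluster* ("Binds"), and the largest
single-amino-acid composition ("Bias", a percentage); bias is absent when
no sequence is available rather than imputed.

## Dark tissues

Expression tables are long-form (tissue, protein, normalised log-scale
intensity); a pair absent from the table is *missing*, kept distinct from a
literal 0 until `zero_fill()` replaces it by 0 — the convention for
proteins with no mass-spectrometry evidence. A tissue's darkness is the
ratio of dark residues among the residues of its expressed proteins
(intensity strictly above the threshold, default 0; no "highly expressed"
cutoff is applied by default since none is well defined, but
`min_intensity` exposes one). Presence weighting is the default; intensity
weighting, where both sums are weighted by the normalised intensity, is an
option and is recorded in the output. The residue-level ratio is used
rather than the fraction of dark proteins, matching the "ratio of dark
residues" reading; ranking is descending with ties broken by tissue name.

## The synthetic-data generator

`simulate_universe()` produces, under one master seed with six
per-component substreams (so one table can be regenerated without
disturbing the others), a complete input bundle plus a ground-truth
manifest. What it emulates, and the defaults chosen once as realistic study
conditions:

* **Lengths** are log-normal (meanlog 5.4, sdlog 0.5; median ≈ 220
  residues, a typical eukaryotic protein length), floored at 30 residues.
* **Classes** are multinomial with fractions dark 0.25 / grey 0.55 / white
  0.20; with grey dark-fractions uniform on (0.1, 0.9) this yields a total
  darkness near 50%, the regime reported for higher eukaryotes. Coverage
  intervals are *constructed* from the class — none for dark, full-length
  criterion-A for white, partial coverage hitting the drawn dark fraction
  for grey (sometimes split across criteria A and B to exercise the union)
  — so the realized class always equals the planted one.
* **Annotations**: for a planted (odds ratio $\omega$, non-dark prevalence
  $q$), the dark-class presence probability solves the 2×2 odds identity:
  with odds $o_d = \omega \cdot q/(1-q)$, it is $p_d = o_d/(1+o_d)$ —
  making the planted odds ratio the exact population parameter the
  enrichment module estimates. Null annotations share one prevalence
  across classes.
* **Links** are drawn Chung–Lu style: endpoints sampled proportionally to
  the class target degree (defaults dark 1, non-dark 10, the qualitative
  gap seen between dark and non-dark interactomes), scores uniform on
  0–999, pairs normalised undirected.
* **Genes** are scattered uniformly over chromosomes with uniform random
  central positions; planted runs place dark proteins at consecutive
  indices of the order. Infeasible plants (run longer than the chromosome,
  too few dark proteins) fail before anything is written.
* **Expression** assembles each tissue's expressed set greedily — fully
  dark proteins to raise the running dark-residue ratio, fully white ones
  to lower it, grey only as fallback — so the realized ratio tracks the
  planted target to within one protein's weight; intensities are positive
  normal deviates on the log scale, and a dropout probability (default
  0.1) turns measurements into missing entries, emulating proteins without
  mass-spectrometry evidence.
* **Sequences** are toy amino-acid strings; dark proteins put 30% of their
  composition on one preferred residue, giving the cluster Bias column
  something detectable.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real annotation ontologies and their correlation
structure (annotations are planted independently per protein);
length-dependent structural coverage (real PDB coverage is biased towards
globular, crystallisable domains); genome architecture (gene density,
clustering of paralogues beyond the planted runs); realistic score
distributions of interaction networks (real combined scores are heavily
skewed); and tissue co-expression structure. Statistical guarantees
validated here (calibration, recovery, conservation) transfer to real data;
any biological conclusion does not.

## Validation design and problem sizes

The suite validates: mass conservation of the partition on 100 random
universes of 40 proteins; agreement of the exact-test p with an independent
log-factorial enumeration over **all** 635,375 tables of total ≤ 60 (to
1e-12); hand-computed BH step-up values and its order invariants; null
calibration — 200 universes of 250 proteins with 30 null annotations for
the 1% FDR, and 200 chromosomes of 80 genes for the 5% permutation level,
both judged by one-sided binomial tests against the nominal level; and
planted-parameter recovery at the sizes where the estimators' sampling
error makes the checks meaningful (odds ratio 8 within 25% at 5,000
proteins; a 10-gene run in a 500-gene, 5%-dark chromosome at p ≤ 0.005; a
tissue target of 0.5 within 0.05 at 200 expressed proteins; the dark
median < non-dark median degree ordering at 800 proteins). The longest-run
scan is checked against an exhaustive window oracle on every binary vector
up to length 15.

## Known limitations

* The pipeline consumes coverage intervals; it does not compute
  sequence-to-structure alignments, so the quality of darkness estimates is
  bounded by the upstream alignment pipeline.
* Annotation identity is exact-string; no ontology expansion or semantic
  grouping of annotation text is attempted, so rephrased annotations are
  distinct test units.
* Enrichment treats proteins as exchangeable; phylogenetic relatedness
  between proteins (shared annotations through common descent) inflates
  effective test counts in real proteomes.
* Whether the published "Ratio" columns of enrichment tables are sample
  odds ratios cannot be verified without the unprinted background totals;
  the sample odds ratio is emitted and labelled as such.
* Intermediate autonomy values (between 0 and 1) are convention-dependent
  as described above; only the endpoints are convention-free.
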