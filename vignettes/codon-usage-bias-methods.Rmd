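---
title: "Methods: codon usage bias analysis with codonbias"
author: "codonbias authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias analysis with codonbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

# The problem

Synonymous codons are not used uniformly. The strength and direction of
this codon usage bias (CUB) carries information about the forces acting
on a gene family: mutation pressure moves all codon positions together,
while translational selection acts mostly on silent third positions of
highly expressed genes. `codonbias` implements the standard analysis
battery used in plant molecular-evolution studies of gene families such
as the small heat shock proteins (HSP20): per-gene indices, three
mutation-versus-selection diagnostics, optimal-codon determination,
RSCU-based multivariate views, and distance-based phylogenetics —
together with a seeded synthetic-CDS generator so the entire pipeline is
testable without external sequence downloads.

# Data model and conventions

All computation starts from a `CodonCounts` matrix (genes × 64 codons,
fixed lexicographic order). Conventions applied throughout:

* CDS validation: ATG start, single terminal stop (TAA/TAG/TGA), length
  divisible by 3. Strict mode rejects violations; lenient mode keeps and
  flags start/stop failures. Non-ACGT characters (ambiguity codes
  included) and bad lengths are always rejected — distributing ambiguous
  bases fractionally buys little and complicates every downstream
  identity. RNA-style input (U) is accepted and mapped to T.
* The terminal stop codon is excluded from counts, composition and every
  index, so `length(translate(cds)) == nCodons(cds)`.
* GC1/GC2/GC3 are computed over *all* sense codons, which keeps
  `gc == (gc1 + gc2 + gc3)/3` exact and testable; GC3s restricts to
  synonymous codons (Met/Trp excluded). The silent base frequencies
  A3s/T3s/G3s/C3s use the CodonW denominator (codons whose family can
  silently carry the base); a simpler all-synonymous denominator is
  available behind `x3sSimple = TRUE`.

# Indices

**RSCU** is observed count over the uniform within-family expectation;
families unobserved in a gene are reported `NA`, never 0 — an RSCU of 0
is a strong statement (complete avoidance), absence of data is not.

**ENc** follows Wright's estimator: per-family homozygosity
$F = (n\sum p_i^2 - 1)/(n-1)$ for families observed at least twice,
averaged within degeneracy classes, and
$N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$, capped at
61. The 6-fold families (Leu, Ser, Arg) are treated as single families.
If the lone 3-fold family (Ile) is unobserved, $\bar F_3$ is imputed as
$(\bar F_2+\bar F_4)/2$; if any other class is empty, or a class mean is
zero, ENc is `NA` rather than extrapolated — reproducibility beats
coverage for very short genes.

**CAI, Fop, CBI** need relative-adaptiveness weights. No external
reference organism is assumed: by default weights are derived from the
dataset itself, pooling the bottom-5 genes by ENc (the putative
high-expression set) and setting $w = \mathrm{RSCU}/\mathrm{RSCU_{max}}$
per family. This is the only default reproducible from the input alone;
user-supplied `ReferenceWeights` are accepted everywhere. Codons absent
from the reference pool get a floor weight of 0.01 so CAI's geometric
mean stays defined. CAI is the Sharp–Li geometric mean over codons of
degenerate families; Fop the optimal-codon fraction; CBI the
Bennetzen–Hall excess over random expectation.

# Selection diagnostics

* **ENc–GC3s**: observed ENc against Wright's null curve
  $N_c = 2 + s + 29/(s^2 + (1-s)^2)$. Genes more than 0.5 ENc units
  (configurable, purely presentational) under the curve are "below";
  bias classes are strong (ENc ≤ 35), weak (50 ≤ ENc ≤ 61), and
  intermediate.
* **PR2**: $x = G_3/(G_3+C_3)$, $y = A_3/(A_3+T_3)$ over silent third
  positions, default over all synonymous codons with a
  `fourfold_only` option (the classic formulation); the literature
  prints both axis conventions, and occasionally a typo
  ($G_3/(G_3+T_3)$) — the parity pair implemented here is the standard
  A vs T and G vs C comparison.
* **Neutrality**: OLS of GC12 on GC3 across genes; the slope is read as
  the fractional contribution of mutation pressure, its complement as
  selection. Pearson r and a two-sided p accompany the fit.
* **Expression**: per-condition Pearson r *and* OLS slope of FPKM on
  ENc are both reported — published tables sometimes label slopes as
  "correlations" (values below −1 make the distinction obvious), so the
  package refuses to guess and emits both. A `total` condition (sum over
  conditions) is appended.

# Optimal codons

Genes are sorted by ENc (ties broken lexicographically by id, so runs
are deterministic); the bottom k = 5 form the high-expression database
and the top k = 5 the low-expression database. A codon is optimal when
RSCU > 1 in **both** pools (strict) and
$\Delta\mathrm{RSCU} = \mathrm{RSCU_{high}} - \mathrm{RSCU_{low}} \ge 0.08$
(inclusive by default; `inclusive = FALSE` gives the strict variant some
abstracts use). Stop codons are never candidates. Cross-species
summaries report the union, per-codon species membership, and the
third-position base tally.

# Multivariate views and trees

RSCU vectors (59 dimensions) feed PCA and clustering. PCA is on
centered, unscaled data — RSCU is already family-normalized, and unit
scaling would inflate noise from rarely observed families; a `scale.`
flag exposes the alternative. Loading signs follow a fixed convention
(largest-magnitude loading positive) so scores are reproducible.
Missing families are imputed by column mean by default (`zero` and
`drop_rows` policies available, recorded on the result).

Gene and species–super-gene clustering uses squared Euclidean distance
with between-groups average linkage — the "intergroup linkage" of SPSS
style cluster procedures. Phylogenetics is distance-based: p-distances
with complete deletion by default ("gaps removed": every column with a
gap in any sequence is dropped; pairwise deletion available),
Saitou–Nei neighbor joining with negative branch lengths clamped to
zero, and column-resampling bootstrap whose supports attach to internal
nodes; Newick output rounds lengths to 6 significant digits and
round-trips through standard parsers. Alignment itself is out of scope:
pre-aligned CDS are expected.

# The synthetic generator

`generatorConfig()` defaults describe the emulated study conditions: 140
genes, CDS lengths uniform on 393–1116 nt (the printed range of the
HSP20 family the pipeline was designed around), four species, twelve
subfamilies, i.i.d. amino acids from a typical plant protein
composition, per-gene selection strength $s \sim U(0, 3)$ boosting the
subfamily's planted preferred codon, and log-linear expression
$\log \mathrm{FPKM} = 3 + 0.8\,s + N(0, 0.5)$ over three named
conditions — which induces the negative FPKM–ENc correlation the
expression diagnostic expects.

Two deliberate design points:

* **Background preference.** Every gene shares a mild genome-wide boost
  (`baselinePreference = 0.5`) of the preferred codons on top of its
  own $s$. Real genomes keep such background bias even in weakly
  expressed genes, and it is what makes the "RSCU > 1 in both
  databases" criterion well-posed: with no background, the
  low-expression pool sits exactly on the RSCU = 1 boundary and
  optimal-codon calls degenerate to coin flips on sampling noise. Tests
  of the uniform-usage extreme set it to 0 explicitly.
* **Regimes.** The mutation regime samples codons jointly with a
  per-gene GC weight on *all* positions (amino-acid usage drifts with
  GC, as mutation pressure does), giving neutrality slopes near 1; the
  selection regime confines GC drift to silent third positions and adds
  per-gene preference, giving slopes near 0 and a majority of genes
  below the expected ENc curve.

What the generator does **not** emulate: codon autocorrelation along the
sequence, realistic protein domain structure, indels/alignment noise, or
expression measurement error beyond lognormal noise. Passing the
recovery suites therefore demonstrates correctness of the estimators
under the stated stochastic model, not robustness to every property of
real transcriptomes.

Problem sizes used by the validation suites — chosen to make the
stochastic properties sharp at desk scale — are 100–200 random genes for
oracle-equivalence checks, 200 genes at $S = 6$ for optimal-codon
recovery, 500 genes per regime for the neutrality separation, and random
trees up to 12 taxa for NJ round-trips.

# Numerical choices and degenerate inputs

* pI by bisection on [0, 14] to 1e-4 pH with a bundled Lehninger-style
  pKa set (net charge is strictly decreasing, so the root is unique).
  Published pI values computed with other tools/pKa tables will differ
  in the second decimal; the table is versioned with the package.
* Molecular weight uses average residue masses plus one water, in kDa.
* Ties: expression-database membership and reference optimal codons
  break ties lexicographically; hierarchical merges and NJ joins follow
  the smallest-index conventions of `hclust`/`ape::nj`.
* Degenerate inputs: zero-codon genes error in `composition`; genes
  whose every degenerate family is observed < 2 times get `NA` ENc;
  constant columns yield `NA` correlation cells; zero PR2 denominators
  yield `NA` coordinates; empty pools and empty CDS sets error early
  with explicit messages.

# Limitations

Correspondence analysis, tAI/CSC-style indices, model-based
evolutionary distances and alignment are intentionally out of scope.
Absolute CAI/CBI/Fop values depend on the reference weights; with the
self-derived default they are comparable within a dataset, not across
publications that used external reference sets.
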