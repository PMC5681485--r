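---
title: "Methods: from multi-trait mixed-model GWAS to annotated co-association networks"
author: "awmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-trait mixed-model GWAS to annotated co-association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters,
the synthetic-data design, and the numerical and design choices behind
`awmnet`. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The mixed model and the EMMAX approximation

Each trait is analysed under

$$ y = X\beta + g + e, \qquad g \sim N(0, \sigma_a^2 K), \quad e \sim N(0, \sigma_e^2 I), $$

where $X$ carries an intercept and treatment-coded contemporary-group
dummies (one level dropped; rank checked by pivoted QR) and $K$ is the
VanRaden method-1 genomic relationship matrix,
$K = ZZ'/(2\sum_i p_i(1-p_i))$ with $Z$ the $2p$-centred genotypes and
$p$ the observed allele frequencies. Missing genotypes are mean-imputed
per SNP before centring (unbiased under missingness completely at
random); missing phenotypes define a per-trait analysis subset and are
never imputed. `stabilize()` adds a diagonal ridge only when the smallest
eigenvalue of $K$ is negative, and records the adjustment.

Variance components are estimated once per trait under the null
(no-SNP) model — the EMMAX approximation. After one spectral
decomposition $K = UDU'$, the restricted likelihood is profiled in the
single ratio $\delta = \sigma_e^2/\sigma_a^2$; the criterion is evaluated
on a 64-point grid over $\log\delta \in [-10, 10]$ and refined by a
bounded 1-D search in the bracketing interval, so secondary modes of the
profile are not missed. REML is the default (standard for variance
components in the presence of fixed effects); ML is available. When the
profile is flat (e.g. $K \propto I$, where the split
$\sigma_a^2/\sigma_e^2$ is unidentifiable) the fit carries an
`identifiable = FALSE` diagnostic and a warning rather than an arbitrary
confident answer. Pseudo-heritability is reported as
$\sigma_a^2/(\sigma_a^2+\sigma_e^2)$.

Each SNP is then tested by generalized least squares of $y$ on
$[X \mid g]$ with the covariance $\sigma_a^2 K + \sigma_e^2 I$ held fixed
at the null estimates. The Wald statistic is referred to a $t$
distribution on $n - \mathrm{rank}([X \mid g])$ degrees of freedom — the
reference distribution is asymptotically normal, and $t$ was chosen for
small-$n$ correctness. SNPs collinear with the fixed effects (including
SNPs monomorphic within a trait's analysis subset) are flagged and
reported with effect 0 and $p = 1$ instead of being silently dropped.
The scan is implemented by whitening in the rotated basis and
residualizing against $X$ (Frisch–Waugh), which is algebraically
identical to the explicit dense GLS solve; the test suite asserts
equality with such an oracle to 1e-8.

## Quality control

Filter order: sample call rate, SNP call rate, MAF, then HWE, with SNP
statistics recomputed on the surviving samples — chosen so the HWE test
sees the cleaned sample set (the order is not dictated by the workflow's
provenance, which is silent on it). Defaults: call rates ≥ 0.95, MAF ≥
0.05, HWE $P \geq 10^{-4}$. Both an exact HWE test (summing the
probabilities of all heterozygote counts with the observed allele counts
that are no more probable than the observed table) and the 1-df
chi-square test are provided; the exact test is the default. The two
disagree by a few hundredths in the mid-range of $p$ at realistic sample
sizes — that is the chi-square approximation itself, so the tests assert
decision agreement at the $10^{-4}$ cut and convergence with $n$ rather
than a fixed pointwise tolerance. Monomorphic SNPs get $p = 1$ by
convention and are left to the MAF filter.

## The AWM funnel

`build_awm()` applies, in a fixed and logged order: (1) key-trait filter
(raw $P <$ 0.05 by default — deliberately permissive so small-effect
pleiotropic markers enter), (2) pleiotropy filter (association with at
least `min_other_traits = 2` phenotypes other than the key one), (3)
gene-proximity filter (within a gene or within 2,500 bp of one; 1-based
inclusive intervals; both boundary conventions are tested on both
sides). The source workflow's two counts ("at least two phenotypes" vs
"at least two other phenotypes") are irreconcilable from its text, so the
threshold is an explicit knob rather than a silent resolution, and the
key-trait column is included by default with a flag
(`include_key_trait_column = FALSE`) to reproduce the traits-minus-one
layout. Columns are z-scored over the selected rows by default (raw
effects retained as a sensitivity mode); whether the original analysis
standardized is unstated. Effects are expressed per copy of the same
counted allele across traits so row correlations are meaningful.

## PCIT

Edges are Pearson correlations between AWM rows across trait columns
(at least 3 columns required; constant rows are excluded with a
warning). For every trio $(x, y, z)$ the three first-order partial
correlations, e.g.

$$ r_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}{\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}, $$

set the information-theoretic tolerance
$\varepsilon = \tfrac13 (r_{xy\cdot z}/r_{xy} + r_{xz\cdot y}/r_{xz} + r_{yz\cdot x}/r_{yz})$,
and the trio flags edge $(x,y)$ as non-significant when
$|r_{xy}| \le |\varepsilon r_{xz}|$ and $|r_{xy}| \le |\varepsilon r_{yz}|$.
An edge survives iff no trio flags it; with fewer than three nodes every
edge survives vacuously. Numerical conventions: trios with a
conditioning correlation within 1e-12 of $\pm 1$, or with a non-finite
tolerance (zero denominators), are skipped rather than allowed to
propagate NaN. The implementation sweeps one conditioning node at a time
with matrix operations and is asserted outcome-identical to a naive
triple loop. The significance rule (not a raw partial-correlation
threshold) is the retention criterion; the correlation itself is the
edge weight handed to clustering.

## MCODE

Vertex weight = $k_{\max} \times$ density of the highest $k$-core of the
closed neighbourhood. Clusters grow breadth-first from the
highest-weight unassigned vertex, admitting neighbours with weight
$\ge (1 - \mathrm{vwp}) \times$ seed weight (vwp = 0.2 by default, from
the original molecular-complex-detection publication, as are haircut on,
fluff off, max depth 100); each vertex joins at most one cluster;
haircut keeps the cluster's 2-core; clusters need ≥ 3 nodes. Score =
density × nodes with the simple-graph maximum $n(n-1)/2$ — loops and
multi-edges are excluded from the density because the published cluster
tables this mirrors cannot be reproduced from their own printed
node/edge counts under any other printed convention. All ties (seed
order, ranking) break lexicographically by node id, so output is
deterministic.

A structural limitation worth knowing: the expansion rule has no
bridge-resistance. Two dense communities joined by even a handful of
edges between similarly weighted vertices are absorbed into one cluster;
on 30+30 planted-partition graphs with between-block edge probability
0.02 (≈ 18 expected bridges) the first cluster regularly swallows most
of both blocks. The validation suite measures this honestly instead of
hiding it; disjoint dense structures (the planted-clique test) are
recovered exactly.

## Annotation and enrichment

SNP-to-gene assignment is interval arithmetic over 1-based inclusive
gene models (GenomicRanges underneath, with distances recomputed in
base-pair units so that "gene end + 2,500" is near and "+ 2,501" is not;
`distanceToNearest()` alone counts adjacency as 0). Ties go to the
smaller distance, then the lexicographically smaller gene id. Near-gene
SNPs get an upstream/downstream sub-category from the nearest gene's
strand.

Enrichment is the upper-tail hypergeometric probability per term, BH FDR
across tested terms, and fold enrichment
$(k/n)/(K/N)$. The universe defaults to all genes hosting (or within the
window of) at least one post-QC SNP — the original analysis never states
its background, so the choice is explicit and recorded in output
headers. The cluster enrichment score is $-\log_{10}$ of the geometric
mean of member $p$-values (1.3 ⇔ geometric-mean $p$ = 0.05). Term
grouping computes Cohen's kappa between binary gene-membership vectors
over the analysed list and takes single-linkage connected components at
kappa > 0.3; the full iterative merge heuristic of interactive tools is
deliberately simplified to this reproducible rule, since only the
thresholds are published. Which FDR variant the original chart printed
is unstated; BH is implemented and labelled.

## The synthetic study design

The generator emulates a paternal half-sib beef-cattle design at one
quarter scale: 500 genotyped offspring of 37 sires (≈ 14 per sire, the
full design's ratio), 8 contemporary groups (fixed effects, SD 0.5
phenotypic SD), 5,000 SNPs on 5 chromosomes with 30 kb mean spacing and
MAF uniform on [0.05, 0.5], 10 traits with heritabilities spanning
0.17–0.67 (trait 1, the key phenotype, at 0.38), and 10% phenotypes
missing completely at random (the source trait table shows per-trait N
ranging well below the herd size). Offspring draw one allele from their
sire and one from the population, giving sire–offspring relationship
0.5 and half-sib relationship 0.25 with no linkage disequilibrium beyond
family structure — LD is not required to exercise the AWM/PCIT logic,
and an unstructured panel keeps every stage's expectations analytic.

Pleiotropy is planted as 15 QTL in three blocks of five; each QTL
affects the key trait plus one contiguous block of three other traits.
Effects are scaled by 1/sd(genotype) so each QTL contributes exactly
`qtl_effect_sd`² = 2.4% of phenotypic variance per affected trait, with
a per-QTL sign times a per-block direction pattern, so same-block QTL
have proportional effect profiles — exactly the correlated-effect
structure PCIT is meant to detect. These sizes come from a design-stage
power calculation: 2.4% at n = 500 gives ≈ 0.9 power at nominal
$P < 0.05$, hence ≈ 0.88 expected per-QTL survival through the AWM
funnel and ≥ 3 surviving members per block (the MCODE minimum cluster
size) with probability ≈ 0.99. The key trait's summed QTL variance
(15 × 2.4% = 36%) stays within its heritability. The residual genetic
variance is a genomic polygenic term (a genome-wide random effect vector
through the observed genotypes) with one latent factor shared within
each trait block (shared fraction 0.4), so trait correlations arise only
through shared QTL and shared polygenic factors. Phenotypic variance is
1 by construction (genetic + residual; contemporary groups sit on top as
fixed effects).

Gene models are placed by a two-phase algorithm that makes the
within/near/intergenic designations exact by construction: genes are
confined between midpoints to neighbouring SNPs (no overlap possible)
and kept > 2,500 bp clear of intergenic-designated SNPs; quotas are
topped up with transitive-closure promotion when close intergenic SNPs
block each other; QTL SNPs are hosted first (an unavoidable blocking
neighbour is excused as a recorded "shadow" SNP rather than losing the
QTL). One planted "causal" term collects the QTL-hosting genes plus a
few decoys, giving enrichment a positive control.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium and
the SNP-tagging it implies, selection and assortative mating, dominance
and imprinting, genotyping error, non-random phenotype missingness,
real gene-length and term-size distributions, and the GO DAG. Results on
real panels will be noisier at every stage than the planted-truth
recovery rates suggest.

## Determinism and problem sizes

A single integer seed drives everything; the generators expand it by a
fixed rule (`seed * 31 + stage`) so stages are independently
reproducible, and identical seeds give bit-identical PLINK/TSV/GMT
artifacts. The validation suite uses 500 animals × 5,000 SNPs for
calibration runs, 800 × 1,500 for heritability recovery, instances up to
n = 50 for dense-GLS oracle equivalence, 200 random matrices up to
n = 60 for PCIT oracle equivalence, and ten full pipeline replicates for
end-to-end recovery — sizes chosen so each check has the statistical
resolution its tolerance needs while remaining desk-scale.

## Known limitations

* EMMAX estimates variance components once per trait; for very large
  SNP effects the per-SNP exact mixed model would differ.
* The GLS test holds the null covariance fixed (score-test flavour);
  p-values are asymptotically, not exactly, $t$.
* MCODE merges bridge-connected communities (see above).
* The proximity annotator resolves only what gene-level intervals can
  support (no transcript-aware consequences, no regulatory regions).
* PCIT's tolerance is the trio-mean ratio form; other published variants
  exist and would retain slightly different edge sets.
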