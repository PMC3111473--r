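---
title: "Distinction-based pathway analysis: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinction-based pathway analysis: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poda)
```

## The model

`poda` asks, pathway by pathway, whether cases are genetically closer to the
other cases than controls are, over the SNPs mapped to the pathway's genes.

Genotypes are stored as the per-individual minor-allele frequency: 0, 0.5
or 1 for homozygous-major, heterozygous and homozygous-minor calls. Under
this coding the mean of a SNP column over any pool of samples is the pool's
minor allele frequency, so a pool has a natural *centroid* — its MAF
vector. For sample $i$ at locus $j$, with $f_j$ and $g_j$ the control- and
case-pool MAFs computed after removing sample $i$ from its own class,

$$d_{ij} = |y_{ij} - f_j| - |y_{ij} - g_j|$$

is the distance to the control centroid minus the distance to the case
centroid along coordinate $j$: positive means closer to the cases. Its
range is $[-1, 1]$. Over the $s$ loci of a SNP set the per-sample summary
is the one-sample standardised mean

$$D_i = \frac{\bar d_i}{\mathrm{sd}(d_i)/\sqrt{s_i}},$$

with the sample ($n-1$) standard deviation and $s_i$ the number of loci
actually observed for sample $i$. The denominator is the essential
difference from a plain nearest-centroid rule: a sample consistently
slightly closer to the cases at every locus outscores one that is strongly
closer at a few loci and farther at others, which is what lets correlated,
individually weak signals accumulate. On data of realistic size $D$
typically spans about $-3$ to $3$.

The leave-one-out construction matters twice over. Statistically it keeps
each sample's score free of its own influence on the centroids; practically
it makes $D_i$ usable as an out-of-sample predictor, which is why disease
odds can be modelled downstream as `status ~ D` by logistic regression.

The case/control difference in $D$ is summarised non-parametrically by the
Wilcoxon rank-sum statistic $W$ (ranks ascending over all samples, midranks
for ties, summed over cases). Two biases make raw $W$ incomparable across
pathways: genes with many SNPs are likelier to contain a spuriously
significant representative, and longer pathways sample case/control
differences more thoroughly. Both are handled empirically:

1. **Permutation normalisation.** Case/control labels are permuted
   (class sizes preserved); under each permutation the per-gene SNP
   selection is *redone* and $W$ recomputed. The distinction score is
   $DS = (W - \mathrm{mean}(W_{perm})) / \mathrm{sd}(W_{perm})$. Because
   selection runs inside the permutation, the null ensemble inherits the
   large-gene selection advantage, and correlations between SNPs are left
   intact.
2. **Length-matched resampling.** $DS$ is recomputed for random sets of
   $s$ SNPs drawn from the pool of all per-gene representative SNPs; the
   p-value is $(b+1)/(B+1)$, where $b$ counts random sets with $DS$ at
   least the pathway's (ties count toward $b$, which is conservative, and
   the add-one form never reports zero).

A pathway is therefore called significant only if it distinguishes cases
from controls *better than a random, equally long collection of
most-informative-per-gene SNPs* — not merely better than chance labels.

## Representative-SNP selection

One SNP represents each gene: the gene's QC-passing SNP with the smallest
two-sided Fisher's exact p (allelic 2×2 table by default; a genotypic 2×3
option exists). The point is to detect multi-*gene* structure — several
SNPs inside one gene are usually in linkage disequilibrium, and letting
them all vote would make a single haplotype block look like a concerted
multi-gene signal. The chosen SNP is the gene's most informative marker; it
need not be significant on its own.

Exact p ties break toward the lexicographically smaller SNP id, making
selection deterministic and independent of annotation order. A SNP mapped
to two genes may represent both; within one pathway's SNP set it is counted
once. QC retains a SNP when its missing fraction is at most `max_missing`
(default 0.10) and its MAF is at least `min_maf` (default 0.01) within the
cases and within the controls separately — standard GWAS practice;
near-monomorphic-in-a-class SNPs carry no usable distance signal. There is
no Hardy–Weinberg filter: departures from HWE are part of what a
genotype-level method may legitimately use.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n_perm` | 100 | label permutations for $DS$; enough for a stable mean/sd of the null $W$ |
| `n_resample` | 1000 | random sets per pathway length; resolution floor of the p-value is $1/(B+1)$ |
| `max_missing` | 0.10 | per-SNP missing-call ceiling |
| `min_maf` | 0.01 | class-wise MAF floor |
| `cull.threshold` | 0.60 | redundancy culling: a pathway sharing *strictly more* than this fraction of its SNPs (shared / smaller set) with a retained pathway is removed |
| `sd_floor`, `cap` | 1e-12, 1e6 | degeneracy guards for $D$ (below) |

All stochastic steps take an explicit seed; `run_full_analysis()` writes a
manifest echoing every effective parameter, so a run is reconstructible
from the manifest plus inputs.

## Numerical choices and degenerate inputs

* $D$ is undefined when a sample's $d_{ij}$ are constant
  ($\mathrm{sd} = 0$). If the constant is zero (for example, all samples
  genotypically identical), $D = 0$; otherwise $D$ is set to
  $\mathrm{sign}(\bar d) \times$ `cap`. The floor `sd_floor = 1e-12`
  separates genuine zeros from rounding.
* Missing genotypes are excluded locus-wise per sample, and $s_i$ (the
  observed-locus count) replaces $s$ in the $\sqrt{s}$ factor. A sample
  with no observed locus in a SNP set is an error, not a silent zero. A
  locus whose leave-one-out pool has no observed call is skipped for that
  sample.
* Rank ties get midranks; $W_{cases} + W_{controls} = N(N+1)/2$ always.
* The minor allele is defined on the pooled sample (cases + controls). At
  an exact 50/50 frequency the file's coded allele (ALT for VCF) stays the
  minor allele, so re-loading is deterministic. Multi-allelic VCF records
  are skipped with a warning — the statistic is defined for biallelic
  SNPs.
* Fisher tables with a zero margin are uninformative and score p = 1.
* Complete separation in the logistic fit is flagged (`separation`) rather
  than silently reported or silently penalised; the Wald p is meaningless
  there, and a constant $D$ yields OR = 1 directly.
* Greedy redundancy culling depends on the walk order, so it is run over
  the score-descending order plus `n_orders` (default 25) random orders and
  the modal retained set is reported, ties resolved toward the
  score-descending outcome.

## Design choices that were genuinely open

* **Shared permutation ensemble in resampling.** Recomputing a fresh
  permutation null for each of the $B$ random sets would multiply the cost
  by $B$; by default the pathway's own permuted labelings normalise every
  random set (`share_ensemble = TRUE`), which keeps the comparison between
  the true and random sets exactly matched. Full per-set re-permutation is
  available behind the flag.
* **Overlap denominator in culling.** "Shares more than 60% of its SNPs"
  needs a denominator; shared / size-of-the-smaller-set is used because it
  is symmetric and always catches a pathway nested inside another.
* **Union of pathways.** Combined "superpathways" are built as the
  deduplicated union of the member pathways' selected SNPs and re-scored
  from scratch — never by feeding several pathways' $D$ vectors into one
  regression, which would double-count shared SNPs.
* **Resampling pool.** Random sets are drawn from the per-gene
  representative SNPs of *all* mapped genes (one slot per gene), mirroring
  how real pathways acquire their SNPs.

## What the simulators emulate — and what they do not

`sim_epistatic_gwas()` generates the package's reference epistatic design:
binomial Hardy–Weinberg genotypes at 50 loci, MAFs evenly spaced over
0.1–0.4, 250 cases and 250 controls collected by rejection sampling from a
penetrance model in which homozygous-minor genotypes at loci {1,2} or {1,3}
multiply a baseline disease probability (default 0.2) by a relative risk of
3 (capped at 1).

Two generator choices deserve their rationale:

* **MAF order.** The per-locus MAFs are assigned in *descending* order, so
  the interacting loci sit at the top of the range (≈0.4). The two-locus
  homozygous-minor carrier frequency scales as $\mathrm{MAF}^4$: at 0.4 the
  risk genotype appears in a few percent of the population, while at 0.1 it
  would occur at ~$10^{-4}$ and be unobservable at these sample sizes. A
  uniform-random mode (`maf_spacing = "uniform"`) is available.
* **Baseline prevalence 0.2.** The penetrance baseline is a free parameter
  of the design (only the relative risk is fixed); 0.2 keeps
  $3 \times 0.2 \le 1$ and makes case quotas reachable quickly. Note an
  intrinsic ceiling of this design that no prevalence choice lifts: with
  relative risk $R$ and carrier frequency $q$, the carrier fraction among
  cases is $qR/(qR + 1 - q)$ — about 13% here — so the pathway signal is
  carried by a minority of cases and single-replicate detection power at
  $\alpha = 0.05$ is moderate (the test suite and the acceptance script
  measure it as a rejection *rate* over replicates rather than asserting
  near-certain detection, and the frozen expectations — causal rate at
  least twice nominal, excluded-pathway rate near nominal — come from a
  pilot of exactly that oracle). For the same reason the risk loci carry
  weak but non-zero marginal associations.

`sim_null_gwas()` is the matching label-independent generator used for
calibration; `sim_xor_gwas()` builds the canonical centroid-invisible
configuration: controls carry concordant genotype pairs {(0,0), (1,1)} and
cases discordant pairs {(0,1), (1,0)} at two focal loci in exactly equal
halves, so both classes have identical centroids (MAF 0.5 at both loci) and
$d_{ij}$ is identically zero, while the classes are perfectly separable
from the joint genotypes.

None of the generators simulate linkage disequilibrium (the per-gene
representative-SNP step exists precisely to blunt within-gene LD),
population stratification, genotyping batch effects, or covariates.
Passing tests on these designs therefore demonstrates the statistic's
behaviour under its own assumptions — clean biallelic HWE genotypes and
exchangeable samples — not robustness to the confounding structure of real
cohorts.

## Problem sizes used by the test suite

The suite checks the vectorised statistic against a scalar per-sample,
per-locus oracle on 50×100 data; rank-sum midranks against a counting
oracle on 200 small instances; null calibration of $DS$ and the resampled
p over 200 replicates at 100 cases/100 controls (one 20-gene pathway
against a 50-gene pool, 50 permutations, 99 resamples); the epistatic
design's rejection rates over 200 replicates at full size (250/250 × 50);
and the XOR contrast at 200 samples per class. These sizes give tight
oracle comparisons and binomial bands while keeping a full run to a few
minutes on one core.

## Limitations

* Epistasis with *exactly* equal class centroids (XOR-type compensation) is
  invisible to the centroid statistic by construction; the
  pairwise-distance variant reacts to it but costs $O(N^2 s)$ and its
  finite-sample separation arises from leave-one-out asymmetry in the mean
  distances, so it should be read as a screen, not an effect size.
* The distinction score detects *differential homogeneity*; it does not
  localise which SNPs drive it. A follow-up per-SNP examination inside
  flagged pathways is the intended workflow.
* Logistic odds ratios are per-unit-of-$D$ and depend on the pathway's SNP
  count through the scaling of $D$; they are comparable across pathways
  only loosely.
* p-values below $1/(B+1)$ are unreachable by construction; raise
  `n_resample` when ranking the extreme tail matters.
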