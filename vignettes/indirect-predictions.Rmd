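---
title: "Indirect genomic predictions under genotyping errors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect genomic predictions under genotyping errors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ipgblup)
```

## The problem

Large genotyped livestock populations increasingly rely on *indirect
predictions* (IP) for young selection candidates: instead of re-running the
full single-step genomic BLUP (ssGBLUP) evaluation every time a batch of new
genotypes arrives, per-locus SNP effects are back-solved once from the GEBV
of the genotyped reference animals, and a candidate's breeding value is then
just its centered gene content times those effects. Indirect predictions
depend *only* on the candidate's SNP codes, so genotyping or imputation
errors hit them with full force — unlike GEBV, which are buffered by
pedigree and phenotype information. This package implements a simulation
pipeline to quantify that sensitivity: a forward-in-time breeding program,
the ssGBLUP machinery, the back-solving step, controlled genotyping-error
injection, and the evaluation statistics comparing IP against benchmark
GEBV.

## Models

### Single-step GBLUP

The evaluation model is a single-trait animal model
$y = \mathbf{1}\mu + u + e$ with $\mathrm{var}(u) = H\sigma^2_a$ and
Henderson's mixed-model equations using

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}
\end{bmatrix},$$

where $A^{-1}$ is the sparse pedigree inverse (Henderson's rules with
Meuwissen–Luo inbreeding), $A_{22}$ the pedigree relationships among
genotyped animals (computed by Colleau's indirect method, never forming the
full $A$), and $G^* = (1-\alpha)(\mathbf{11'}c + dG) + \alpha A_{22}$ the
tuned and blended VanRaden matrix, $G = ZZ'/k$ with
$k = 2\sum_l p_l(1-p_l)$. Tuning uses the single mean-based equation
$c = \overline{A_{22}} - \overline{G}$, $d = 1 - c/2$ (a two-equation
diagonal/off-diagonal variant is available via `tune_method = "two_eq"`).
Variance components are treated as known: with $h^2 = 0.25$ and
$\sigma^2_p = 1$, $\lambda = \sigma^2_e/\sigma^2_a = 3$. The solver
(`solve_mme()`) factorizes small systems densely, uses a sparse Cholesky
for pedigree-only systems, and Jacobi-preconditioned conjugate gradients
for large single-step systems (relative-residual tolerance `1e-10` by
default; the experiment runner uses `1e-8`, far below the sampling noise of
any reported statistic).

### Back-solving and indirect prediction

The *benchmark* run fits ssGBLUP with genotypes of both the training
generations and the candidates (candidates carry no phenotypes and enter
through $H^{-1}$ only); its candidate GEBV are the reference. The *reduced*
run drops the candidate generation entirely and its training GEBV
$\hat u_t$ are converted to SNP effects

$$\hat a = (1-\alpha)\, d\, \frac{1}{2\sum_l p_l(1-p_l)}\,
Z_t' G^{*-1}_{tt} \hat u_t,$$

and indirect predictions are $IP = Z_v \hat a$. The residual polygenic
fraction is deliberately ignored in this derivation (it is part of the
simulated trait only); with a 5% fraction its effect on the IP is marginal,
which is precisely the operating point the pipeline studies.

### Centering frequencies

All gene contents are centered with one frequency set, used for $Z_t$,
$Z_v$, $G$ and $k$. The default is the **base-population frequency**,
VanRaden's original prescription — and in this simulation the base is
known exactly: every locus starts the historical phase at frequency 0.5,
so base centering is simply $p_l = 0.5$. The choice is load-bearing twice
over. First, centering by the *observed training* frequencies makes
$\mathbf{1}'Z_t = 0$ exactly, hence $\mathbf{1}'G = 0$, so direct genomic
values — and with them the IP — lose the genetic trend and sit on a
different base than the GEBV, producing standardized biases of several
genetic standard deviations even with perfect genotypes. Second, the
error substitution's fixed point is the heterozygote (codes are pulled
toward 1, i.e. toward frequency 0.5): centered at the base, the expected
effect of errors is a pure multiplicative compression of the gene content
by $1 - 1.5\,\mathrm{rate}$, whereas centering at any drifted estimate
(e.g. frequencies observed in the 126 current-population founders) adds a
per-locus offset $(1 - 2p_l)$ at every perturbed locus — spurious noise
that exaggerates how fast the error scenarios degrade. Founder-estimate
and observed-training centering remain available via `freq_source`. Loci
monomorphic at the centering frequencies contribute nothing: zero columns
in $Z$, zero weight in $k$, zero back-solved effect.

### Genotyping errors

`inject_errors()` perturbs, for each animal independently, exactly
`round(rate * n_loci)` uniformly chosen loci; each perturbed code is
replaced by one of its two alternatives with probability 1/2 (a 0 becomes
1 or 2, and so on), so every perturbed entry differs from its original.
The per-animal reading of "x% of the SNPs changed" gives exact printed
counts per candidate; a shared-locus mode (`shared_loci = TRUE`), the
platform-artifact interpretation, is also implemented. Validation-genotype
errors never touch the centering constants (the base frequencies are a
fixed reference). The training-error side experiment perturbs the training
genotypes before the reduced run, so the errors propagate through $G$,
$\hat u_t$ and $\hat a$ — with one deliberate exception: the tuning
constants $c$ and $d$ are kept at the values calibrated on the clean
evaluation, as production pipelines do between runs. This matters for the
*direction* of the effect. Errors compress the centered gene contents by
$\kappa = 1 - 1.5\,\mathrm{rate}$; back-solving through the noisy
$G^{*-1}$ then inflates the effects by roughly $1/\kappa$ to keep
reproducing $\hat u_t$, and applying those inflated effects to *clean*
candidate genotypes inflates the mean IP. Re-tuning on the noisy $G$
renormalizes its scale and cancels that compensation, turning the
inflation into a $\kappa$-fold deflation. A pipeline that re-tunes is
available by calling `run_reduced()` on perturbed genotypes directly.

## The simulator

The generator emulates a cattle-like breeding program in three phases:

1. **Historical**: discrete generations, random union of gametes, equal sex
   ratio, no selection; census declines linearly through two bottlenecks so
   drift builds linkage disequilibrium without fixing every locus.
   Recurrent mutation (rate $10^{-4}$ per locus per gamete) flips allele
   states. Loci start at frequency 0.5 from a pool several times larger
   than the final panel; after this phase `select_panel()` samples the SNP
   panel and QTL among loci with minor-allele frequency at least 0.05.
2. **Expansion**: 8 generations of random mating with exponential census
   growth, after which the current-population founders are sampled.
3. **Current population**: 15 generations of truncation selection.
   Each generation every breeding dam produces a fixed litter
   (default 5, sexes equally likely); EBV are re-estimated by pedigree
   BLUP (animal model, $A^{-1}$, true variance ratio) on all phenotypes to
   date — the cheapest estimator consistent with selecting "on EBV" — and
   the stated fractions of sires (60%) and dams (20%) are culled from the
   bottom of the ranking and replaced by the top young candidates. Mating
   is rank-assortative: sires and dams are sorted by EBV and dams assigned
   to sires in contiguous rank blocks. Phenotypes are recorded on both
   sexes; the trait has $h^2 = 0.25$ of which 5 points of phenotypic
   variance are a residual polygenic effect simulated alongside the QTL
   (founder polygenic deviations $N(0, 0.05)$, offspring by the standard
   parent-average plus Mendelian-sampling recursion with inbreeding).
   QTL effects are drawn standard normal and rescaled so the founder QTL
   variance under linkage equilibrium equals $(h^2 - 0.05)\sigma^2_p$;
   with $\sigma^2_p = 1$ the additive SD is 0.5, the unit in which
   standardized biases are expressed.

Meiosis follows the Haldane model (Poisson crossovers, no interference),
implemented in compiled code, as forward simulators in this field do.

### Interpreting "30% growth of the breeding population"

A 30% *per-generation* growth of the dam herd over 15 generations would
multiply it 39-fold, which is incompatible with roughly flat generation
sizes (a training set of four generations only ~3.6 times the size of the
single validation generation). The package therefore reads the figure as
**cumulative** growth across the current phase: dams grow at
$(1.3)^{1/14} - 1 \approx 1.9\%$ per generation, rounded down. The exact
offspring-per-dam policy behind the published dataset sizes is not
recoverable; the litter size is a configuration value.

### Desk-scale profile

`desk_profile()` is the configuration every shipped test and the
acceptance script use: 25 sires (the sire count pins the effective
population size near the design's value: $N_e = 4N_mN_f/(N_m+N_f) \approx
83$ with 120 base dams, against 99 at full scale) and about 10,400
animals over 15 generations — ~2,970 genotyped training animals in
generations 11–14 and ~775 candidates in generation 15 — with 5,000 SNPs
and 200 QTL, 5 replicates, one to two minutes per replicate on one CPU.
Two deliberate departures from naive proportional scaling:

* **Historical phase**: 100 + 100 generations at sizes 500 → 100 → 50.
  Scaling the full 1,020 + 1,000 generations down proportionally in size
  would drive cumulative drift $\exp(-\sum 1/2N)$ far past fixation of
  every locus; the shortened schedule keeps the two-bottleneck structure
  while a 5× locus pool still yields the panel. This is a stand-in
  targeting the same qualitative LD and drift structure, not a replica.
* **Map length scales with marker count**: 200 cM across the same 29
  chromosomes, chosen so the per-adjacent-marker linkage disequilibrium
  matches the full-scale design ($4N_ec \approx 0.13$ there: 70,000
  markers on 23.33 Morgans at $N_e = 100$; here 5,000 markers at $N_e
  \approx 83$ give the same product at 0.04 cM spacing). The attenuation
  of indirect predictions under genotyping errors is governed by
  per-marker linkage disequilibrium (how much of each marker's signal its
  neighbours share); keeping the full 23.33 Morgan map under a 14-fold
  thinner panel would make every error scenario degrade far more steeply
  than the full-scale experiment it stands in for.

What the generator does *not* emulate: sequence-level variation, dominance
and epistasis, litter-size and mortality processes, genotyping-platform
error patterns beyond uniform code substitution, overlapping-generation
age structure beyond what the replacement rates induce. Passing tests
therefore demonstrate the pipeline's internal consistency and the
direction and rough magnitude of error-induced degradation — not
quantitative transfer to any particular real population.

## Numerical choices

* Seeds: one master seed per replicate; map construction, historical
  phase, panel choice, expansion, QTL effects and selection each draw from
  a named sub-seed, and error injection uses an offset stream so all error
  scenarios within a replicate perturb the identical population.
* Symmetry of assembled relationship matrices is enforced by averaging
  with the transpose; positive definiteness of $G^*$ normally comes from
  blending ($\alpha = 0.05$). In degenerate small-sample settings (fewer
  effective markers than genotyped animals combined with a negative
  tuning shift) $G^*$ can still be indefinite; its inverse is then
  computed with the spectrum floored at $10^{-4}$ of the mean diagonal —
  the offending directions get near-zero variance instead of aborting the
  fit — and a warning is raised.
* The APY inverse is provided for fidelity (its full-core limit is tested
  to equal the dense inverse to 1e-8; an 80%-core inverse reproduces the
  dense solve's action with correlation above 0.99), not for scalability —
  desk-scale matrices are dense throughout.
* Sample (n−1) variances everywhere; 95% CIs via Fisher z for
  correlations and t intervals for regression coefficients; statistics
  are computed per replicate and then averaged, never pooled.
* Ties in EBV ranking are broken by order of appearance (`order()`),
  which is deterministic.
* Degenerate inputs (monomorphic panels, singular core blocks, empty
  training sets, unsorted pedigrees) raise errors rather than limping on.

## Known limitations

* **Absolute-scale statistics do not transfer to desk scale.** The
  mean-based tuning is nearly inert at full scale (the means of $G$ and
  $A_{22}$ among tens of thousands of genotyped animals on a 23 Morgan
  map differ little, so $c \approx 0$ and $d \approx 1$), but on the desk
  profile's short, drift-heavy map the genomic mean among genotyped
  animals exceeds the pedigree mean by about 0.5, giving $c \approx -0.5$
  and $d \approx 1.25$. The $d$-inflation propagates into the back-solved
  effects and lifts the mean IP above the mean benchmark GEBV by 1–1.5
  phenotypic SD (setting $c = 0, d = 1$ restores the training-level
  identity and near-zero bias, confirming the mechanism). RMSE and
  standardized bias are dominated by that mean gap, so they reproduce the
  full-scale study's ordering only partially and its magnitudes not at
  all, and the RMSE ladder can even lose monotonicity (errors first
  shrink the gap before overwhelming it). Correlations, regression
  slopes and variance ratios — the scale-free statistics — reproduce
  closely. The tuning formula is kept as published in preference to the
  absolute-scale statistics.
* EBV-based selection refits a pedigree BLUP each generation; at very
  large configurations this is the slowest simulator stage.
* Single trait, mean-only fixed effects, known variance components — by
  design; none of the published comparisons require more.
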