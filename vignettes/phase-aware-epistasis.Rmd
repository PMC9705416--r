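---
title: "Phase-aware epistasis models for case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-aware epistasis models for case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiphase)
```

## The statistical problem

Marginal single-variant tests leave part of the heritability of complex
binary traits unexplained, and one candidate explanation is epistasis: the
effect of a risk allele at one locus depends on the genotype at another.
With phased genotypes an interaction can be resolved one level deeper than
with genotype dosages alone, because the two risk alleles of a
double heterozygote either ride on the same inherited haplotype (*cis*) or
on opposite haplotypes (*trans*), and these configurations can carry
different risk. epiphase implements a scan for such interactions between a
*lead* variant (the strongest marginal signal of a region) and every other
common variant in a search window such as a topologically associating
domain.

## Encodings

For sample $i$ and variant $j$, with a chosen *counted* allele (by default
the minor allele of the loaded sample, configurable per variant and always
recorded), we use

* $A_i^j \in \{0,1,2\}$ — additive dosage of the counted allele,
* $D_i^j \in \{0,1\}$ — heterozygote indicator (dominance deviation),
* $H_i^{j,1}, H_i^{j,2} \in \{0,1\}$ — counted-allele indicators on the
  two inherited haplotypes, with $H^{j,1}_i + H^{j,2}_i = A^j_i$ wherever
  phase is available.

The dominance-deviation coding (heterozygote indicator rather than carrier
indicator) is used because, together with $A$, it spans the same model
space while staying orthogonal to $A$ under Hardy–Weinberg equilibrium.
Haplotype labels 1/2 are arbitrary; every downstream quantity is invariant
to swapping them jointly at all variants, which the test suite asserts.

## The model family

All models are logistic regressions of case status $y_i$ with principal
components PC1 and PC2 as population-structure covariates. The marginal
model per variant is

$$\mathrm{logit}\,p_i = \alpha_0 + \alpha_1 \mathrm{PC1}_i +
\alpha_2 \mathrm{PC2}_i + \gamma_1 A_i^j + \gamma_2 D_i^j,$$

tested against the covariate-only null with a 2-df likelihood-ratio test
(LRT). The conditional scan adds the lead variant's $A, D$ to both models
and again tests the candidate's $A, D$ jointly (2 df; the reference
describing this analysis does not pin the df, and the 2-df added-terms
formulation is the one coherent nesting of the printed models, so it is
the package's choice).

For a lead/partner pair the *base* interaction-free model carries the
covariates and both variants' $A, D$. The four epistasis models extend it
with:

| model | added term(s) | df |
|---|---|---|
| phase-independent | $\beta_1 A^{lead} A^{j}$ | 1 |
| cis | $\beta_1 (H^{lead,1}H^{j,1} + H^{lead,2}H^{j,2})$ | 1 |
| trans | $\beta_1 (H^{lead,1}H^{j,2} + H^{lead,2}H^{j,1})$ | 1 |
| cis & trans (C&T) | both, with free $\beta_1, \beta_2$ | 2 |

The cis and trans products each lie in $\{0,1,2\}$ and satisfy the
decomposition identity $\mathrm{cis} + \mathrm{trans} = A^{lead}A^{j}$, so
the phase-independent model is exactly the C&T model constrained to
$\beta_1 = \beta_2$, and the log-likelihoods obey
$\ell_{C\&T} \ge \max(\ell_{cis}, \ell_{trans}, \ell_{PI}) \ge \ell_{base}$
on every dataset. Haplotype models use only samples phased at both
variants (complete-case per pair) and are refused across contigs, where
statistical phasing is unreliable; cross-locus scans therefore run the
phase-independent model only.

## Multiple testing

Variants in a region are correlated through linkage disequilibrium (LD),
so a raw Bonferroni correction over all tests is conservative. The
package estimates the effective number of independent tests from the
eigenvalues $\lambda_k$ of the Pearson correlation matrix of additive
dosages as

$$M_{\mathrm{eff}} = \sum_k \big[ I(\lambda_k \ge 1) +
(\lambda_k - \lfloor \lambda_k \rfloor) \big],$$

the Li & Ji (2005) estimator, and uses $\alpha / M_{\mathrm{eff}}$ as the
per-test threshold. Signed correlations (not $|r|$ or $r^2$) enter the
spectrum, matching the standard formulation; $M_{\mathrm{eff}}$ is
computed on the MAF-filtered set actually tested. Numerically, eigenvalues
within $10^{-9}$ of an integer are snapped to it before the step function
is applied, because $f(\lambda)$ is discontinuous at integers and exact
duplicate variants otherwise land on the wrong side through floating-point
error; negative eigenvalues beyond $-10^{-10}$ are an error, smaller ones
are clipped to zero.

## Fitting and inference

Maximum likelihood is by iteratively reweighted least squares with a
convergence tolerance of $10^{-10}$ on the deviance and at most 100
iterations. Rank-deficient designs and degenerate (constant) interaction
columns raise typed errors that scans convert into NA rows carrying the
reason, so a single collinear pair never kills a region-wide scan.
Complete separation is flagged when any coefficient magnitude exceeds 15
(on encoded regressors, whose scale is bounded, a genuine odds ratio of
$e^{15}$ is not meaningful); flagged fits are reported, never silently
returned. No penalized refit is applied by default, matching the plain
logistic formulation of the models above.

The descriptive genotype log-odds table (the companion to the model fits)
uses raw counts with the Haldane–Anscombe correction,
$\log\{(\text{cases}+0.5)/(\text{controls}+0.5)\}$, rather than model
predictions: it is meant as an unadjusted picture robust to empty cells,
which are reported as NA rows with zero counts rather than dropped.

The variance-explained gain of an interaction term is reported as the
difference in Nagelkerke pseudo-$R^2$ between the base and epistasis fits,
optionally mapped to the liability scale with the Lee et al. case-control
transformation when a population prevalence is supplied. Both labels are
embedded in the output; this is a descriptive summary, not a heritability
estimate.

## The synthetic cohort generator

Because no individual-level cohort ships with the package, every
calibration and power statement rests on the generator, which emulates
exactly the assumptions of the model family:

* haplotypes are drawn i.i.d. per individual (two per person) from small
  *pools* — discrete haplotype distributions per LD block; two-SNP blocks
  are constructed from target MAFs and a target $r^2$ by solving
  $D = \sqrt{r^2\,p(1-p)q(1-q)}$ with positive-$D$ orientation, and
  infeasible requests fail with the maximum attainable $r^2$ named;
  multi-block pools are concatenations of independent blocks;
* population structure is two (or more) subpopulations with their own
  pools; PC covariates are generated as the centered subpopulation
  indicator plus Gaussian noise (sd 0.1) — a deliberately simple stand-in
  for genotype PCA, sufficient because the PCs act only as nuisance
  covariates in every model;
* disease status is Bernoulli with the logit given by the configured
  model (intercept, PC effects, main effects, and one of the four
  interaction mechanisms), so generative truth and analysis model share
  one parameterization and parameter recovery is well defined;
* case-control ascertainment resamples in batches until the requested
  case/control counts are reached, with a patience bound (default $10^7$
  draws) that turns an unreachable quota into an explicit error.

Consequences worth stating: genotypes are in Hardy–Weinberg equilibrium
within subpopulations by construction, LD decays only within blocks, and
there is no phasing error, genotyping error, or missingness unless
injected. Passing calibration on these data shows the statistics are
correct under the model's own assumptions; it does not certify behaviour
under phasing error or cryptic relatedness, which real cohorts have and
the generator deliberately omits.

Default study conditions used by the calibration suites: a lead variant
with MAF 0.35 and additive log-odds 0.4–0.5 (a common, strongly
associated enhancer-variant profile), partner MAF 0.30, baseline
intercept $-1$ (cohort prevalence near 0.3), interaction effects
$\beta_1 = 0.8$ at $n = 5000$ for recovery studies and $\beta_1 = 1.0$ at
$n = 6000$ for the end-to-end fixture, null panels of $n = 2000$ with
1000 (test suite) or 500 (acceptance script) replicates, and LD-fidelity
checks at $n = 50{,}000$. These sizes keep each suite in the minutes
range on a single core while leaving Monte-Carlo error well below the
margins being asserted.

## LD utilities

$r^2$ is computed haplotype-based ($D^2/(p(1-p)q(1-q))$ from phased
haplotype counts) when phase is available, falling back to the squared
dosage correlation (composite LD) otherwise; the estimator used is
recorded on the result. Significant hits are grouped by single-linkage
clustering at $r^2 \ge 0.8$ — the reference analysis reports LD clusters
without stating a rule, so the threshold is explicit and configurable
here — with each cluster represented by its smallest-p member. Proxy
selection for replication panels maximizes reference $r^2$ per target
(ties by physical proximity, then id) and flags mappings below 0.8 as
weak rather than refusing them.

## Secondary (conditional) epistasis

To ask whether a detected variant has a role beyond the top epistatic
variant, both the null and the alternative model carry the top variant's
main effects *and* its interaction with the lead (in the same model kind
as the candidate's best model); the alternative adds the candidate's own
interaction term. Conditioning on the top variant's main effects alone
would leave shared interaction signal in the null and overstate
independence, which is why the interaction term is included — the precise
formulation is this package's design choice and is stated in outputs
rather than asserted as anyone else's.

## Known limitations

* Hard genotype calls only; no dosage/imputation support.
* Two-locus interactions only, one lead at a time.
* The generator's LD structure is blockwise; long-range decay and
  recombination gradients are not emulated.
* Complete-case handling per test assumes missingness unrelated to
  genotype and phenotype.
* The liability-scale transform assumes the standard threshold model and
  a user-supplied prevalence; it is reported alongside, never used for
  inference.
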