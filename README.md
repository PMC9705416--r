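# epiphase

Phase-aware SNP×SNP epistasis scanning for phased case-control cohorts.

## What problem this solves

In regions where a single *lead* variant dominates the association signal
(for example a strong enhancer variant), part of the residual risk can come
from interactions between the lead and other nearby variants. With phased
genotypes such interactions can be resolved below the genotype level: in a
double heterozygote the two risk alleles sit either on the same inherited
haplotype (*cis*) or on opposite haplotypes (*trans*), and those two
configurations can carry different risk. epiphase fits, for every candidate
variant *j* against the lead, four logistic interaction models on top of a
shared base model
(intercept + PC1 + PC2 + A<sup>lead</sup> + D<sup>lead</sup> + A<sup>j</sup> + D<sup>j</sup>,
with A the additive dosage and D the heterozygote indicator):

| model | interaction term | LRT df |
|---|---|---|
| phase-independent | β₁ A<sup>lead</sup>A<sup>j</sup> | 1 |
| cis | β₁ (H<sup>lead,1</sup>H<sup>j,1</sup> + H<sup>lead,2</sup>H<sup>j,2</sup>) | 1 |
| trans | β₁ (H<sup>lead,1</sup>H<sup>j,2</sup> + H<sup>lead,2</sup>H<sup>j,1</sup>) | 1 |
| cis & trans (C&T) | both terms, free β₁, β₂ | 2 |

H<sup>·,1</sup>, H<sup>·,2</sup> are counted-allele indicators on the two
haplotypes (H¹ + H² = A). Since cis + trans = A<sup>lead</sup>A<sup>j</sup>,
the phase-independent model is the C&T model constrained to β₁ = β₂.
Inference is by likelihood-ratio test against the base model; the
region-wide significance threshold is α divided by the effective number of
independent tests (Li & Ji eigenvalue estimator) to account for LD between
tested variants. The package also provides marginal and conditional
single-variant scans, lead selection, LD clustering and proxy selection,
secondary (conditional) epistasis analysis, a descriptive genotype
log-odds table that splits double heterozygotes into cis/trans
configurations, and a synthetic phased-cohort generator used for all
calibration.

Intended users: statistical geneticists analysing phased case-control
sequence data in a bounded region (e.g. a TAD), and method developers who
need a calibrated, fully simulatable reference implementation of
haplotype-resolved interaction tests.

## Worked example

Simulate a cohort with a cis interaction (β₁ = 0.8) between a lead variant
(MAF 0.35) and a partner (MAF 0.30), plus an unrelated LD block, then scan:

```r
library(epiphase)

pool <- pool_blocks(
  build_two_snp_pool(0.35, 0.30, 0.10, loci = c("lead", "partner")),
  build_two_snp_pool(0.20, 0.20, 0.90, loci = c("s1", "s2")))
cfg <- sim_config(pool, n_samples = 4000, intercept = -1,
                  main_effects = c(lead_add = 0.4),
                  mechanism = "cis", beta1 = 0.8, seed = 11)
sim <- simulate_cohort(cfg)

scan <- epistasis_scan(sim$geno, "lead", sim$phenotype, sim$covariates)
scan
#> <epistasis_scan> lead = lead | 3 variants | Meff = 4 | threshold = 0.0125
#> significant (any model): 1
scan$table[, c("id", "p_cis", "p_trans", "best_model", "sig_any")]
#>        id    p_cis p_trans best_model sig_any
#> 1 partner 1.50e-16  0.0948        cis    TRUE
#> 2      s1 1.15e-01  0.7263        cis   FALSE
#> 3      s2 1.11e-01  0.5906        cis   FALSE
```

The planted partner is detected far below the Meff-adjusted threshold, the
cis model fits best (the data were generated cis), and the unrelated block
stays null. The descriptive log-odds table shows the same mechanism in the
raw counts — among lead heterozygotes, the cis-configured double
heterozygotes carry higher risk than the trans-configured ones:

```r
tab <- genotype_logodds_table(sim$phenotype,
                              encode_variant(sim$geno, "lead"),
                              encode_variant(sim$geno, "partner"))
subset(tab, lead_geno == "1")
#>   lead_geno  j_geno n_cases n_controls log_odds   ci_lo  ci_hi
#> 2         1       0     252        458   -0.597 -0.7501 -0.443
#> 6         1   1_cis     398        316    0.230  0.0828  0.378
#> 7         1 1_trans      55        123   -0.800 -1.1166 -0.483
#> 9         1       2     101         73    0.323  0.0226  0.623
```

The full pipeline (VCF in, TSV + JSON manifest out) is available as
`run_simulate()` / `run_scan()`, or from a shell via the thin wrapper
`inst/cli/epiphase.R` (subcommands `simulate` and `scan`).

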