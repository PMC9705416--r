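test_that("epistasis models carry the right interaction terms and dfs", {
  sim <- cis_cohort(n = 1000, seed = 51)
  dfs <- vapply(c("phase_independent", "cis", "trans", "cis_and_trans"),
                function(m) fit_epistasis_pair(sim$geno, "lead", "partner",
                                               sim$phenotype, sim$covariates,
                                               m)$lrt$df, integer(1))
  expect_equal(unname(dfs), c(1L, 1L, 1L, 2L))
  pf <- fit_epistasis_pair(sim$geno, "lead", "partner", sim$phenotype,
                           sim$covariates, "cis_and_trans")
  expect_true(all(c("cis", "trans") %in% names(pf$fit$coefficients)))
  expect_true(all(c("A_lead", "D_lead", "A_j", "D_j") %in%
                    pf$base$term_names))
})

test_that("C&T constrained to equal coefficients matches phase-independent", {
  sim <- cis_cohort(n = 2000, seed = 52)
  el <- encode_variant(sim$geno, "lead")
  ej <- encode_variant(sim$geno, "partner")
  ct <- cis_trans_products(el, ej)
  cv <- sim$covariates[, c("PC1", "PC2")]
  base_terms <- c(as.list(cv), list(A_lead = el$A, D_lead = el$D,
                                    A_j = ej$A, D_j = ej$D))
  constrained <- fit_logistic(sim$phenotype,
                              c(base_terms, list(sum = ct$cis + ct$trans)))
  pi_fit <- fit_epistasis_pair(sim$geno, "lead", "partner", sim$phenotype,
                               cv, "phase_independent")$fit
  expect_equal(constrained$log_likelihood, pi_fit$log_likelihood,
               tolerance = 1e-8)
})

test_that("nesting chain of the four models holds on any dataset", {
  for (s in c(61, 62)) {
    sim <- cis_cohort(n = 1500, seed = s)
    fits <- lapply(setNames(nm = c("phase_independent", "cis", "trans",
                                   "cis_and_trans")),
                   function(m) fit_epistasis_pair(sim$geno, "lead", "partner",
                                                  sim$phenotype,
                                                  sim$covariates, m))
    base_ll <- fits$cis$base$log_likelihood
    ll <- vapply(fits, function(f) f$fit$log_likelihood, numeric(1))
    expect_gte(ll["cis_and_trans"], max(ll[1:3]) - 1e-8)
    expect_gte(min(ll), base_ll - 1e-8)
  }
})

test_that("degenerate pairs are flagged instead of crashing the scan", {
  sim <- cis_cohort(n = 500, seed = 53)
  g <- sim$geno
  # duplicate the lead column under a new id: lead-vs-duplicate is collinear
  dup <- phased_geno(cbind(g$hap1, g$hap1[, 1]), cbind(g$hap2, g$hap2[, 1]),
                     rbind(g$variants[, c("id", "chrom", "pos", "ref", "alt",
                                          "counted")],
                           data.frame(id = "dup", chrom = "1", pos = 99999L,
                                      ref = "A", alt = "T", counted = 1L)))
  expect_error(fit_epistasis_pair(dup, "lead", "dup", sim$phenotype,
                                  sim$covariates, "phase_independent"),
               class = "epiphase_rank_deficiency")
  sc <- suppressMessages(epistasis_scan(dup, "lead", sim$phenotype,
                                        sim$covariates))
  row <- sc$table[sc$table$id == "dup", ]
  expect_true(is.na(row$p_phase_independent))
  expect_match(row$reason_phase_independent, "collinear|rank")
})

test_that("haplotype models refuse unphased data and cross-contig pairs", {
  sim <- cis_cohort(n = 300, seed = 54)
  g <- sim$geno
  g$phased[] <- FALSE
  expect_error(fit_epistasis_pair(g, "lead", "partner", sim$phenotype,
                                  sim$covariates, "cis"),
               class = "epiphase_phase_required")
  # phase-independent still works on unphased data
  expect_s3_class(fit_epistasis_pair(g, "lead", "partner", sim$phenotype,
                                     sim$covariates,
                                     "phase_independent")$fit,
                  "epiphase_fit")
  g2 <- sim$geno
  g2$variants$chrom[2] <- "8"
  expect_error(fit_epistasis_pair(g2, "lead", "partner", sim$phenotype,
                                  sim$covariates, "cis"),
               class = "epiphase_cross_contig_phase")
})

test_that("cis-simulated data favours the cis model over trans", {
  cis_stat <- numeric(8); trans_stat <- numeric(8)
  for (s in 1:8) {
    sim <- cis_cohort(n = 2500, beta1 = 0.8, seed = 500 + s)
    cis_stat[s] <- fit_epistasis_pair(sim$geno, "lead", "partner",
                                      sim$phenotype, sim$covariates,
                                      "cis")$lrt$statistic
    trans_stat[s] <- fit_epistasis_pair(sim$geno, "lead", "partner",
                                        sim$phenotype, sim$covariates,
                                        "trans")$lrt$statistic
  }
  expect_gt(mean(cis_stat), mean(trans_stat))
  # and the scan's model ranking agrees
  sim <- cis_cohort(n = 4000, beta1 = 0.8, seed = 555)
  sc <- suppressMessages(epistasis_scan(sim$geno, "lead", sim$phenotype,
                                        sim$covariates))
  row <- sc$table[sc$table$id == "partner", ]
  expect_lt(row$p_cis, row$p_trans)
  expect_error(epistasis_scan(sim$geno, "lead", sim$phenotype,
                              sim$covariates, models = character(0)),
               "at least one")
})

test_that("cross-locus scan runs phase-independent only across contigs", {
  sim <- cis_cohort(n = 2000, seed = 56)
  ga <- subset_geno(sim$geno, variants = c("lead", "partner"))
  gb <- subset_geno(sim$geno, variants = c("s1", "s2"))
  gb$variants$chrom <- "8"
  res <- suppressMessages(cross_locus_scan(ga, "lead", gb, "s1",
                                           sim$phenotype, sim$covariates))
  expect_equal(res$b_vs_lead_a$table$id, c("s1", "s2"))
  expect_equal(res$a_vs_lead_b$table$id, c("lead", "partner"))
  expect_error(cross_locus_scan(ga, "lead", gb, "s1", sim$phenotype,
                                sim$covariates, models = "cis"),
               class = "epiphase_cross_contig_phase")
})

test_that("genotype log-odds table implements the corrected formula", {
  # constructed cells: lead hom-ref, partner hom-ref with 3 cases 1 control
  h1 <- matrix(0L, 4, 2); h2 <- matrix(0L, 4, 2)
  g <- phased_geno(h1, h2, data.frame(id = c("L", "J"), chrom = "1",
                                      pos = 1:2, ref = "A", alt = "T",
                                      counted = 1L))
  y <- c(1, 1, 1, 0)
  tab <- genotype_logodds_table(y, encode_variant(g, "L"),
                                encode_variant(g, "J"))
  cell <- tab[tab$lead_geno == "0" & tab$j_geno == "0", ]
  expect_equal(cell$log_odds, log(3.5 / 1.5))
  # all-equal cells give zero log odds; empty cells stay as NA rows
  empty <- tab[tab$lead_geno == "2" & tab$j_geno == "2", ]
  expect_true(is.na(empty$log_odds))
  expect_equal(empty$n_cases + empty$n_controls, 0)
})

test_that("log-odds table is invariant to a joint haplotype swap", {
  sim <- cis_cohort(n = 2000, beta1 = 0.8, seed = 57)
  g <- sim$geno
  swapped <- phased_geno(g$hap2, g$hap1,
                         g$variants[, c("id", "chrom", "pos", "ref", "alt",
                                        "counted")])
  t1 <- genotype_logodds_table(sim$phenotype, encode_variant(g, "lead"),
                               encode_variant(g, "partner"))
  t2 <- genotype_logodds_table(sim$phenotype,
                               encode_variant(swapped, "lead"),
                               encode_variant(swapped, "partner"))
  expect_equal(t1, t2)
})

test_that("variance-explained gain is zero for identical fits, positive for real epistasis", {
  sim <- cis_cohort(n = 4000, beta1 = 0.8, seed = 58)
  pf <- fit_epistasis_pair(sim$geno, "lead", "partner", sim$phenotype,
                           sim$covariates, "cis")
  same <- variance_explained_gain(pf$fit, pf$fit)
  expect_equal(same$gain, 0)
  gain <- variance_explained_gain(pf$base, pf$fit, prevalence = 0.0002)
  expect_gt(gain$gain, 0)
  expect_equal(gain$method, "nagelkerke")
  expect_lt(gain$liability$gain, gain$gain)  # rare-disease shrinkage
  expect_error(variance_explained_gain(pf$fit, pf$base), "nested")
})

test_that("secondary epistasis removes LD shadows, keeps independent signals", {
  # two genuinely independent interactions with the lead
  blocks <- pool_blocks(
    haplotype_pool(matrix(c(1L, 0L), 2, 1), c(0.35, 0.65), loci = "lead"),
    haplotype_pool(matrix(c(1L, 0L), 2, 1), c(0.3, 0.7), loci = "p1"),
    haplotype_pool(matrix(c(1L, 0L), 2, 1), c(0.3, 0.7), loci = "p2"))
  cfg <- sim_config(blocks, n_samples = 6000, intercept = -1,
                    main_effects = c(lead_add = 0.4),
                    mechanism = "phase_independent", beta1 = 0.7,
                    lead = "lead", partner = "p1", seed = 59)
  sim <- simulate_cohort(cfg)
  # plant the second interaction by re-simulating the phenotype with both
  el <- encode_variant(sim$geno, "lead")
  e1 <- encode_variant(sim$geno, "p1")
  e2 <- encode_variant(sim$geno, "p2")
  set.seed(590)
  eta <- -1 + 0.4 * el$A + 0.7 * el$A * e1$A + 0.7 * el$A * e2$A
  y <- rbinom(length(eta), 1, 1 / (1 + exp(-eta)))
  sec <- secondary_epistasis(sim$geno, "lead", top = "p1",
                             candidates = c("p2"), y, sim$covariates,
                             models = "phase_independent")
  expect_lt(sec$p[sec$id == "p2"], 1e-3)   # independent signal survives
})

test_that("secondary epistasis flags or nullifies perfect-LD candidates", {
  sim <- simulate_cohort(planted_fixture_config(n = 4000, seed = 60))
  pf <- secondary_epistasis(sim$geno, "lead", top = "partner",
                            candidates = c("shadow1", "shadow2"),
                            sim$phenotype, sim$covariates, models = "cis")
  for (i in seq_len(nrow(pf)))
    expect_true(is.na(pf$p[i]) || pf$p[i] > 1e-3)
})
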