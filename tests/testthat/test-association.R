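test_that("intercept-only fit reproduces the closed-form likelihood", {
  y <- rep(c(1, 0), each = 50)
  f <- fit_logistic(y)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-8)
  expect_equal(f$log_likelihood, 100 * log(0.5), tolerance = 1e-10)
  expect_equal(f$aic, 2 - 2 * f$log_likelihood)
  expect_equal(f$bic, log(100) - 2 * f$log_likelihood)
  expect_true(f$converged)
  expect_false(f$separation_detected)
})

test_that("degenerate designs raise informative errors", {
  y <- rep(c(1, 0), each = 20)
  expect_error(fit_logistic(rep(1, 40), list(x = rnorm(40))),
               class = "epiphase_degenerate_response")
  expect_error(fit_logistic(y, list(const = rep(2, 40))),
               class = "epiphase_degenerate_term")
  x <- rnorm(40)
  err <- tryCatch(fit_logistic(y, list(a = x, b = 2 * x)),
                  error = function(e) e)
  expect_s3_class(err, "epiphase_rank_deficiency")
  expect_match(conditionMessage(err), "b")
})

test_that("perfect separation is flagged, not silently returned", {
  y <- rep(c(1, 0), each = 20)
  set.seed(29)
  x <- c(rnorm(20, 1, 0.1), rnorm(20, -1, 0.1))
  f <- fit_logistic(y, list(x = x))
  expect_true(f$separation_detected)
})

test_that("coefficients match an independent Newton-Raphson oracle", {
  for (s in 1:20) {
    d <- random_logit_data(n = sample(30:50, 1), k = sample(1:3, 1),
                           seed = 100 + s)
    f <- tryCatch(fit_logistic(d$y, as.data.frame(d$X)),
                  error = function(e) NULL)
    if (is.null(f) || f$separation_detected) next
    o <- nr_logistic(d$y, d$X)
    expect_equal(unname(f$coefficients), unname(o$coef), tolerance = 1e-6)
    expect_equal(f$log_likelihood, o$ll, tolerance = 1e-8)
  }
})

test_that("LRT machinery respects nesting, df and the chi-square null", {
  y <- rep(c(1, 0), each = 30)
  x <- rnorm(60); z <- rnorm(60)
  f0 <- fit_logistic(y)
  f1 <- fit_logistic(y, list(x = x))
  f2 <- fit_logistic(y, list(x = x, z = z))
  t01 <- lrt(f0, f1); t02 <- lrt(f0, f2)
  expect_equal(t01$df, 1); expect_equal(t02$df, 2)
  expect_gte(t01$statistic, 0)
  # identical models: statistic 0, p 1
  tsame <- lrt(f1, f1)
  expect_equal(tsame$statistic, 0)
  expect_equal(tsame$p_value, 1)
  # non-nested pairs refuse
  expect_error(lrt(fit_logistic(y, list(w = rnorm(60))), f1), "nested")
  # likelihood monotonicity under nesting
  expect_gte(f2$log_likelihood, f1$log_likelihood - 1e-10)
  expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-10)
})

test_that("null LRT p-values are uniform", {
  set.seed(77)
  pv <- replicate(400, {
    y <- rbinom(400, 1, 0.4)
    x <- rnorm(400)
    lrt(fit_logistic(y), fit_logistic(y, list(x = x)))$p_value
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
})

test_that("marginal scan finds a real additive effect and ranks the lead", {
  sim <- cis_cohort(n = 4000, beta1 = 0, seed = 21)
  ms <- suppressMessages(marginal_scan(sim$geno, sim$phenotype,
                                       sim$covariates))
  expect_equal(ms$id, sim$geno$variants$id[order(sim$geno$variants$pos)])
  expect_equal(ms$df, rep(2L, 4))
  expect_lt(ms$p[ms$id == "lead"], 1e-4)
  expect_equal(select_lead_variant(ms)$id, "lead")
  # override pins a named variant regardless of p
  expect_equal(select_lead_variant(ms, override = "s1")$id, "s1")
  expect_error(select_lead_variant(ms, override = "nope"), "override")
})

test_that("lead selection ties break by position then id", {
  tab <- data.frame(id = c("b", "a"), pos = c(200L, 100L), p = c(1e-5, 1e-5))
  expect_equal(select_lead_variant(tab)$id, "a")
  tab2 <- data.frame(id = c("b", "a"), pos = c(100L, 100L), p = c(1e-5, 1e-5))
  expect_equal(select_lead_variant(tab2)$id, "a")
  expect_error(select_lead_variant(data.frame(id = "x", pos = 1L,
                                              p = NA_real_)), "no testable")
})

test_that("marginal scan p-values are invariant to allele orientation", {
  sim <- cis_cohort(n = 800, seed = 23)
  g <- sim$geno
  ms1 <- suppressMessages(marginal_scan(g, sim$phenotype, sim$covariates))
  g$variants$counted <- 1L - g$variants$counted
  ms2 <- suppressMessages(marginal_scan(g, sim$phenotype, sim$covariates))
  expect_equal(ms1$p, ms2$p, tolerance = 1e-8)
})

test_that("conditional scan neutralizes LD proxies but not real signals", {
  # partner in strong LD with the lead shares its signal
  blocks <- pool_blocks(
    build_two_snp_pool(0.35, 0.35, 0.95, loci = c("lead", "proxy")),
    build_two_snp_pool(0.3, 0.3, 0, loci = c("own", "null")))
  cfg <- sim_config(blocks, n_samples = 5000, intercept = -1,
                    main_effects = c(lead_add = 0.5, partner_add = 0.4),
                    lead = "lead", partner = "own", seed = 31)
  sim <- simulate_cohort(cfg)
  cs <- suppressMessages(conditional_scan(sim$geno, sim$phenotype,
                                          sim$covariates, "lead"))
  expect_false("lead" %in% cs$id)
  expect_gt(cs$p[cs$id == "proxy"], 0.01)   # proxy signal absorbed by lead
  expect_lt(cs$p[cs$id == "own"], 1e-4)     # independent signal survives
})

test_that("PCA covariates separate simulated subpopulations", {
  pools <- list(
    pool_blocks(lapply(1:6, function(i)
      build_two_snp_pool(0.1, 0.1, 0, loci = paste0("v", i, c("a", "b"))))),
    pool_blocks(lapply(1:6, function(i)
      build_two_snp_pool(0.45, 0.45, 0, loci = paste0("v", i, c("a", "b"))))))
  cfg <- sim_config(pools, n_samples = 600, subpop_weights = c(0.5, 0.5),
                    seed = 41)
  sim <- simulate_cohort(cfg)
  pcs <- compute_pcs(sim$geno, k = 2)
  r <- cor(pcs$PC1, as.numeric(sim$truth$subpop == 2))
  expect_gt(abs(r), 0.9)
  # duplicate samples get identical scores
  dup <- subset_geno(sim$geno, samples = c(1, 1, 2:100))
  pd <- compute_pcs(dup, k = 2)
  expect_equal(pd[1, ], pd[2, ], ignore_attr = TRUE)
  # k = 0 yields an empty covariate set
  expect_equal(ncol(compute_pcs(sim$geno, k = 0)), 0)
  expect_error(compute_pcs(subset_geno(sim$geno, variants = 1), k = 2),
               "too few|at least|components")
})
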