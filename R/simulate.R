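#' Simulation configuration for a phased case-control cohort
#'
#' Bundles the generative ingredients: per-subpopulation haplotype pools,
#' subpopulation weights, sample size, and the coefficients of the logistic
#' disease model — intercept, PC covariate effects, additive/dominance main
#' effects at a lead and a partner locus, and an interaction acting through
#' one of four mechanisms (`phase_independent`, `cis`, `trans`,
#' `cis_and_trans`) or `none`.
#'
#' The disease model is
#' logit p = a0 + a1 PC1 + a2 PC2 + g1 A_lead + g2 D_lead + g3 A_j + g4 D_j
#'           + interaction,
#' where the interaction term is A_lead*A_j (phase-independent),
#' H1H1 + H2H2 (cis), H1H2 + H2H1 (trans), or both with separate
#' coefficients (cis-and-trans).
#'
#' @param pools a `haplotype_pool`, a `pool_blocks`, or a list of one of
#'   those per subpopulation.
#' @param n_samples number of individuals (ignored under case-control
#'   ascertainment).
#' @param intercept baseline log-odds a0.
#' @param pc_effects length-2 numeric, effects of PC1 and PC2.
#' @param main_effects named numeric: `lead_add`, `lead_dom`, `partner_add`,
#'   `partner_dom` (missing names default to 0).
#' @param mechanism interaction mechanism tag.
#' @param beta1 interaction log-odds (cis coefficient for `cis_and_trans`).
#' @param beta2 trans coefficient, `cis_and_trans` only.
#' @param lead,partner locus labels of the interacting pair (defaults: first
#'   two loci of the first pool).
#' @param subpop_weights subpopulation sampling probabilities (sum to 1).
#' @param seed integer RNG seed.
#' @param ascertainment `list(type = "cohort")` or
#'   `list(type = "case_control", n_cases =, n_controls =)`; the latter
#'   accepts an optional `patience` bound on total draws (default 1e7)
#'   after which sampling aborts with a simulation-exhausted error.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(pools, n_samples,
                       intercept = 0, pc_effects = c(0, 0),
                       main_effects = c(lead_add = 0, lead_dom = 0,
                                        partner_add = 0, partner_dom = 0),
                       mechanism = c("none", "phase_independent", "cis",
                                     "trans", "cis_and_trans"),
                       beta1 = 0, beta2 = NULL,
                       lead = NULL, partner = NULL,
                       subpop_weights = NULL, seed = 1,
                       ascertainment = list(type = "cohort")) {
  mechanism <- match.arg(mechanism)
  if (inherits(pools, "haplotype_pool") || inherits(pools, "pool_blocks"))
    pools <- list(pools)
  pools <- lapply(pools, function(p)
    if (inherits(p, "haplotype_pool")) pool_blocks(list(p)) else p)
  if (is.null(subpop_weights)) subpop_weights <- rep(1, length(pools))
  subpop_weights <- subpop_weights / sum(subpop_weights)
  if (length(subpop_weights) != length(pools))
    stop("one weight per subpopulation pool required")
  loci <- unlist(lapply(pools[[1]], `[[`, "loci"))
  for (p in pools)
    if (!identical(unlist(lapply(p, `[[`, "loci")), loci))
      stop("all subpopulation pools must share the same loci")
  if (is.null(lead)) lead <- loci[1]
  if (is.null(partner)) partner <- if (length(loci) > 1) loci[2] else loci[1]
  if (!all(c(lead, partner) %in% loci)) stop("lead/partner not in pool loci")
  me <- c(lead_add = 0, lead_dom = 0, partner_add = 0, partner_dom = 0)
  me[names(main_effects)] <- main_effects
  if (mechanism == "cis_and_trans" && is.null(beta2))
    stop("cis_and_trans mechanism requires beta2")
  if (mechanism != "cis_and_trans") beta2 <- NULL
  if (!ascertainment$type %in% c("cohort", "case_control"))
    stop("unknown ascertainment type")
  if (ascertainment$type == "cohort" &&
      (length(n_samples) != 1 || n_samples <= 0))
    stop("n_samples must be a positive count")
  structure(list(pools = pools, subpop_weights = subpop_weights,
                 n_samples = n_samples, intercept = intercept,
                 pc_effects = pc_effects, main_effects = me,
                 mechanism = mechanism, beta1 = beta1, beta2 = beta2,
                 lead = lead, partner = partner, seed = as.integer(seed),
                 ascertainment = ascertainment),
            class = "sim_config")
}

# draw n individuals: haplotypes per block, subpopulation, PCs, disease status
.draw_batch <- function(config, n) {
  k <- length(config$pools)
  sub <- sample.int(k, n, replace = TRUE, prob = config$subpop_weights)
  m <- length(unlist(lapply(config$pools[[1]], `[[`, "loci")))
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  for (s in seq_len(k)) {
    rows <- which(sub == s)
    if (!length(rows)) next
    col <- 1L
    for (block in config$pools[[s]]) {
      nl <- length(block$loci)
      i1 <- sample.int(nrow(block$haplotypes), length(rows), replace = TRUE,
                       prob = block$frequencies)
      i2 <- sample.int(nrow(block$haplotypes), length(rows), replace = TRUE,
                       prob = block$frequencies)
      h1[rows, col:(col + nl - 1L)] <- block$haplotypes[i1, , drop = FALSE]
      h2[rows, col:(col + nl - 1L)] <- block$haplotypes[i2, , drop = FALSE]
      col <- col + nl
    }
  }
  # PC1 tracks subpopulation 2 membership (centered by its expected weight);
  # PC2 is pure noise -- both stand in for genotype-PCA nuisance covariates
  w2 <- if (k > 1) config$subpop_weights[2] else 0
  pc1 <- (if (k > 1) as.numeric(sub == 2L) - w2 else rep(0, n)) +
    rnorm(n, sd = 0.1)
  pc2 <- rnorm(n, sd = 0.1)
  loci <- unlist(lapply(config$pools[[1]], `[[`, "loci"))
  li <- match(config$lead, loci); pi <- match(config$partner, loci)
  al <- h1[, li] + h2[, li]; ap <- h1[, pi] + h2[, pi]
  dl <- as.numeric(al == 1L); dp <- as.numeric(ap == 1L)
  cis <- h1[, li] * h1[, pi] + h2[, li] * h2[, pi]
  trans <- h1[, li] * h2[, pi] + h2[, li] * h1[, pi]
  inter <- switch(config$mechanism,
    none = 0,
    phase_independent = config$beta1 * al * ap,
    cis = config$beta1 * cis,
    trans = config$beta1 * trans,
    cis_and_trans = config$beta1 * cis + config$beta2 * trans)
  eta <- config$intercept + config$pc_effects[1] * pc1 +
    config$pc_effects[2] * pc2 +
    config$main_effects["lead_add"] * al +
    config$main_effects["lead_dom"] * dl +
    config$main_effects["partner_add"] * ap +
    config$main_effects["partner_dom"] * dp + inter
  y <- rbinom(n, 1L, 1 / (1 + exp(-eta)))
  list(h1 = h1, h2 = h2, sub = sub, pc1 = pc1, pc2 = pc2, y = y)
}

#' Simulate a phased case-control cohort
#'
#' Each individual draws a subpopulation, then two independent haplotypes
#' (maternal = H1, paternal = H2) per LD block from that subpopulation's
#' pool; PC covariates derive from subpopulation membership plus Gaussian
#' noise (sd 0.1); disease status is Bernoulli with the configured logistic
#' model. Under case-control ascertainment, sampling continues in batches
#' until the requested case and control counts are reached (patience bound
#' 1e7 draws).
#'
#' @param config a `sim_config`.
#' @return list with `geno` (a [phased_geno]), `phenotype` (0/1 vector),
#'   `covariates` (data.frame: sample_id, status, PC1, PC2), and `truth`
#'   (the configuration's coefficients echoed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  asc <- config$ascertainment
  if (asc$type == "cohort") {
    b <- .draw_batch(config, config$n_samples)
  } else {
    need_ca <- asc$n_cases; need_co <- asc$n_controls
    got <- NULL; drawn <- 0L
    patience <- if (is.null(asc$patience)) 1e7 else asc$patience
    batch_n <- max(1000L, 2L * (need_ca + need_co))
    while (is.null(got) ||
           sum(got$y == 1L) < need_ca || sum(got$y == 0L) < need_co) {
      if (drawn >= patience)
        stop("simulation exhausted: case/control quota unreachable after ",
             patience, " draws")
      nb <- .draw_batch(config, batch_n)
      drawn <- drawn + batch_n
      got <- if (is.null(got)) nb else
        Map(function(a, b) if (is.matrix(a)) rbind(a, b) else c(a, b), got, nb)
    }
    keep <- c(head(which(got$y == 1L), need_ca),
              head(which(got$y == 0L), need_co))
    keep <- sort(keep)
    b <- lapply(got, function(x)
      if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep])
  }
  loci <- unlist(lapply(config$pools[[1]], `[[`, "loci"))
  variants <- data.frame(
    id = loci, chrom = "1", pos = 10000L + 1000L * seq_along(loci),
    ref = "A", alt = "T", counted = 1L, stringsAsFactors = FALSE)
  geno <- phased_geno(b$h1, b$h2, variants,
                      samples = sprintf("S%05d", seq_along(b$y)))
  covariates <- data.frame(sample_id = geno$samples, status = b$y,
                           PC1 = b$pc1, PC2 = b$pc2,
                           stringsAsFactors = FALSE)
  truth <- list(intercept = config$intercept,
                pc_effects = config$pc_effects,
                main_effects = as.list(config$main_effects),
                mechanism = config$mechanism,
                beta1 = config$beta1, beta2 = config$beta2,
                lead = config$lead, partner = config$partner,
                seed = config$seed,
                subpop_weights = config$subpop_weights,
                subpop = b$sub)
  list(geno = geno, phenotype = b$y, covariates = covariates, truth = truth)
}

#' Simulate a null scan panel around an associated lead variant
#'
#' Generates a panel in which the lead variant carries a real additive main
#' effect and every other variant has zero main and interaction effect and is
#' in linkage equilibrium with the lead — the reference dataset for type-I
#' error calibration of the epistasis scan.
#'
#' @param n_variants total number of variants (lead included), >= 2.
#' @param n_samples number of individuals.
#' @param seed integer RNG seed.
#' @param lead_maf lead-variant MAF (default 0.35).
#' @param lead_beta lead additive log-odds effect (default 0.5).
#' @param maf_range range the null-variant MAFs are drawn from.
#' @param intercept baseline log-odds.
#' @return same structure as [simulate_cohort()].
#' @export
simulate_null_scan_panel <- function(n_variants, n_samples, seed = 1,
                                     lead_maf = 0.35, lead_beta = 0.5,
                                     maf_range = c(0.05, 0.5),
                                     intercept = 0) {
  if (n_variants < 2) stop("n_variants must be >= 2")
  set.seed(seed)
  mafs <- c(lead_maf, runif(n_variants - 1, maf_range[1], maf_range[2]))
  h1 <- vapply(mafs, function(p) rbinom(n_samples, 1L, p),
               integer(n_samples))
  h2 <- vapply(mafs, function(p) rbinom(n_samples, 1L, p),
               integer(n_samples))
  eta <- intercept + lead_beta * (h1[, 1] + h2[, 1])
  y <- rbinom(n_samples, 1L, 1 / (1 + exp(-eta)))
  ids <- c("lead", sprintf("null%03d", seq_len(n_variants - 1)))
  variants <- data.frame(
    id = ids, chrom = "1", pos = 10000L + 1000L * seq_len(n_variants),
    ref = "A", alt = "T", counted = 1L, stringsAsFactors = FALSE)
  geno <- phased_geno(h1, h2, variants,
                      samples = sprintf("S%05d", seq_len(n_samples)))
  covariates <- data.frame(sample_id = geno$samples, status = y,
                           PC1 = rnorm(n_samples, sd = 0.1),
                           PC2 = rnorm(n_samples, sd = 0.1),
                           stringsAsFactors = FALSE)
  list(geno = geno, phenotype = y, covariates = covariates,
       truth = list(lead = "lead", lead_maf = lead_maf,
                    lead_beta = lead_beta, intercept = intercept,
                    seed = seed, null_mafs = mafs[-1]))
}
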