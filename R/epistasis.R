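.EPI_MODELS <- c("phase_independent", "cis", "trans", "cis_and_trans")

# interaction term(s) for a lead/partner encoding pair under one model kind
.interaction_terms <- function(el, ej, model) {
  switch(model,
    phase_independent = list(AxA = el$A * ej$A),
    cis = list(cis = cis_trans_products(el, ej)$cis),
    trans = list(trans = cis_trans_products(el, ej)$trans),
    cis_and_trans = {
      ct <- cis_trans_products(el, ej)
      list(cis = ct$cis, trans = ct$trans)
    },
    stop("unknown epistasis model: ", model))
}

# shared pair-fitting core on pre-built encodings
.pair_fit <- function(el, ej, phenotype, cv, model, extra_terms = NULL) {
  inter <- .interaction_terms(el, ej, model)
  if (model != "phase_independent" && all(is.na(inter[[1]])))
    stop(errorCondition(
      paste0("haplotype model '", model, "' requires phased samples"),
      class = c("epiphase_phase_required", "error")))
  base_terms <- c(as.list(cv),
                  list(A_lead = el$A, D_lead = el$D, A_j = ej$A, D_j = ej$D),
                  extra_terms)
  alt <- fit_logistic(phenotype, c(base_terms, inter))
  sub <- function(x) if (is.null(dim(x))) x[alt$used] else x[alt$used, ]
  base <- fit_logistic(phenotype[alt$used], lapply(base_terms, sub))
  list(fit = alt, base = base, lrt = lrt(base, alt), model = model)
}

#' Fit one epistasis model for a lead/partner variant pair
#'
#' The alternative model adds the interaction term(s) of the requested kind
#' to the base model (intercept + PC1 + PC2 + A and D at both variants):
#' A_lead*A_j for the phase-independent model, the cis or trans haplotype
#' product for the cis/trans models, or both with free coefficients for the
#' cis-and-trans (C&T) model. The LRT against the base model has 1 df
#' (phase-independent, cis, trans) or 2 df (C&T). Haplotype models use only
#' samples phased at both variants and are refused across contigs.
#'
#' @param geno a [phased_geno] containing both variants.
#' @param lead,j variant ids or indices, lead != j.
#' @param phenotype 0/1 response.
#' @param covariates data.frame with PC1/PC2 (or NULL).
#' @param model one of "phase_independent", "cis", "trans", "cis_and_trans".
#' @return list with `fit` (alternative), `base`, `lrt`, `model`.
#' @export
fit_epistasis_pair <- function(geno, lead, j, phenotype, covariates = NULL,
                               model = .EPI_MODELS) {
  model <- match.arg(model)
  li <- if (is.character(lead)) match(lead, geno$variants$id) else lead
  ji <- if (is.character(j)) match(j, geno$variants$id) else j
  if (is.na(li) || is.na(ji)) stop("lead or partner variant not in matrix")
  if (li == ji) stop("lead and partner must differ")
  if (model != "phase_independent" &&
      geno$variants$chrom[li] != geno$variants$chrom[ji])
    stop(errorCondition(
      "haplotype models are not defined across contigs (phase unreliable)",
      class = c("epiphase_cross_contig_phase", "error")))
  el <- encode_variant(geno, li)
  ej <- encode_variant(geno, ji)
  .pair_fit(el, ej, phenotype, .cov_terms(covariates), model)
}

#' Scan all variants against a lead for epistasis
#'
#' Fits the requested interaction models for every non-lead variant, reports
#' per-model LRT p-values, interaction estimates, AIC/BIC and convergence,
#' the best model by smallest p (ties broken in fixed model order) and by
#' smallest BIC, the r^2 of each variant with the lead, and per-model and
#' union significance flags against the Meff-adjusted Bonferroni threshold.
#'
#' @param geno a MAF-filtered [phased_geno].
#' @param lead lead variant id or index.
#' @param phenotype 0/1 response.
#' @param covariates data.frame with PC1/PC2 (or NULL).
#' @param models subset of the four model names (non-empty).
#' @param alpha family-wise significance level.
#' @param m_eff effective number of tests; computed from `geno` via
#'   [effective_tests()] when NULL.
#' @return object of class `epistasis_scan`: `table` (one row per non-lead
#'   variant, ordered by position), `m_eff`, `threshold`, `models`, `alpha`.
#' @export
epistasis_scan <- function(geno, lead, phenotype, covariates = NULL,
                           models = .EPI_MODELS, alpha = 0.05,
                           m_eff = NULL) {
  if (!length(models)) stop("at least one epistasis model must be requested")
  models <- match.arg(models, .EPI_MODELS, several.ok = TRUE)
  li <- if (is.character(lead)) match(lead, geno$variants$id) else lead
  if (is.na(li)) stop("lead variant not in matrix")
  if (is.null(m_eff)) m_eff <- effective_tests(geno)$m_eff
  threshold <- bonferroni_threshold(m_eff, alpha)
  cv <- .cov_terms(covariates)
  el <- encode_variant(geno, li)
  ord <- order(geno$variants$pos)
  ord <- ord[ord != li]
  rows <- lapply(ord, function(ji) {
    v <- geno$variants[ji, ]
    row <- list(id = v$id, chrom = v$chrom, pos = v$pos, maf = v$maf,
                r2_lead = r2_pairwise(geno, li, ji))
    for (m in models) {
      pf <- tryCatch(
        fit_epistasis_pair(geno, li, ji, phenotype, covariates, m),
        error = function(e) e)
      tag <- function(s) paste0(s, "_", m)
      if (inherits(pf, "error")) {
        row[[tag("p")]] <- NA_real_
        row[[tag("beta1")]] <- NA_real_
        if (m == "cis_and_trans") row[[tag("beta2")]] <- NA_real_
        row[[tag("aic")]] <- NA_real_; row[[tag("bic")]] <- NA_real_
        row[[tag("converged")]] <- FALSE
        row[[tag("reason")]] <- conditionMessage(pf)
      } else {
        cf <- pf$fit$coefficients
        row[[tag("p")]] <- pf$lrt$p_value
        row[[tag("beta1")]] <- switch(m, phase_independent = cf[["AxA"]],
                                      trans = cf[["trans"]], cf[["cis"]])
        if (m == "cis_and_trans") row[[tag("beta2")]] <- cf[["trans"]]
        row[[tag("aic")]] <- pf$fit$aic; row[[tag("bic")]] <- pf$fit$bic
        row[[tag("converged")]] <- pf$fit$converged
        row[[tag("reason")]] <- NA_character_
      }
      row[[tag("sig")]] <- !is.na(row[[tag("p")]]) &&
        row[[tag("p")]] < threshold
    }
    pvals <- unlist(row[paste0("p_", models)])
    if (any(!is.na(pvals))) {
      best <- models[which.min(replace(pvals, is.na(pvals), Inf))]
      row$best_model <- best
      row$best_p <- min(pvals, na.rm = TRUE)
      bics <- unlist(row[paste0("bic_", models)])
      row$best_model_by_ic <-
        models[which.min(replace(bics, is.na(bics), Inf))]
    } else {
      row$best_model <- NA_character_; row$best_p <- NA_real_
      row$best_model_by_ic <- NA_character_
    }
    row$sig_any <- any(unlist(row[paste0("sig_", models)]))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), m_eff = m_eff,
                 threshold = threshold, models = models, alpha = alpha,
                 lead = geno$variants$id[li]),
            class = "epistasis_scan")
}

#' @export
print.epistasis_scan <- function(x, ...) {
  cat("<epistasis_scan> lead =", x$lead, "|", nrow(x$table), "variants |",
      "Meff =", format(x$m_eff, digits = 4),
      "| threshold =", format(x$threshold, digits = 3), "\n")
  cat("significant (any model):", sum(x$table$sig_any), "\n")
  invisible(x)
}

#' Cross-locus epistasis scan between two regions
#'
#' Tests every variant of locus B against the lead of locus A and vice
#' versa, using the phase-independent model only: haplotype (cis/trans)
#' models are refused across contigs because phase is not reliable between
#' chromosomes.
#'
#' @param geno_a,geno_b [phased_geno] matrices on different contigs with the
#'   same samples.
#' @param lead_a,lead_b lead variant ids in their respective matrices.
#' @param phenotype 0/1 response.
#' @param covariates data.frame with PC1/PC2 (or NULL).
#' @param models must be "phase_independent" (anything else errors).
#' @param alpha family-wise level.
#' @return list with `a_vs_lead_b` and `b_vs_lead_a` scan tables and the
#'   Meff-based thresholds used for each.
#' @export
cross_locus_scan <- function(geno_a, lead_a, geno_b, lead_b, phenotype,
                             covariates = NULL,
                             models = "phase_independent", alpha = 0.05) {
  if (!all(models == "phase_independent"))
    stop(errorCondition(
      "only the phase-independent model is available across loci",
      class = c("epiphase_cross_contig_phase", "error")))
  ca <- unique(geno_a$variants$chrom); cb <- unique(geno_b$variants$chrom)
  if (length(intersect(ca, cb)))
    stop("cross-locus scan expects loci on different contigs")
  if (!identical(geno_a$samples, geno_b$samples))
    stop("the two matrices must share samples")
  cv <- .cov_terms(covariates)
  one_side <- function(geno_lead, lead, geno_test) {
    li <- match(lead, geno_lead$variants$id)
    if (is.na(li)) stop("lead variant not in its matrix")
    el <- encode_variant(geno_lead, li)
    m_eff <- effective_tests(geno_test)$m_eff
    thr <- bonferroni_threshold(m_eff, alpha)
    ord <- order(geno_test$variants$pos)
    rows <- lapply(ord, function(ji) {
      v <- geno_test$variants[ji, ]
      out <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                        maf = v$maf, beta1 = NA_real_, p = NA_real_,
                        sig = FALSE, reason = NA_character_,
                        stringsAsFactors = FALSE)
      tryCatch({
        ej <- encode_variant(geno_test, ji)
        pf <- .pair_fit(el, ej, phenotype, cv, "phase_independent")
        out$beta1 <- pf$fit$coefficients[["AxA"]]
        out$p <- pf$lrt$p_value
        out$sig <- !is.na(out$p) && out$p < thr
        out
      }, error = function(e) { out$reason <- conditionMessage(e); out })
    })
    list(table = do.call(rbind, rows), m_eff = m_eff, threshold = thr)
  }
  list(b_vs_lead_a = one_side(geno_a, lead_a, geno_b),
       a_vs_lead_b = one_side(geno_b, lead_b, geno_a))
}

#' Secondary (conditional) epistasis analysis
#'
#' Asks whether each detected epistatic variant keeps a role after
#' conditioning on the most significant one: for each candidate j, both the
#' null and the alternative augment the base model with the top variant's
#' main effects (A_top, D_top) and its interaction with the lead (same model
#' kind as the candidate's best model); the alternative adds the candidate's
#' own lead interaction. The LRT therefore isolates the candidate's added
#' interaction beyond the top variant's.
#'
#' @param geno a [phased_geno].
#' @param lead lead variant id.
#' @param top the most significant epistatic variant's id.
#' @param candidates variant ids to test (top and lead excluded
#'   automatically).
#' @param phenotype 0/1 response.
#' @param covariates data.frame with PC1/PC2 (or NULL).
#' @param models model kind per candidate: single name recycled, or a named
#'   vector keyed by candidate id (e.g. each candidate's best model).
#' @return data.frame: id, pos, model, p, df, reason.
#' @export
secondary_epistasis <- function(geno, lead, top, candidates, phenotype,
                                covariates = NULL,
                                models = "phase_independent") {
  li <- match(lead, geno$variants$id)
  ti <- match(top, geno$variants$id)
  if (is.na(li) || is.na(ti)) stop("lead or top variant not in matrix")
  candidates <- setdiff(candidates, c(lead, top))
  if (length(models) == 1 && is.null(names(models)))
    models <- setNames(rep(models, length(candidates)), candidates)
  cv <- .cov_terms(covariates)
  el <- encode_variant(geno, li)
  et <- encode_variant(geno, ti)
  rows <- lapply(candidates, function(cid) {
    ji <- match(cid, geno$variants$id)
    m <- models[[cid]]
    out <- data.frame(id = cid, pos = geno$variants$pos[ji], model = m,
                      p = NA_real_, df = NA_integer_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      ej <- encode_variant(geno, ji)
      top_inter <- .interaction_terms(el, et, m)
      names(top_inter) <- paste0("top_", names(top_inter))
      cand_inter <- .interaction_terms(el, ej, m)
      null_terms <- c(as.list(cv),
                      list(A_lead = el$A, D_lead = el$D,
                           A_j = ej$A, D_j = ej$D,
                           A_top = et$A, D_top = et$D),
                      top_inter)
      alt <- fit_logistic(phenotype, c(null_terms, cand_inter))
      sub <- function(x) if (is.null(dim(x))) x[alt$used] else x[alt$used, ]
      nul <- fit_logistic(phenotype[alt$used], lapply(null_terms, sub))
      t <- lrt(nul, alt)
      out$p <- t$p_value; out$df <- t$df
      out
    }, error = function(e) { out$reason <- conditionMessage(e); out })
  })
  do.call(rbind, rows)
}

#' Genotype-combination log-odds table with cis/trans split
#'
#' Descriptive companion to the model fits: samples are cross-classified by
#' lead genotype (counted-allele dosage 0/1/2) and partner genotype, with the
#' double-heterozygote cell split by haplotype configuration into cis (both
#' counted alleles on the same inherited haplotype) and trans. Per cell,
#' log odds = ln((cases + 0.5) / (controls + 0.5)) with the
#' Haldane-Anscombe continuity correction; 95% CIs use the corrected
#' standard error. Empty cells are reported with NA log-odds, never dropped.
#'
#' @param phenotype 0/1 response.
#' @param lead_enc,j_enc encodings from [encode_variant()] (both phased).
#' @return data.frame: lead_geno, j_geno (with "1_cis"/"1_trans" rows),
#'   n_cases, n_controls, log_odds, ci_lo, ci_hi.
#' @export
genotype_logodds_table <- function(phenotype, lead_enc, j_enc) {
  ct <- cis_trans_products(lead_enc, j_enc)
  ok <- !is.na(lead_enc$H1) & !is.na(j_enc$H1) & !is.na(phenotype)
  if (!all(ok))
    message(sum(!ok), " sample(s) without phase at both variants excluded")
  jcat <- as.character(j_enc$A)
  dh <- lead_enc$A == 1 & j_enc$A == 1
  jcat[dh & ct$cis == 1] <- "1_cis"
  jcat[dh & ct$trans == 1] <- "1_trans"
  cells <- expand.grid(lead_geno = c("0", "1", "2"),
                       j_geno = c("0", "1", "1_cis", "1_trans", "2"),
                       stringsAsFactors = FALSE)
  # the plain "1" row only exists where the lead is homozygous
  cells <- cells[!(cells$lead_geno == "1" & cells$j_geno == "1") &
                 !(cells$lead_geno != "1" &
                   cells$j_geno %in% c("1_cis", "1_trans")), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- ok & lead_enc$A == as.numeric(substr(cells$lead_geno[i], 1, 1)) &
      jcat == cells$j_geno[i]
    ca <- sum(phenotype[sel] == 1); co <- sum(phenotype[sel] == 0)
    lo <- if (ca + co == 0) NA_real_ else log((ca + 0.5) / (co + 0.5))
    se <- if (ca + co == 0) NA_real_ else sqrt(1 / (ca + 0.5) + 1 / (co + 0.5))
    data.frame(lead_geno = cells$lead_geno[i], j_geno = cells$j_geno[i],
               n_cases = ca, n_controls = co, log_odds = lo,
               ci_lo = lo - 1.96 * se, ci_hi = lo + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$lead_geno, out$j_geno), ]
}

#' Variance-explained gain from adding epistasis terms
#'
#' Nagelkerke pseudo-R-squared difference between a base fit and a nested
#' epistasis fit on the same samples; when a population prevalence is
#' supplied, each pseudo-R-squared is additionally mapped to the liability
#' scale (Lee et al. case-control transformation), labelled as such.
#'
#' @param base_fit,epistasis_fit nested `epiphase_fit`s on the same samples.
#' @param prevalence optional population disease prevalence in (0, 1).
#' @return list: `gain`, `r2_base`, `r2_epistasis`, `method`, and (with
#'   prevalence) `liability` with the transformed values.
#' @export
variance_explained_gain <- function(base_fit, epistasis_fit,
                                    prevalence = NULL) {
  if (!all(base_fit$term_names %in% epistasis_fit$term_names))
    stop("fits are not nested")
  if (base_fit$n_used != epistasis_fit$n_used)
    stop("fits must use the same samples")
  n <- base_fit$n_used
  ll0 <- base_fit$null_log_likelihood
  nagelkerke <- function(ll)
    (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))
  r2b <- nagelkerke(base_fit$log_likelihood)
  r2e <- nagelkerke(epistasis_fit$log_likelihood)
  out <- list(gain = r2e - r2b, r2_base = r2b, r2_epistasis = r2e,
              method = "nagelkerke")
  if (!is.null(prevalence)) {
    K <- prevalence; P <- base_fit$n_cases / n
    z <- stats::dnorm(stats::qnorm(1 - K))
    C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
    out$liability <- list(r2_base = r2b * C, r2_epistasis = r2e * C,
                          gain = (r2e - r2b) * C,
                          method = "lee_liability_transform",
                          prevalence = K)
  }
  out
}
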