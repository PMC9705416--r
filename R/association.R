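#' Fit a logistic case-control model by maximum likelihood
#'
#' The shared ML engine behind every scan: iteratively reweighted least
#' squares (via `stats::glm.fit`) on an intercept plus the supplied named
#' regressors, with explicit convergence, separation and rank-deficiency
#' handling. Rows with any missing regressor or response are dropped
#' (complete-case per fit) and the count used is reported.
#'
#' @param y 0/1 response vector.
#' @param terms named list / data.frame / matrix of regressors (no
#'   intercept; an intercept is always included).
#' @param epsilon IRLS convergence tolerance (default 1e-10).
#' @param maxit maximum IRLS iterations (default 100).
#' @return an object of class `epiphase_fit`: coefficients, standard errors,
#'   log-likelihood, `converged` and `separation_detected` flags, `n_used`,
#'   AIC, BIC, and the row mask `used`.
#' @export
fit_logistic <- function(y, terms = NULL, epsilon = 1e-10, maxit = 100) {
  if (is.null(terms)) terms <- matrix(numeric(0), length(y), 0)
  if (is.list(terms) && !is.data.frame(terms))
    terms <- do.call(cbind, terms)
  terms <- as.matrix(terms)
  if (nrow(terms) != length(y)) stop("terms and response lengths differ")
  used <- !is.na(y) & complete.cases(terms)
  yy <- y[used]; X <- cbind(`(Intercept)` = 1, terms[used, , drop = FALSE])
  if (length(unique(yy)) < 2)
    stop(errorCondition("all-case or all-control response",
                        class = c("epiphase_degenerate_response", "error")))
  if (ncol(X) > 1) {
    const <- apply(X[, -1, drop = FALSE], 2, function(v) var(v) == 0)
    if (any(const))
      stop(errorCondition(
        paste("constant regressor column(s):",
              paste(colnames(X)[-1][const], collapse = ", ")),
        class = c("epiphase_degenerate_term", "error")))
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop(errorCondition(
      paste("rank-deficient design; collinear column(s):",
            paste(aliased, collapse = ", ")),
      class = c("epiphase_rank_deficiency", "error")))
  }
  fit <- suppressWarnings(glm.fit(X, yy, family = binomial(),
                                  control = list(epsilon = epsilon,
                                                 maxit = maxit)))
  k <- fit$rank
  ll <- -fit$deviance / 2   # Bernoulli saturated log-likelihood is 0
  p <- ncol(X)
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  names(se) <- colnames(X)
  pbar <- mean(yy)
  null_ll <- sum(yy) * log(pbar) + sum(1 - yy) * log(1 - pbar)
  structure(list(coefficients = fit$coefficients, se = se,
                 log_likelihood = ll,
                 null_log_likelihood = null_ll,
                 n_cases = sum(yy),
                 converged = fit$converged,
                 separation_detected = any(abs(fit$coefficients) > 15),
                 n_used = sum(used), k = k,
                 aic = 2 * k - 2 * ll,
                 bic = k * log(sum(used)) - 2 * ll,
                 term_names = colnames(X), used = used),
            class = "epiphase_fit")
}

#' @export
print.epiphase_fit <- function(x, ...) {
  cat("<epiphase_fit> logLik =", format(x$log_likelihood),
      " n =", x$n_used, " k =", x$k,
      if (!x$converged) " [NOT CONVERGED]",
      if (x$separation_detected) " [SEPARATION]", "\n")
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Likelihood-ratio test of two nested logistic fits
#'
#' statistic = -2 (logLik_null - logLik_alt); df = difference in free
#' parameters; p from the chi-square upper tail. The null's terms must be a
#' subset of the alternative's and both fits must use the same samples.
#'
#' @param null_fit,alt_fit `epiphase_fit` objects, null nested in alternative.
#' @return an object of class `epiphase_lrt`: `statistic`, `df`, `p_value`,
#'   and a `testable` flag (FALSE when either fit failed to converge, in
#'   which case the p-value is NA).
#' @export
lrt <- function(null_fit, alt_fit) {
  if (!all(null_fit$term_names %in% alt_fit$term_names))
    stop("models are not nested (null terms not a subset of alternative's)")
  if (null_fit$n_used != alt_fit$n_used)
    stop("nested fits must use the same samples")
  testable <- null_fit$converged && alt_fit$converged
  stat <- -2 * (null_fit$log_likelihood - alt_fit$log_likelihood)
  if (stat < 0 && stat > -1e-8) stat <- 0
  df <- alt_fit$k - null_fit$k
  structure(list(statistic = stat, df = df,
                 p_value = if (testable) pchisq(stat, df, lower.tail = FALSE)
                           else NA_real_,
                 testable = testable,
                 separation = null_fit$separation_detected ||
                   alt_fit$separation_detected),
            class = "epiphase_lrt")
}

.cov_terms <- function(covariates, used_names = c("PC1", "PC2")) {
  if (is.null(covariates)) return(NULL)
  cv <- as.data.frame(covariates)
  cv <- cv[, intersect(used_names, names(cv)), drop = FALSE]
  if (!ncol(cv)) NULL else cv
}

#' Marginal single-variant association scan
#'
#' Per variant, fits intercept + PC1 + PC2 + A + D against the
#' covariate-only null and reports the 2-df LRT p-value. Per-variant fit
#' failures become NA rows with a reason; the scan continues.
#'
#' @param geno a MAF-filtered [phased_geno].
#' @param phenotype 0/1 response vector.
#' @param covariates data.frame with PC1/PC2 columns (or NULL for none).
#' @return data.frame sorted by position: id, chrom, pos, maf, beta_add,
#'   beta_dom, log_likelihood, df, p, reason.
#' @export
marginal_scan <- function(geno, phenotype, covariates = NULL) {
  cv <- .cov_terms(covariates)
  ord <- order(geno$variants$pos)
  rows <- lapply(ord, function(j) {
    v <- geno$variants[j, ]
    out <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos, maf = v$maf,
                      beta_add = NA_real_, beta_dom = NA_real_,
                      log_likelihood = NA_real_, df = NA_integer_,
                      p = NA_real_, reason = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      e <- encode_variant(geno, j)
      terms_alt <- c(as.list(cv), list(A = e$A, D = e$D))
      af <- fit_logistic(phenotype, terms_alt)
      nf <- fit_logistic(phenotype[af$used],
                         if (is.null(cv)) NULL else cv[af$used, , drop = FALSE])
      t <- lrt(nf, af)
      out$beta_add <- af$coefficients[["A"]]
      out$beta_dom <- af$coefficients[["D"]]
      out$log_likelihood <- af$log_likelihood
      out$df <- t$df; out$p <- t$p_value
      if (!t$testable) out$reason <- "non-convergence"
      out
    }, error = function(e) { out$reason <- conditionMessage(e); out })
    res
  })
  do.call(rbind, rows)
}

#' Conditional association scan on a lead variant
#'
#' Per variant j (j != lead), adds A_j + D_j to a null already containing
#' the covariates and the lead variant's A and D, testing with a 2-df LRT
#' whether j carries association beyond the lead.
#'
#' @inheritParams marginal_scan
#' @param lead lead variant id or index.
#' @return data.frame as in [marginal_scan()] (lead excluded).
#' @export
conditional_scan <- function(geno, phenotype, covariates = NULL, lead) {
  li <- if (is.character(lead)) match(lead, geno$variants$id) else lead
  if (is.na(li)) stop("lead variant not present in matrix")
  cv <- .cov_terms(covariates)
  el <- encode_variant(geno, li)
  ord <- order(geno$variants$pos)
  ord <- ord[ord != li]
  rows <- lapply(ord, function(j) {
    v <- geno$variants[j, ]
    out <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos, maf = v$maf,
                      beta_add = NA_real_, beta_dom = NA_real_,
                      log_likelihood = NA_real_, df = NA_integer_,
                      p = NA_real_, reason = NA_character_,
                      stringsAsFactors = FALSE)
    tryCatch({
      e <- encode_variant(geno, j)
      talt <- c(as.list(cv), list(A_lead = el$A, D_lead = el$D,
                                  A = e$A, D = e$D))
      af <- fit_logistic(phenotype, talt)
      tn <- c(as.list(cv), list(A_lead = el$A, D_lead = el$D))
      nf <- fit_logistic(phenotype[af$used],
                         lapply(tn, function(x)
                           if (is.null(dim(x))) x[af$used] else x[af$used, ]))
      t <- lrt(nf, af)
      out$beta_add <- af$coefficients[["A"]]
      out$beta_dom <- af$coefficients[["D"]]
      out$log_likelihood <- af$log_likelihood
      out$df <- t$df; out$p <- t$p_value
      if (!t$testable) out$reason <- "non-convergence"
      out
    }, error = function(e) { out$reason <- conditionMessage(e); out })
  })
  do.call(rbind, rows)
}

#' Select the lead variant from a marginal scan
#'
#' Smallest marginal p-value wins; ties broken by smaller position, then
#' lexical id. An override pins a named variant regardless of p.
#'
#' @param scan output of [marginal_scan()].
#' @param override optional variant id to pin as lead.
#' @return the selected row of `scan`.
#' @export
select_lead_variant <- function(scan, override = NULL) {
  if (!is.null(override)) {
    i <- match(override, scan$id)
    if (is.na(i)) stop("override variant not in scan table")
    return(scan[i, ])
  }
  ok <- which(!is.na(scan$p))
  if (!length(ok)) stop("no testable variants: all scan p-values are NA")
  ok <- ok[order(scan$p[ok], scan$pos[ok], scan$id[ok])]
  scan[ok[1], ]
}

#' Principal components of the dosage matrix
#'
#' Plain PCA on the mean-centered, variance-standardized additive dosages
#' after greedy LD pruning (drop a variant whose r^2 with any of the last
#' `window` retained variants exceeds `r2_prune`). Missing dosages are
#' mean-imputed before decomposition. Sign convention: within each
#' component, the loading of largest magnitude is positive.
#'
#' @param geno a [phased_geno].
#' @param k number of components (k = 0 returns an empty covariate set).
#' @param r2_prune pruning threshold on squared dosage correlation.
#' @param window number of preceding retained variants checked.
#' @return data.frame of per-sample scores, columns PC1..PCk.
#' @export
compute_pcs <- function(geno, k = 2, r2_prune = 0.2, window = 50) {
  if (k == 0)
    return(data.frame(row.names = geno$samples))
  A <- dosage(geno)
  A <- apply(A, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE); col })
  v <- apply(A, 2, var)
  A <- A[, v > 0, drop = FALSE]
  kept <- integer(0)
  for (j in seq_len(ncol(A))) {
    recent <- utils::tail(kept, window)
    ok <- TRUE
    for (i in recent) {
      r <- suppressWarnings(cor(A[, j], A[, i]))
      if (!is.na(r) && r^2 > r2_prune) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  if (length(kept) < k + 1)
    stop("too few variants after pruning for ", k, " components")
  Z <- scale(A[, kept, drop = FALSE])
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    load <- pc$rotation[, i]
    if (load[which.max(abs(load))] < 0) scores[, i] <- -scores[, i]
  }
  out <- as.data.frame(scores)
  names(out) <- paste0("PC", seq_len(k))
  rownames(out) <- NULL
  out
}
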