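#' Effective number of independent tests (Li & Ji eigenvalue method)
#'
#' Computes the Pearson correlation matrix of additive dosages
#' (pairwise-complete), takes its eigenvalues lambda_i (clipped at 0 for
#' numerical negatives beyond -1e-10), and counts
#' Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ].
#' An identity correlation gives Meff = M; perfectly duplicated variants
#' collapse to a single effective test.
#'
#' @param geno a [phased_geno] with >= 2 variants, or a numeric dosage
#'   matrix (samples x variants).
#' @return object of class `meff_result`: `m_total`, `m_eff`,
#'   `eigenvalues`, `method`.
#' @export
effective_tests <- function(geno) {
  A <- if (inherits(geno, "phased_geno")) dosage(geno) else as.matrix(geno)
  v <- apply(A, 2, var, na.rm = TRUE)
  if (any(is.na(v) | v == 0)) {
    message(sum(is.na(v) | v == 0), " constant variant(s) excluded from Meff")
    A <- A[, !is.na(v) & v > 0, drop = FALSE]
  }
  m <- ncol(A)
  if (m < 2) stop("Meff needs at least 2 polymorphic variants")
  R <- cor(A, use = "pairwise.complete.obs")
  R[is.na(R)] <- 0; diag(R) <- 1
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam < -1e-10))
    stop("correlation matrix not positive semidefinite (min eigenvalue ",
         format(min(lam)), ")")
  lam <- pmax(lam, 0)
  # f(lambda) steps at integers; snap eigenvalues within numerical error of
  # an integer so exact duplicates land on the intended side
  near <- abs(lam - round(lam)) < 1e-9
  lam[near] <- round(lam[near])
  m_eff <- sum((lam >= 1) + (lam - floor(lam)))
  structure(list(m_total = m, m_eff = m_eff, eigenvalues = lam,
                 method = "li_ji_2005"),
            class = "meff_result")
}

#' @export
print.meff_result <- function(x, ...) {
  cat("<meff_result> M =", x$m_total, " Meff =", format(x$m_eff, digits = 6),
      " (", x$method, ")\n")
  invisible(x)
}

#' Meff-adjusted Bonferroni per-test threshold
#'
#' @param m_eff effective number of independent tests (>= 1).
#' @param alpha family-wise error level, in (0, 1).
#' @return per-test p-value threshold alpha / m_eff.
#' @export
bonferroni_threshold <- function(m_eff, alpha = 0.05) {
  if (m_eff < 1) stop("m_eff must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / m_eff
}
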