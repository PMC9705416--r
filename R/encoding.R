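#' Encode a variant as additive, dominance and haplotype regressors
#'
#' Maps one variant's phased genotypes into the regressors of the logistic
#' models: A counts copies of the counted allele (0/1/2), D indicates
#' heterozygosity (dominance-deviation coding, so A and D stay orthogonal
#' under Hardy-Weinberg equilibrium), and H1/H2 indicate the counted allele
#' on each haplotype, satisfying H1 + H2 = A wherever phase is available.
#' For unphased samples H1/H2 are NA.
#'
#' @param geno a [phased_geno].
#' @param variant variant id or index.
#' @param counted optional override of the counted allele index (0 = ref,
#'   1 = alt); default is the variant's stored orientation (minor allele).
#' @return list with numeric vectors `A`, `D`, `H1`, `H2` and the resolved
#'   `counted` allele index.
#' @export
encode_variant <- function(geno, variant, counted = NULL) {
  j <- if (is.character(variant)) match(variant, geno$variants$id)
       else as.integer(variant)
  if (is.na(j) || j < 1 || j > nrow(geno$variants))
    stop("unknown variant: ", variant)
  if (is.null(counted)) counted <- geno$variants$counted[j]
  if (!counted %in% c(0L, 1L))
    stop("counted allele must be 0 (ref) or 1 (alt)")
  h1 <- geno$hap1[, j]; h2 <- geno$hap2[, j]
  if (counted == 0L) { h1 <- 1L - h1; h2 <- 1L - h2 }
  a <- h1 + h2
  d <- as.numeric(a == 1L)
  ph <- geno$phased[, j]
  H1 <- ifelse(ph, as.numeric(h1), NA_real_)
  H2 <- ifelse(ph, as.numeric(h2), NA_real_)
  list(A = unname(as.numeric(a)), D = unname(d),
       H1 = unname(H1), H2 = unname(H2), counted = counted)
}

#' Cis and trans interaction products of two encoded variants
#'
#' cis = H1_lead*H1_j + H2_lead*H2_j (counted alleles on the same inherited
#' haplotype); trans = H1_lead*H2_j + H2_lead*H1_j (opposite haplotypes).
#' Both lie in {0, 1, 2} and satisfy cis + trans = A_lead * A_j, so the
#' phase-independent interaction is their sum. Samples unphased at either
#' variant get NA in both products.
#'
#' @param lead,other encodings from [encode_variant()].
#' @return list with numeric vectors `cis` and `trans`.
#' @export
cis_trans_products <- function(lead, other) {
  cis <- lead$H1 * other$H1 + lead$H2 * other$H2
  trans <- lead$H1 * other$H2 + lead$H2 * other$H1
  list(cis = cis, trans = trans)
}
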