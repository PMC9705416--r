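#' Construct a phased genotype matrix
#'
#' The central genotype container: per-sample, per-variant haplotype allele
#' indicators. `hap1` and `hap2` hold 0/1 alleles (NA = missing); for
#' unphased entries both alleles are still stored (so the additive dosage
#' `hap1 + hap2` is always defined) but the `phased` flag is FALSE and the
#' haplotype assignment is arbitrary.
#'
#' @param hap1,hap2 integer matrices (samples x variants) of 0/1/NA alleles.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; a `counted` column (the allele index, 0 or 1, counted by
#'   the additive coding) is added if absent.
#' @param samples character vector of sample ids.
#' @param phased logical matrix of per-entry phase flags, or a single logical
#'   recycled to the full matrix.
#' @return an object of class `phased_geno`.
#' @export
phased_geno <- function(hap1, hap2, variants, samples = NULL, phased = TRUE) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  if (!identical(dim(hap1), dim(hap2)))
    stop("hap1 and hap2 dimensions differ")
  ok <- c(hap1, hap2); ok <- ok[!is.na(ok)]
  if (length(ok) && !all(ok %in% c(0L, 1L)))
    stop("haplotype alleles must be 0/1 or NA")
  if (nrow(variants) != ncol(hap1))
    stop("one variant row per genotype column required")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(hap1)))
  if (length(samples) != nrow(hap1))
    stop("one sample id per genotype row required")
  if (is.logical(phased) && length(phased) == 1)
    phased <- matrix(phased, nrow(hap1), ncol(hap1))
  phased <- as.matrix(phased)
  if (!identical(dim(phased), dim(hap1)))
    stop("phased flag dimensions differ from genotypes")
  phased[is.na(hap1) | is.na(hap2)] <- FALSE
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  if (any(variants$pos < 1)) stop("positions are 1-based and must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
  dimnames(hap1) <- dimnames(hap2) <- dimnames(phased) <-
    list(samples, variants$id)
  obj <- structure(list(samples = samples, variants = variants,
                        hap1 = hap1, hap2 = hap2, phased = phased),
                   class = "phased_geno")
  obj$variants$maf <- variant_maf(obj)
  if (is.null(variants$counted))
    obj$variants$counted <- ifelse(alt_allele_freq(obj) <= 0.5, 1L, 0L)
  obj
}

#' @export
print.phased_geno <- function(x, ...) {
  cat("<phased_geno> ", length(x$samples), " samples x ",
      nrow(x$variants), " variants; ",
      round(100 * mean(x$phased), 1), "% phased entries\n", sep = "")
  invisible(x)
}

#' @export
dim.phased_geno <- function(x) c(length(x$samples), nrow(x$variants))

#' Additive dosage matrix
#'
#' Count of the counted (by default minor) allele per sample and variant;
#' defined for unphased entries too.
#'
#' @param x a `phased_geno`.
#' @return integer matrix (samples x variants) with values 0/1/2 or NA.
#' @export
dosage <- function(x) {
  a <- x$hap1 + x$hap2
  flip <- which(x$variants$counted == 0L)
  if (length(flip)) a[, flip] <- 2L - a[, flip]
  a
}

alt_allele_freq <- function(x) {
  colMeans((x$hap1 + x$hap2) / 2, na.rm = TRUE)
}

#' Minor-allele frequencies of a genotype matrix
#'
#' Computed on non-missing genotypes of the loaded sample; invariant to
#' allele relabelling (reported as min(p, 1-p)).
#'
#' @param x a `phased_geno`.
#' @return numeric vector of per-variant MAFs.
#' @export
variant_maf <- function(x) {
  p <- alt_allele_freq(x)
  unname(pmin(p, 1 - p))
}

#' Subset a phased genotype matrix by variants and/or samples
#'
#' @param x a `phased_geno`.
#' @param variants indices, logical mask, or variant ids.
#' @param samples indices, logical mask, or sample ids.
#' @return a `phased_geno` restricted to the selection, with MAF recomputed.
#' @export
subset_geno <- function(x, variants = NULL, samples = NULL) {
  vi <- seq_len(nrow(x$variants)); si <- seq_along(x$samples)
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, x$variants$id)
          else vi[variants]
    if (anyNA(vi)) stop("unknown variant selection")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample selection")
  }
  v <- x$variants[vi, , drop = FALSE]
  rownames(v) <- NULL
  phased_geno(x$hap1[si, vi, drop = FALSE], x$hap2[si, vi, drop = FALSE],
              v, samples = x$samples[si],
              phased = x$phased[si, vi, drop = FALSE])
}
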