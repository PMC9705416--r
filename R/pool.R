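#' Construct a haplotype pool
#'
#' A haplotype pool is a small discrete distribution over 0/1 allele vectors
#' shared by all samples of a (sub)population. Sampling two haplotypes per
#' individual independently from the pool yields Hardy-Weinberg genotype
#' frequencies and the linkage disequilibrium encoded in the pool.
#'
#' @param haplotypes matrix (n_haplotypes x n_loci) of 0/1 alleles, or a list
#'   of equal-length 0/1 vectors.
#' @param frequencies numeric vector of haplotype probabilities, summing to 1.
#' @param loci character vector of variant labels (default V1..Vk).
#' @return an object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(haplotypes, frequencies, loci = NULL) {
  if (is.list(haplotypes)) haplotypes <- do.call(rbind, haplotypes)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotype alleles must be 0/1")
  if (length(frequencies) != nrow(haplotypes))
    stop("one frequency per haplotype required")
  if (any(frequencies < 0))
    stop("haplotype frequencies must be non-negative")
  if (abs(sum(frequencies) - 1) > 1e-12)
    stop("haplotype frequencies must sum to 1 (got ", sum(frequencies), ")")
  if (is.null(loci)) loci <- paste0("V", seq_len(ncol(haplotypes)))
  if (length(loci) != ncol(haplotypes))
    stop("one locus label per column required")
  colnames(haplotypes) <- loci
  structure(list(loci = loci, haplotypes = haplotypes,
                 frequencies = as.numeric(frequencies)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool> ", length(x$loci), " loci, ",
      nrow(x$haplotypes), " haplotypes\n", sep = "")
  invisible(x)
}

#' Allele frequencies implied by a pool
#'
#' @param pool a `haplotype_pool`.
#' @return named numeric vector: frequency of the `1` allele at each locus.
#' @export
pool_allele_freqs <- function(pool) {
  drop(pool$frequencies %*% pool$haplotypes)
}

#' Build a two-SNP haplotype pool with target MAFs and r-squared
#'
#' Solves for the four haplotype frequencies of a two-locus system whose
#' marginal minor-allele frequencies are `maf_a` and `maf_b` and whose
#' squared LD correlation r^2 = D^2 / (p(1-p)q(1-q)) equals `r2`, with D
#' oriented positive (minor alleles co-occur). The `1` allele codes the minor
#' allele at both loci.
#'
#' @param maf_a,maf_b minor-allele frequencies, in (0, 0.5].
#' @param r2 target squared LD correlation, in [0, 1].
#' @param loci labels for the two loci.
#' @return a `haplotype_pool` with four haplotypes (11, 10, 01, 00).
#' @export
build_two_snp_pool <- function(maf_a, maf_b, r2, loci = c("A", "B")) {
  stopifnot(length(maf_a) == 1, length(maf_b) == 1, length(r2) == 1)
  if (maf_a <= 0 || maf_a > 0.5 || maf_b <= 0 || maf_b > 0.5)
    stop("MAFs must lie in (0, 0.5]")
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  p <- maf_a; q <- maf_b
  # positive-D feasibility bound: D <= min(p(1-q), q(1-p))
  d_max <- min(p * (1 - q), q * (1 - p))
  r2_max <- d_max^2 / (p * (1 - p) * q * (1 - q))
  d <- sqrt(r2 * p * (1 - p) * q * (1 - q))
  if (d > d_max + 1e-12)
    stop(sprintf(
      "r2 = %g infeasible for MAFs (%g, %g); maximum attainable r2 = %g",
      r2, p, q, r2_max))
  d <- min(d, d_max)
  freqs <- c(p * q + d,             # 1 1
             p * (1 - q) - d,       # 1 0
             (1 - p) * q - d,       # 0 1
             (1 - p) * (1 - q) + d) # 0 0
  freqs <- pmax(freqs, 0)
  freqs <- freqs / sum(freqs)
  haplotype_pool(rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L)),
                 freqs, loci = loci)
}

#' Concatenate independent pool blocks
#'
#' Multi-SNP pools are represented as a list of independent blocks; each
#' individual haplotype is drawn per block and concatenated. This emulates a
#' region made of LD blocks in mutual linkage equilibrium.
#'
#' @param ... `haplotype_pool` objects (or a single list of them).
#' @return an object of class `pool_blocks` (a list of pools).
#' @export
pool_blocks <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1 && !inherits(blocks[[1]], "haplotype_pool"))
    blocks <- blocks[[1]]
  if (!all(vapply(blocks, inherits, logical(1), "haplotype_pool")))
    stop("all blocks must be haplotype_pool objects")
  loci <- unlist(lapply(blocks, `[[`, "loci"))
  if (anyDuplicated(loci)) stop("duplicated locus labels across blocks")
  structure(blocks, class = "pool_blocks")
}

#' Pool r-squared between two loci of a pool
#'
#' Exact r^2 implied by the pool's haplotype frequencies (not a sample
#' estimate).
#'
#' @param pool a `haplotype_pool`.
#' @param a,b locus labels or indices.
#' @return r^2 value, or NA if either locus is monomorphic.
#' @export
pool_r2 <- function(pool, a = 1, b = 2) {
  H <- pool$haplotypes
  if (is.character(a)) a <- match(a, pool$loci)
  if (is.character(b)) b <- match(b, pool$loci)
  p <- sum(pool$frequencies * H[, a])
  q <- sum(pool$frequencies * H[, b])
  if (p %in% c(0, 1) || q %in% c(0, 1)) return(NA_real_)
  p11 <- sum(pool$frequencies * (H[, a] == 1 & H[, b] == 1))
  d <- p11 - p * q
  d^2 / (p * (1 - p) * q * (1 - q))
}
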