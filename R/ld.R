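#' Pairwise r-squared between two variants
#'
#' Haplotype-based r^2 = D^2 / (pA(1-pA) pB(1-pB)) from phased haplotype
#' counts; falls back to the squared Pearson correlation of additive dosages
#' (composite LD) when phase is unavailable at either variant. The estimator
#' used is recorded in the `method` attribute. Invariant to allele-label
#' flips.
#'
#' @param geno a [phased_geno].
#' @param a,b variant ids or indices.
#' @return r^2 in [0, 1] (NA with a message if either variant is
#'   monomorphic among usable samples).
#' @export
r2_pairwise <- function(geno, a, b) {
  ai <- if (is.character(a)) match(a, geno$variants$id) else a
  bi <- if (is.character(b)) match(b, geno$variants$id) else b
  if (is.na(ai) || is.na(bi)) stop("unknown variant")
  ph <- geno$phased[, ai] & geno$phased[, bi]
  if (any(ph)) {
    h <- c(geno$hap1[ph, ai], geno$hap2[ph, ai])
    g <- c(geno$hap1[ph, bi], geno$hap2[ph, bi])
    keep <- !is.na(h) & !is.na(g)
    h <- h[keep]; g <- g[keep]
    pa <- mean(h); pb <- mean(g)
    if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
      message("monomorphic variant: LD undefined")
      return(NA_real_)
    }
    d <- mean(h * g) - pa * pb
    r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
    attr(r2, "method") <- "haplotype"
  } else {
    A <- (geno$hap1[, ai] + geno$hap2[, ai])
    B <- (geno$hap1[, bi] + geno$hap2[, bi])
    keep <- !is.na(A) & !is.na(B)
    if (var(A[keep]) == 0 || var(B[keep]) == 0) {
      message("monomorphic variant: LD undefined")
      return(NA_real_)
    }
    r2 <- cor(A[keep], B[keep])^2
    attr(r2, "method") <- "composite"
  }
  r2
}

#' Full pairwise LD matrix
#'
#' @param geno a [phased_geno].
#' @param variants optional subset of variant ids/indices.
#' @return symmetric matrix of r^2 values with unit diagonal.
#' @export
ld_matrix <- function(geno, variants = NULL) {
  idx <- if (is.null(variants)) seq_len(nrow(geno$variants))
         else if (is.character(variants)) match(variants, geno$variants$id)
         else variants
  m <- length(idx)
  R <- diag(1, m)
  dimnames(R) <- list(geno$variants$id[idx], geno$variants$id[idx])
  if (m > 1)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      r <- suppressMessages(r2_pairwise(geno, idx[i], idx[j]))
      R[i, j] <- R[j, i] <- as.numeric(r)
    }
  R
}

#' Single-linkage LD clustering of hit variants
#'
#' Variants with pairwise r^2 at or above the threshold are linked; clusters
#' are the connected components. Each cluster's representative is the member
#' with the smallest best-model p-value (ties by smaller position).
#'
#' @param hits data.frame with columns `id`, `pos`, and `p` (best-model p).
#' @param geno a [phased_geno] containing the hits.
#' @param r2_threshold linkage threshold (default 0.8).
#' @return data.frame: id, pos, p, cluster (integer), representative
#'   (logical).
#' @export
ld_clusters <- function(hits, geno, r2_threshold = 0.8) {
  if (!nrow(hits)) stop("at least one hit required")
  R <- ld_matrix(geno, hits$id)
  n <- nrow(hits)
  # union-find over edges r2 >= threshold (single linkage)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (!is.na(R[i, j]) && R[i, j] >= r2_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster <- match(roots, sort(unique(roots)))
  out <- data.frame(id = hits$id, pos = hits$pos, p = hits$p,
                    cluster = cluster, representative = FALSE,
                    stringsAsFactors = FALSE)
  for (cl in unique(cluster)) {
    members <- which(cluster == cl)
    best <- members[order(out$p[members], out$pos[members])][1]
    out$representative[best] <- TRUE
  }
  out[order(out$cluster, out$pos), ]
}

#' Select best LD proxies for target variants
#'
#' For replication on a panel that lacks some target variants: each target
#' present in the panel maps to itself (r^2 = 1); each absent target maps to
#' the panel variant with the highest r^2 to it in the reference, ties
#' broken by physical proximity then id. Mappings below `min_r2` are flagged
#' weak.
#'
#' @param targets character vector of target variant ids (present in the
#'   reference).
#' @param panel a [phased_geno]: the replication panel's variants.
#' @param reference a [phased_geno] containing targets and panel variants,
#'   used to measure LD.
#' @param min_r2 proxy quality floor (default 0.8).
#' @return data.frame: target, proxy, r2, weak (logical).
#' @export
select_proxies <- function(targets, panel, reference, min_r2 = 0.8) {
  if (!all(targets %in% reference$variants$id))
    stop("all targets must be present in the reference")
  panel_ids <- intersect(panel$variants$id, reference$variants$id)
  if (!length(panel_ids))
    stop("no panel variant is present in the reference: targets unmappable")
  rows <- lapply(targets, function(tg) {
    if (tg %in% panel$variants$id)
      return(data.frame(target = tg, proxy = tg, r2 = 1, weak = FALSE,
                        stringsAsFactors = FALSE))
    r2s <- vapply(panel_ids, function(pid)
      as.numeric(suppressMessages(r2_pairwise(reference, tg, pid))),
      numeric(1))
    r2s[is.na(r2s)] <- -Inf
    tpos <- reference$variants$pos[match(tg, reference$variants$id)]
    ppos <- reference$variants$pos[match(panel_ids, reference$variants$id)]
    ordold <- order(-r2s, abs(ppos - tpos), panel_ids)
    best <- ordold[1]
    data.frame(target = tg, proxy = panel_ids[best],
               r2 = max(r2s[best], 0),
               weak = r2s[best] < min_r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
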