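#' Define genomic regions (0-based, half-open)
#'
#' @param chrom character vector of contig names.
#' @param start,end integer bounds, 0-based half-open (BED convention).
#' @return data.frame of class `genomic_regions`.
#' @export
genomic_regions <- function(chrom, start, end) {
  if (any(start >= end)) stop("regions require start < end")
  if (any(start < 0)) stop("region starts must be >= 0")
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("genomic_regions", "data.frame"))
}

#' Read regions from a BED file
#'
#' @param path BED file (plain or gzipped); first three columns used.
#' @return a [genomic_regions()] data.frame.
#' @export
read_regions_bed <- function(path) {
  bed <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  genomic_regions(bed[[1]], bed[[2]], bed[[3]])
}

.strip_chr <- function(x) sub("^chr", "", x)

#' Read phased genotypes from a VCF file
#'
#' Loads biallelic records (SNVs and indels alike), optionally restricted to
#' regions, into a [phased_geno] matrix. "|"-separated GT fields are parsed
#' as phased haplotypes; "/"-separated ones are loaded with the phased flag
#' FALSE (haplotype assignment arbitrary). Multi-allelic records are skipped
#' with a message. The counted allele defaults to the minor allele in the
#' loaded sample.
#'
#' @param path VCF 4.x file, plain or gzipped, with a GT FORMAT field.
#' @param regions optional [genomic_regions()]; variants are kept iff their
#'   0-based position falls inside some region. chr-prefix differences
#'   between VCF and regions are normalized with a note.
#' @return a [phased_geno].
#' @export
read_phased_vcf <- function(path, regions = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt[, "FORMAT"]
  if (nrow(vcf@gt) > 0 &&
      !all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("VCF lacks a GT field in FORMAT")
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi))
    message(sum(!bi), " multi-allelic record(s) skipped")
  keep <- bi
  chrom <- vcf@fix[, "CHROM"]
  pos <- as.integer(vcf@fix[, "POS"])
  if (!is.null(regions)) {
    vchr <- chrom; rchr <- regions$chrom
    if (!any(vchr %in% rchr) &&
        any(.strip_chr(vchr) %in% .strip_chr(rchr))) {
      message("normalizing chr-prefix between VCF and regions")
      vchr <- .strip_chr(vchr); rchr <- .strip_chr(rchr)
    }
    p0 <- pos - 1L  # VCF is 1-based; region logic 0-based half-open
    in_region <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(regions)))
      in_region <- in_region | (vchr == rchr[i] &
                                p0 >= regions$start[i] & p0 < regions$end[i])
    keep <- keep & in_region
  }
  if (!any(keep)) {
    warning("no variants overlap the requested regions")
    empty <- matrix(integer(0), ncol(vcf@gt) - 1L, 0)
    return(phased_geno(empty, empty,
                       data.frame(id = character(0), chrom = character(0),
                                  pos = integer(0), ref = character(0),
                                  alt = character(0)),
                       samples = colnames(vcf@gt)[-1]))
  }
  vcf <- vcf[keep, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")   # variants x samples
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  a1[!a1 %in% c("0", "1")] <- NA; a2[!a2 %in% c("0", "1")] <- NA
  hap1 <- t(matrix(as.integer(a1), nrow(gt), ncol(gt)))
  hap2 <- t(matrix(as.integer(a2), nrow(gt), ncol(gt)))
  phased <- t(matrix(grepl("|", gt, fixed = TRUE), nrow(gt), ncol(gt)))
  ids <- vcf@fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(vcf@fix[noid, "CHROM"], ":", vcf@fix[noid, "POS"], ":",
                      vcf@fix[noid, "ALT"], ":", vcf@fix[noid, "REF"])
  variants <- data.frame(id = ids, chrom = vcf@fix[, "CHROM"],
                         pos = as.integer(vcf@fix[, "POS"]),
                         ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"],
                         stringsAsFactors = FALSE)
  phased_geno(hap1, hap2, variants, samples = colnames(vcf@gt)[-1],
              phased = phased)
}

#' Write a phased genotype matrix as a VCF file
#'
#' Plain-text VCF 4.2 with GT-only FORMAT; phased entries use "|",
#' unphased "/", missing ".|.". Round-trips exactly through
#' [read_phased_vcf()].
#'
#' @param geno a [phased_geno].
#' @param path output path (".gz" suffix gzips).
#' @return invisibly, `path`.
#' @export
write_phased_vcf <- function(geno, path) {
  v <- geno$variants
  sep <- ifelse(geno$phased, "|", "/")
  c1 <- ifelse(is.na(geno$hap1), ".", geno$hap1)
  c2 <- ifelse(is.na(geno$hap2), ".", geno$hap2)
  gt <- matrix(paste0(c1, ifelse(is.na(geno$hap1) | is.na(geno$hap2),
                                 "|", sep), c2),
               nrow(geno$hap1), ncol(geno$hap1))
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", unique(v$chrom), ">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            ".", "GT", gt[, i]), collapse = "\t"), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, body), con)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with header: sample_id, status (0/1), PC1, PC2.
#'
#' @param path TSV path (plain or gzipped).
#' @return data.frame with those columns.
#' @export
read_phenotypes <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  req <- c("sample_id", "status")
  miss <- setdiff(req, names(ph))
  if (length(miss)) stop("phenotype table lacks: ", paste(miss, collapse = ", "))
  if (!all(ph$status %in% c(0, 1))) stop("status must be 0/1")
  ph
}

#' Write the phenotype/covariate table
#'
#' @param covariates data.frame (sample_id, status, PC1, PC2).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a genotype matrix by minor-allele frequency
#'
#' Retains variants whose MAF (computed on non-missing genotypes of the
#' loaded sample) is at least `threshold`; the common-variant floor is 0.05.
#'
#' @param geno a [phased_geno].
#' @param threshold MAF floor, in [0, 0.5].
#' @return the filtered [phased_geno].
#' @export
filter_by_maf <- function(geno, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5)
    stop("MAF threshold must lie in [0, 0.5]")
  if (nrow(geno$variants) == 0) stop("empty genotype matrix")
  maf <- variant_maf(geno)
  keep <- !is.na(maf) & maf >= threshold
  message("MAF filter at ", threshold, ": retained ", sum(keep),
          ", removed ", sum(!keep), " variant(s)")
  subset_geno(geno, variants = keep)
}

#' Flag variants falling inside intervals
#'
#' @param variants variant data.frame (id, chrom, pos — 1-based).
#' @param intervals a [genomic_regions()] (possibly empty).
#' @param label annotation label (used for the returned vector's name
#'   attribute only).
#' @return logical vector, one flag per variant: TRUE iff the 0-based
#'   position lies in some interval.
#' @export
annotate_intervals <- function(variants, intervals, label = "interval") {
  if (is.null(intervals) || nrow(intervals) == 0) {
    flags <- rep(FALSE, nrow(variants))
  } else {
    vchr <- variants$chrom; ichr <- intervals$chrom
    if (!any(vchr %in% ichr) &&
        any(.strip_chr(vchr) %in% .strip_chr(ichr))) {
      message("normalizing chr-prefix between variants and intervals")
      vchr <- .strip_chr(vchr); ichr <- .strip_chr(ichr)
    }
    vg <- GenomicRanges::GRanges(vchr,
            IRanges::IRanges(start = variants$pos, width = 1))
    # BED half-open [start, end) -> 1-based closed [start+1, end]
    ig <- GenomicRanges::GRanges(ichr,
            IRanges::IRanges(start = intervals$start + 1L,
                             end = intervals$end))
    flags <- GenomicRanges::countOverlaps(vg, ig) > 0
  }
  names(flags) <- variants$id
  attr(flags, "label") <- label
  flags
}
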