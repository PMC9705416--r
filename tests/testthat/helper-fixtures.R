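# Shared fixtures built in code at test time.

# a two-block pool: lead/partner with mild LD, plus an unrelated tight block
demo_blocks <- function(r2_lead = 0.1) {
  pool_blocks(
    build_two_snp_pool(0.35, 0.3, r2_lead, loci = c("lead", "partner")),
    build_two_snp_pool(0.2, 0.2, 0.9, loci = c("s1", "s2")))
}

# cohort with a cis interaction planted between lead and partner
cis_cohort <- function(n = 3000, beta1 = 0.8, seed = 1) {
  cfg <- sim_config(demo_blocks(), n_samples = n, intercept = -1,
                    main_effects = c(lead_add = 0.4),
                    mechanism = "cis", beta1 = beta1, seed = seed)
  simulate_cohort(cfg)
}

# random phased genotype matrix: haplotypes Bernoulli(maf) per locus
random_phased_geno <- function(n, mafs, seed = 1, chrom = "1") {
  set.seed(seed)
  m <- length(mafs)
  h1 <- vapply(mafs, function(p) rbinom(n, 1L, p), integer(n))
  h2 <- vapply(mafs, function(p) rbinom(n, 1L, p), integer(n))
  phased_geno(h1, h2,
              data.frame(id = paste0("v", seq_len(m)), chrom = chrom,
                         pos = 1000L * seq_len(m), ref = "A", alt = "T",
                         counted = 1L, stringsAsFactors = FALSE))
}

# minimal plain-text VCF written to a temp file; returns the path
write_toy_vcf <- function(body_lines, samples = c("S1", "S2", "S3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

# the end-to-end fixture: a planted cis interaction (lead x partner), two
# near-copies of the partner as LD shadows, two independent null variants
planted_fixture_config <- function(n = 6000, seed = 1) {
  lead_block <- haplotype_pool(matrix(c(1L, 0L), 2, 1), c(0.35, 0.65),
                               loci = "lead")
  # partner + two shadows: shadows track the partner with r2 ~ 0.94
  shadow_block <- haplotype_pool(
    rbind(c(1L, 1L, 1L), c(1L, 1L, 0L), c(1L, 0L, 1L), c(1L, 0L, 0L),
          c(0L, 1L, 1L), c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 0L, 0L)),
    c(0.288, 0.006, 0.006, 0.000, 0.006, 0.006, 0.000, 0.688),
    loci = c("partner", "shadow1", "shadow2"))
  null_block <- build_two_snp_pool(0.25, 0.4, 0, loci = c("null1", "null2"))
  sim_config(pool_blocks(lead_block, shadow_block, null_block),
             n_samples = n, intercept = -1,
             main_effects = c(lead_add = 0.4),
             mechanism = "cis", beta1 = 1.0,
             lead = "lead", partner = "partner", seed = seed)
}
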