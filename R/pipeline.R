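#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and writes the phased VCF, the phenotype /
#' covariate TSV and a JSON truth file echoing the generative coefficients.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param prefix file-name prefix (default "cohort").
#' @return invisibly, a named list of the written paths plus the simulated
#'   objects.
#' @export
run_simulate <- function(config, out_dir, prefix = "cohort") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  paths <- list(
    vcf = file.path(out_dir, paste0(prefix, ".vcf")),
    phenotypes = file.path(out_dir, paste0(prefix, ".pheno.tsv")),
    truth = file.path(out_dir, paste0(prefix, ".truth.json")))
  write_phased_vcf(sim$geno, paths$vcf)
  write_phenotypes(sim$covariates, paths$phenotypes)
  truth <- sim$truth; truth$subpop <- NULL
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(sim = sim)))
}

#' Run the full phase-aware epistasis scan pipeline
#'
#' Orchestrates the analysis end to end: load phased genotypes (optionally
#' restricted to regions), apply the MAF filter, run the marginal scan,
#' select (or pin) the lead variant, run the lead-vs-all epistasis scan with
#' the Meff-adjusted threshold, cluster the significant hits by LD, run the
#' secondary conditional-epistasis analysis on the top hit, annotate hits
#' against enhancer intervals if given, and write every table as TSV next to
#' a JSON manifest recording seeds, thresholds, Meff, the lead choice and
#' per-stage row counts. Rerunning with the same configuration reproduces
#' the outputs.
#'
#' @param vcf path to a phased VCF.
#' @param phenotypes path to the phenotype/covariate TSV (sample_id, status,
#'   PC1, PC2).
#' @param out_dir output directory.
#' @param regions optional BED path restricting the loaded variants.
#' @param enhancers optional BED path of enhancer peaks for annotation.
#' @param lead_override optional variant id pinned as the lead.
#' @param alpha family-wise significance level.
#' @param maf_threshold common-variant MAF floor.
#' @param models epistasis models to fit.
#' @param r2_cluster LD-cluster linkage threshold.
#' @param seed integer seed recorded in the manifest (the scan itself is
#'   deterministic).
#' @return invisibly, a list with the scan objects and the manifest.
#' @export
run_scan <- function(vcf, phenotypes, out_dir,
                     regions = NULL, enhancers = NULL,
                     lead_override = NULL, alpha = 0.05,
                     maf_threshold = 0.05,
                     models = c("phase_independent", "cis", "trans",
                                "cis_and_trans"),
                     r2_cluster = 0.8, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  result <- tryCatch({
    reg <- if (!is.null(regions)) read_regions_bed(regions) else NULL
    geno <- read_phased_vcf(vcf, reg)
    ph <- read_phenotypes(phenotypes)
    ph <- ph[match(geno$samples, ph$sample_id), ]
    if (anyNA(ph$sample_id)) stop("phenotype table is missing samples")
    y <- ph$status
    cv <- ph[, intersect(c("PC1", "PC2"), names(ph)), drop = FALSE]

    stage <- "maf_filter"
    geno <- filter_by_maf(geno, maf_threshold)

    stage <- "marginal_scan"
    marg <- marginal_scan(geno, y, cv)
    write_tsv <- function(df, name) {
      p <- file.path(out_dir, paste0(name, ".tsv"))
      out <- df
      for (cl in names(out))
        if (is.numeric(out[[cl]]) && grepl("^p", cl))
          out[[cl]] <- formatC(out[[cl]], format = "e", digits = 5)
      write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    write_tsv(marg, "marginal")

    stage <- "lead_selection"
    lead <- select_lead_variant(marg, override = lead_override)$id

    stage <- "conditional_scan"
    cond <- conditional_scan(geno, y, cv, lead)
    write_tsv(cond, "conditional")

    stage <- "epistasis_scan"
    scan <- epistasis_scan(geno, lead, y, cv, models = models,
                           alpha = alpha)
    tab <- scan$table
    if (!is.null(enhancers)) {
      enh <- read_regions_bed(enhancers)
      vsub <- geno$variants[match(tab$id, geno$variants$id), ]
      tab$in_enhancer <- as.logical(annotate_intervals(vsub, enh,
                                                       "enhancer"))
      scan$table <- tab
    }
    write_tsv(tab, "epistasis_scan")

    stage <- "ld_clusters"
    hits <- tab[tab$sig_any, c("id", "pos", "best_p")]
    names(hits)[3] <- "p"
    clusters <- if (nrow(hits))
      ld_clusters(hits, geno, r2_threshold = r2_cluster) else NULL
    if (!is.null(clusters)) write_tsv(clusters, "ld_clusters")

    stage <- "secondary_epistasis"
    secondary <- NULL
    if (nrow(hits) > 1) {
      top <- hits$id[which.min(hits$p)]
      kinds <- setNames(tab$best_model[match(hits$id, tab$id)], hits$id)
      secondary <- secondary_epistasis(geno, lead, top,
                                       setdiff(hits$id, top), y, cv,
                                       models = kinds)
      write_tsv(secondary, "secondary_epistasis")
    }

    stage <- "manifest"
    manifest <- list(
      package = "epiphase",
      version = as.character(utils::packageVersion("epiphase")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed, alpha = alpha, maf_threshold = maf_threshold,
      models = models, lead = lead,
      lead_override = !is.null(lead_override),
      m_eff = scan$m_eff, threshold = scan$threshold,
      r2_cluster = r2_cluster,
      counts = list(variants_tested = nrow(tab),
                    marginal_rows = nrow(marg),
                    significant_any = sum(tab$sig_any),
                    clusters = if (is.null(clusters)) 0
                               else length(unique(clusters$cluster)),
                    secondary_rows = if (is.null(secondary)) 0
                                     else nrow(secondary)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(geno = geno, marginal = marg, conditional = cond, lead = lead,
         scan = scan, clusters = clusters, secondary = secondary,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
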