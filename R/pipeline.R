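#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one
#' serializable object. Defaults match the conventional values for a
#' small-cohort ddRAD association study: depth 5x to twice the mean,
#' <= 10% missingness, MAF >= 0.03, FDR thresholds 0.05/0.1, RDA
#' loading screen at +-2.5 SD, and 1000 phenotype randomizations.
#'
#' @param vcf,phenotype_csv,out_dir input/output paths (may be `NULL`
#'   when the pipeline is run on in-memory objects).
#' @param filter a [filter_config] (or a list of its fields).
#' @param lfmm_k latent factor count (`NULL` = automatic via
#'   [choose_k()]).
#' @param lfmm_lambda ridge penalty.
#' @param rda_sd_cut,rda_scale_loci RDA screen settings.
#' @param fdr_method `"storey"` or `"bh"`.
#' @param null_iter phenotype randomizations.
#' @param mantel_perm Mantel test permutations.
#' @param polygenic_k,polygenic_method polygenic refit settings.
#' @param seed global seed; per-stage child seeds are derived from it
#'   by fixed offsets so stages can be rerun independently.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, phenotype_csv = NULL, out_dir = NULL,
                       filter = filter_config(), lfmm_k = NULL,
                       lfmm_lambda = 1e-5, rda_sd_cut = 2.5,
                       rda_scale_loci = FALSE,
                       fdr_method = c("storey", "bh"),
                       null_iter = 1000, mantel_perm = 9999,
                       polygenic_k = 0,
                       polygenic_method = c("lfmm", "ridge"),
                       seed = 1L) {
  if (!inherits(filter, "filter_config"))
    filter <- do.call(filter_config, as.list(filter))
  structure(list(
    vcf = vcf, phenotype_csv = phenotype_csv, out_dir = out_dir,
    filter = filter, lfmm_k = lfmm_k, lfmm_lambda = lfmm_lambda,
    rda_sd_cut = rda_sd_cut, rda_scale_loci = rda_scale_loci,
    fdr_method = match.arg(fdr_method), null_iter = null_iter,
    mantel_perm = mantel_perm, polygenic_k = polygenic_k,
    polygenic_method = match.arg(polygenic_method),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' `load_config(save_config(cfg))` reproduces `cfg` exactly.
#'
#' @param cfg a [run_config].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config`
#'   returns a [run_config].
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$filter <- unclass(x$filter)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  flt <- x$filter
  if (!is.null(flt$max_depth_factor) && identical(flt$max_depth_factor, ".inf"))
    flt$max_depth_factor <- Inf
  x$filter <- do.call(filter_config, flt)
  do.call(run_config, x)
}

# deterministic child seed for a named stage
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, filter = 101L, mantel = 211L, gwas = 307L,
               lfmm = 401L, rda = 503L, null = 601L, polygenic = 701L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full association pipeline
#'
#' Executes the complete analysis: VCF filtering, phenotype
#' construction and checks (normality, site/plot ANOVA, relatedness
#' Mantel test), the three association scans (GWAS, ridge LFMM, RDA),
#' cross-method concordance with ddRADtag collapsing, the
#' phenotype-randomization null, per-locus statistics and site
#' interaction ANCOVA for concordant loci, and the polygenic model on
#' loci supported by at least two methods. With the same configuration
#' and seed, reruns are identical for every stage.
#'
#' @param cfg a [run_config]; alternatively supply `geno` and `pheno`
#'   directly to skip file input.
#' @param geno optional [dosage_matrix] (overrides `cfg$vcf`).
#' @param pheno optional [phenotype_table] (overrides
#'   `cfg$phenotype_csv`).
#' @return A list of class `pipeline_result` with elements `geno`,
#'   `pheno`, `normality`, `anova`, `mantel`, `gwas`, `lfmm`, `rda`,
#'   `concordance`, `null`, `candidate_stats` (per-locus R2 and ANCOVA
#'   for loci flagged by >= 2 methods), `polygenic` (`NULL` when no
#'   locus reaches double concordance) and `config`.
#' @export
run_all <- function(cfg = run_config(), geno = NULL, pheno = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "input"
  result <- tryCatch({
    if (is.null(geno)) {
      stage <- "filter"
      if (is.null(cfg$vcf)) stop("no VCF path and no in-memory genotypes")
      geno <- filter_sites(read_vcf(cfg$vcf), cfg$filter)
    }
    if (is.null(pheno)) {
      stage <- "phenotype"
      if (is.null(cfg$phenotype_csv)) stop("no phenotype CSV path or table")
      pheno <- phenotype_table(utils::read.csv(cfg$phenotype_csv,
                                               stringsAsFactors = FALSE))
    }
    stage <- "align"
    shared <- intersect(geno$individual_ids, pheno$id)
    if (length(shared) < 3) stop("fewer than 3 individuals shared between ",
                                 "genotypes and phenotype")
    geno <- subset_dosage(geno, individuals = shared)
    pheno <- pheno[match(shared, pheno$id), ]
    pheno <- phenotype_table(pheno[, c("id", "site", "plot",
                                       "distance_cm", "days")])

    stage <- "phenotype checks"
    anova_tab <- site_anova(pheno)
    A <- relatedness_matrix(geno)
    mantel <- mantel_growth_vs_relatedness(
      A, pheno, n_perm = cfg$mantel_perm,
      seed = stage_seed(cfg$seed, "mantel"))

    stage <- "gwas"
    gwas <- gwas_scan(geno, pheno, fdr_method = cfg$fdr_method)
    stage <- "lfmm"
    lfmm <- lfmm_scan(geno, pheno, K = cfg$lfmm_k,
                      lambda = cfg$lfmm_lambda,
                      fdr_method = cfg$fdr_method)
    stage <- "rda"
    rda <- rda_scan(geno, pheno, scale_loci = cfg$rda_scale_loci,
                    sd_cut = cfg$rda_sd_cut)

    stage <- "concordance"
    conc <- concordance(gwas, lfmm, rda)
    stage <- "randomization null"
    nullc <- randomization_null(geno, pheno, n_iter = cfg$null_iter,
                                seed = stage_seed(cfg$seed, "null"),
                                fdr_method = cfg$fdr_method)

    stage <- "candidate statistics"
    multi <- c(conc$sets$double, conc$sets$triple)
    cand_stats <- NULL
    if (length(multi)) {
      cand_stats <- merge(per_locus_r2(geno, pheno, multi),
                          site_interaction_ancova(geno, pheno, multi),
                          by = "locus_id")
    }
    stage <- "polygenic"
    poly <- NULL
    if (length(multi)) {
      poly <- polygenic_fit(geno, pheno, multi, K = cfg$polygenic_k,
                            lambda = cfg$lfmm_lambda,
                            method = cfg$polygenic_method)
    }
    list(geno = geno, pheno = pheno,
         normality = attr(pheno, "normality"), anova = anova_tab,
         relatedness = A, mantel = mantel, gwas = gwas, lfmm = lfmm,
         rda = rda, concordance = conc, null = nullc,
         candidate_stats = cand_stats, polygenic = poly, config = cfg)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  class(result) <- "pipeline_result"
  if (!is.null(cfg$out_dir)) report(result, cfg$out_dir)
  result
}

#' Write the pipeline report bundle
#'
#' Emits every stage's tabular output (Manhattan-ready TSVs for the
#' three methods, concordance tables, null-distribution counts,
#' polygenic predictions) plus a JSON summary with full provenance
#' (settings, seeds, method metadata).
#'
#' @param result a `pipeline_result` from [run_all()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
report <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) write_assoc_tsv(df, file.path(out_dir, name))
  w(result$gwas, "gwas.tsv")
  w(result$lfmm, "lfmm.tsv")
  w(result$rda$loadings, "rda.tsv")
  w(result$concordance$loci, "concordance_loci.tsv")
  w(result$concordance$regions, "concordance_regions.tsv")
  utils::write.csv(data.frame(iteration = seq_along(result$null$counts),
                              n_discoveries = result$null$counts),
                   file.path(out_dir, "null_counts.csv"), row.names = FALSE)
  if (!is.null(result$candidate_stats))
    w(result$candidate_stats, "candidate_stats.tsv")
  if (!is.null(result$polygenic)) {
    utils::write.csv(data.frame(id = result$pheno$id,
                                observed = result$pheno$scaled_growth,
                                predicted = unname(result$polygenic$score)),
                     file.path(out_dir, "polygenic_predictions.csv"),
                     row.names = FALSE)
  }
  cfg <- result$config
  summary <- list(
    n_individuals = nrow(result$pheno),
    n_loci = length(result$geno$locus_ids),
    filter_log = if (!is.null(result$geno$filter_log))
      list(input = result$geno$filter_log$input,
           removed = as.list(result$geno$filter_log$removed),
           output = result$geno$filter_log$output) else NULL,
    normality = result$normality,
    anova = result$anova,
    mantel = result$mantel[c("r", "p")],
    gwas = list(fdr_method = attr(result$gwas, "fdr_method"),
                n_sig_q05 = sum(result$gwas$sig_q05, na.rm = TRUE),
                n_sig_q10 = sum(result$gwas$sig_q10, na.rm = TRUE)),
    lfmm = list(K = attr(result$lfmm, "K"),
                gif = attr(result$lfmm, "gif"),
                n_sig_q05 = sum(result$lfmm$sig_q05)),
    rda = list(sd_cut = result$rda$sd_cut,
               n_candidates = sum(result$rda$loadings$candidate)),
    concordance = lapply(result$concordance$sets, length),
    null = result$null$fractions,
    polygenic = if (!is.null(result$polygenic))
      list(n_loci = length(result$polygenic$locus_ids),
           r2 = result$polygenic$r2, p = unname(result$polygenic$p)) else NULL,
    seed = cfg$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(summary)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d individuals x %d loci\n",
              nrow(x$pheno), length(x$geno$locus_ids)))
  cat(sprintf("  GWAS: %d loci at q<0.05, %d at q<0.10\n",
              sum(x$gwas$sig_q05, na.rm = TRUE),
              sum(x$gwas$sig_q10, na.rm = TRUE)))
  cat(sprintf("  LFMM (K=%d, GIF=%.3f): %d loci at q<0.05\n",
              attr(x$lfmm, "K"), attr(x$lfmm, "gif"),
              sum(x$lfmm$sig_q05)))
  cat(sprintf("  RDA: %d loading outliers beyond +-%.1f SD\n",
              sum(x$rda$loadings$candidate), x$rda$sd_cut))
  print(x$concordance)
  if (!is.null(x$polygenic)) print(x$polygenic)
  invisible(x)
}
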