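#' Filter settings for the SNP filter cascade
#'
#' Defaults reproduce the standard ddRAD filtering regime for a small
#' wild cohort: per-genotype depth between 5x and twice the mean depth,
#' at most 10% missing calls per site, and minor allele frequency at
#' least 0.03.
#'
#' @param min_depth minimum per-genotype read depth (reads).
#' @param max_depth_factor per-genotype depth ceiling as a multiple of
#'   the mean depth over all genotypes.
#' @param max_missing maximum per-site fraction of missing genotypes.
#' @param min_maf minimum minor allele frequency (computed over
#'   non-missing calls).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 5, max_depth_factor = 2,
                          max_missing = 0.10, min_maf = 0.03) {
  stopifnot(min_depth >= 0, max_depth_factor > 0,
            max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 0.5)
  structure(list(min_depth = min_depth, max_depth_factor = max_depth_factor,
                 max_missing = max_missing, min_maf = min_maf),
            class = "filter_config")
}

#' Read a VCF into raw genotype records
#'
#' Thin wrapper over [vcfR::read.vcfR()] that extracts what the filter
#' cascade needs: CHROM (ddRADtag ID), POS, REF/ALT alleles, the
#' genotype matrix as ALT-allele counts, and per-genotype depth (DP)
#' when present. Half-calls (e.g. `./0`) and missing genotypes map to
#' `NA`.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @return A list of class `vcf_records` with elements `chrom`, `pos`,
#'   `ref`, `alt` (character vectors, one entry per site), `alt_count`
#'   (sites x individuals integer matrix of ALT allele counts, `NA` =
#'   missing), `dp` (same shape, numeric or `NULL` when FORMAT/DP is
#'   absent) and `individual_ids`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (nrow(vcf@fix) == 0L) stop("VCF '", path, "' contains no variant records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fmt <- vcfR::vcf_field_names(vcf, tag = "FORMAT")
  dp <- NULL
  if ("DP" %in% fmt$ID) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  }
  alt_count <- gt_to_alt_count(gt)
  structure(list(
    chrom = unname(vcf@fix[, "CHROM"]),
    pos = as.integer(vcf@fix[, "POS"]),
    ref = unname(vcf@fix[, "REF"]),
    alt = unname(vcf@fix[, "ALT"]),
    alt_count = alt_count,
    dp = dp,
    individual_ids = colnames(gt)
  ), class = "vcf_records")
}

# GT strings -> ALT allele counts; any half/missing call -> NA
gt_to_alt_count <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    suppressWarnings(sum(as.integer(al) > 0L))
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Apply the SNP filter cascade and code minor-allele dosages
#'
#' Applies, in a fixed order, the filter cascade used for ddRAD SNP
#' matrices: (1) drop indels and sites with more than two alleles;
#' (2) mask individual genotypes whose depth is below `min_depth` or
#' above `max_depth_factor` times the mean depth (mean taken over all
#' non-missing genotype depths of biallelic SNP sites, before masking);
#' (3) drop sites with more than `max_missing` missing genotypes;
#' (4) drop sites with minor allele frequency below `min_maf`. Surviving
#' genotypes are coded as minor-allele dosage in {0, 0.5, 1}; when REF
#' and ALT are equally frequent the tie is broken toward ALT and logged.
#'
#' @param records a `vcf_records` object from [read_vcf()].
#' @param cfg a [filter_config].
#' @return A [dosage_matrix] whose `filter_log` element (class
#'   `filter_log`) records per-rule removal counts, the depth-mask
#'   count, mean depth, and the allele-orientation table.
#' @export
filter_sites <- function(records, cfg = filter_config()) {
  stopifnot(inherits(records, "vcf_records"), inherits(cfg, "filter_config"))
  n_in <- length(records$chrom)
  if (n_in < 1L) stop("no records to filter")

  # rule 1: indels and multi-allelic sites
  is_indel <- nchar(records$ref) != 1L |
    vapply(strsplit(records$alt, ","), function(a) any(nchar(a) != 1L), logical(1))
  is_multi <- grepl(",", records$alt, fixed = TRUE)
  n_indel <- sum(is_indel)
  n_multi <- sum(is_multi & !is_indel)
  keep1 <- !(is_indel | is_multi)

  ac <- records$alt_count[keep1, , drop = FALSE]
  dp <- if (is.null(records$dp)) NULL else records$dp[keep1, , drop = FALSE]
  chrom <- records$chrom[keep1]
  pos <- records$pos[keep1]

  # rule 2: per-genotype depth mask
  n_masked <- 0L
  mean_dp <- NA_real_
  if (!is.null(dp)) {
    mean_dp <- mean(dp[!is.na(ac)], na.rm = TRUE)
    mask <- !is.na(dp) & (dp < cfg$min_depth | dp > cfg$max_depth_factor * mean_dp)
    mask[is.na(mask)] <- FALSE
    n_masked <- sum(mask & !is.na(ac))
    ac[mask] <- NA_integer_
  }

  # rule 3: per-site missingness
  miss <- rowMeans(is.na(ac))
  keep3 <- miss <= cfg$max_missing
  n_missing <- sum(!keep3)
  ac <- ac[keep3, , drop = FALSE]
  chrom <- chrom[keep3]; pos <- pos[keep3]

  # rule 4: minor allele frequency over non-missing calls
  n_obs <- rowSums(!is.na(ac))
  alt_freq <- rowSums(ac, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  maf <- pmin(alt_freq, 1 - alt_freq)
  keep4 <- maf >= cfg$min_maf & n_obs > 0L
  n_maf <- sum(!keep4)
  ac <- ac[keep4, , drop = FALSE]
  chrom <- chrom[keep4]; pos <- pos[keep4]
  alt_freq <- alt_freq[keep4]

  flog <- structure(list(
    input = n_in,
    removed = c(indel = n_indel, multiallelic = n_multi,
                missingness = n_missing, maf = n_maf),
    output = nrow(ac),
    genotypes_depth_masked = n_masked,
    mean_depth = mean_dp,
    config = cfg
  ), class = "filter_log")

  if (nrow(ac) == 0L) {
    cond <- simpleError("no loci survive the filter cascade")
    cond$filter_log <- flog
    stop(cond)
  }

  # minor-allele orientation; tie at 0.5 broken toward ALT
  alt_is_minor <- alt_freq <= 0.5
  flog$n_ties_alt <- sum(alt_freq == 0.5)
  dos <- ac / 2
  dos[!alt_is_minor, ] <- 1 - dos[!alt_is_minor, , drop = FALSE]
  dosage_matrix(t(dos),
                locus_ids = paste0(chrom, ":", pos),
                individual_ids = records$individual_ids,
                coded_allele = unname(ifelse(alt_is_minor, "ALT", "REF")),
                filter_log = flog)
}

#' @export
print.filter_log <- function(x, ...) {
  cat("SNP filter cascade:\n")
  cat(sprintf("  input sites: %d\n", x$input))
  for (nm in names(x$removed))
    cat(sprintf("  removed (%s): %d\n", nm, x$removed[[nm]]))
  cat(sprintf("  genotypes masked by depth: %d (mean depth %.2f)\n",
              x$genotypes_depth_masked, x$mean_depth))
  cat(sprintf("  output sites: %d\n", x$output))
  invisible(x)
}

#' @export
as.data.frame.filter_log <- function(x, ...) {
  data.frame(rule = c("input", names(x$removed), "output"),
             count = c(x$input, unname(x$removed), x$output))
}
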