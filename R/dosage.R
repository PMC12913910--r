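#' Minor-allele dosage matrix
#'
#' The central genotype container of the package: an individuals x loci
#' matrix of minor-allele dosages coded 0 (homozygous major), 0.5
#' (heterozygous) and 1 (homozygous minor), with `NA` marking missing
#' calls. Locus identifiers follow the ddRAD convention `"tag:pos"`,
#' where the tag is the assembled short contig the SNP was called on.
#'
#' @param values numeric matrix, individuals in rows, loci in columns;
#'   entries must be 0, 0.5, 1 or `NA`.
#' @param locus_ids character vector of `"tag:pos"` locus identifiers.
#' @param individual_ids character vector of individual labels.
#' @param coded_allele optional character vector recording, per locus,
#'   which VCF allele (`"REF"` or `"ALT"`) the dosage counts.
#' @param filter_log optional [filter_log] describing how the matrix was
#'   derived from a VCF.
#'
#' @return An object of class `dosage_matrix`: a list with elements
#'   `values`, `locus_ids`, `individual_ids`, `maf` (per-locus minor
#'   allele frequency over non-missing calls), `missing_rate` (per-locus
#'   fraction missing), `coded_allele` and `filter_log`.
#' @export
dosage_matrix <- function(values, locus_ids = colnames(values),
                          individual_ids = rownames(values),
                          coded_allele = NULL, filter_log = NULL) {
  values <- as.matrix(values)
  if (is.null(locus_ids)) locus_ids <- paste0("tag", seq_len(ncol(values)), ":1")
  if (is.null(individual_ids)) individual_ids <- sprintf("ind_%02d", seq_len(nrow(values)))
  ok <- values %in% c(0, 0.5, 1) | is.na(values)
  if (!all(ok)) stop("dosage values must be 0, 0.5, 1 or NA")
  if (length(locus_ids) != ncol(values)) stop("locus_ids length must match ncol(values)")
  if (length(individual_ids) != nrow(values)) stop("individual_ids length must match nrow(values)")
  dimnames(values) <- list(individual_ids, locus_ids)
  obj <- list(
    values = values,
    locus_ids = locus_ids,
    individual_ids = individual_ids,
    maf = dosage_maf(values),
    missing_rate = colMeans(is.na(values)),
    coded_allele = coded_allele,
    filter_log = filter_log
  )
  class(obj) <- "dosage_matrix"
  obj
}

# per-locus minor allele frequency of the coded allele over non-missing calls
dosage_maf <- function(values) {
  f <- colMeans(values, na.rm = TRUE)
  pmin(f, 1 - f)
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d individuals x %d loci\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  MAF range: %.3f-%.3f; overall missingness: %.2f%%\n",
              min(x$maf), max(x$maf), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$values)

#' Subset a dosage matrix
#'
#' @param x a [dosage_matrix].
#' @param individuals,loci index vectors (integer, logical or character)
#'   selecting rows and columns; missing means keep all.
#' @return A [dosage_matrix] restricted to the selection.
#' @export
subset_dosage <- function(x, individuals = NULL, loci = NULL) {
  stopifnot(inherits(x, "dosage_matrix"))
  i <- if (is.null(individuals)) seq_len(nrow(x$values)) else individuals
  j <- if (is.null(loci)) seq_len(ncol(x$values)) else loci
  if (is.character(i)) i <- match(i, x$individual_ids)
  if (is.character(j)) j <- match(j, x$locus_ids)
  if (anyNA(i)) stop("unknown individual ID in subset")
  if (anyNA(j)) stop("unknown locus ID in subset")
  v <- x$values[i, j, drop = FALSE]
  dosage_matrix(v, locus_ids = x$locus_ids[j],
                individual_ids = x$individual_ids[i],
                coded_allele = x$coded_allele[j],
                filter_log = x$filter_log)
}

#' Mean-impute missing dosages
#'
#' Replaces each missing entry by the mean observed dosage at that locus,
#' leaving observed entries untouched. Column means are exactly preserved.
#' Matrix-based stages (relatedness, LFMM, RDA, polygenic scores) require
#' a complete matrix; mean imputation is the deliberately simple default
#' for small cohorts with low missingness.
#'
#' @param geno a [dosage_matrix].
#' @return A [dosage_matrix] with no missing values (imputed entries are
#'   locus means, generally off the 0/0.5/1 grid); attribute
#'   `imputed` set to `TRUE`.
#' @export
impute_mean <- function(geno) {
  stopifnot(inherits(geno, "dosage_matrix"))
  v <- geno$values
  if (!anyNA(v)) {
    attr(geno, "imputed") <- TRUE
    return(geno)
  }
  mu <- colMeans(v, na.rm = TRUE)
  if (anyNA(mu)) stop("cannot impute a locus with no observed calls")
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- mu[idx[, 2]]
  out <- geno
  out$values <- v
  out$missing_rate <- colMeans(is.na(v))
  attr(out, "imputed") <- TRUE
  out
}

# complete numeric matrix from a dosage_matrix, imputing if needed
complete_matrix <- function(geno) {
  stopifnot(inherits(geno, "dosage_matrix"))
  if (anyNA(geno$values)) impute_mean(geno)$values else geno$values
}

#' SNP error rate between technical replicates
#'
#' Fraction of loci, among those with non-missing calls in both members
#' of a replicate pair, at which the two dosage calls disagree. Used to
#' check genotyping repeatability (expected well below 1% for a sound
#' ddRAD dataset).
#'
#' @param geno a [dosage_matrix].
#' @param replicate_pairs a list of length-2 character vectors, or a
#'   two-column matrix/data.frame, of individual IDs forming pairs.
#' @return A data.frame with one row per pair: `id1`, `id2`,
#'   `n_compared` (loci non-missing in both), `n_mismatch`, `error_rate`.
#' @export
replicate_error_rate <- function(geno, replicate_pairs) {
  stopifnot(inherits(geno, "dosage_matrix"))
  if (is.matrix(replicate_pairs) || is.data.frame(replicate_pairs)) {
    replicate_pairs <- lapply(seq_len(nrow(replicate_pairs)),
                              function(i) as.character(unlist(replicate_pairs[i, 1:2])))
  }
  res <- lapply(replicate_pairs, function(pr) {
    if (length(pr) != 2L) stop("each replicate pair must name exactly two individuals")
    i <- match(pr, geno$individual_ids)
    if (anyNA(i)) stop("unknown individual ID: ", paste(pr[is.na(i)], collapse = ", "))
    a <- geno$values[i[1], ]
    b <- geno$values[i[2], ]
    both <- !is.na(a) & !is.na(b)
    if (!any(both)) stop("no loci comparable between ", pr[1], " and ", pr[2],
                         " (disjoint missingness); error rate undefined")
    data.frame(id1 = pr[1], id2 = pr[2],
               n_compared = sum(both),
               n_mismatch = sum(a[both] != b[both]),
               error_rate = mean(a[both] != b[both]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a dosage matrix as TSV
#'
#' Individuals in rows, loci in columns, `NA` for missing.
#'
#' @param geno a [dosage_matrix].
#' @param path output file path.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "dosage_matrix"))
  df <- data.frame(id = geno$individual_ids, geno$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
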