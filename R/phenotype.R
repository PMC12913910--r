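#' Lamina elongation rate from hole-punch distances
#'
#' Kelp growth is measured non-destructively by punching a hole in the
#' lamina 5 cm above the meristem and recording how far it has moved
#' distally after a known number of days. The elongation rate is the
#' measured distance minus the punch offset, divided by elapsed days.
#'
#' @param distance_cm measured hole-to-meristem distance (cm); vectorized.
#' @param days elapsed days between measurements; must be positive.
#' @param offset_cm initial punch distance from the meristem (cm).
#' @return Elongation rate in cm/day.
#' @export
#' @examples
#' elongation_rate(14.48, 79)  # 0.12 cm/day
elongation_rate <- function(distance_cm, days, offset_cm = 5) {
  if (any(days <= 0)) stop("days must be positive")
  if (any(distance_cm < offset_cm))
    stop("distance_cm below the punch offset (", offset_cm,
         " cm): a hole cannot regress toward the meristem")
  (distance_cm - offset_cm) / days
}

#' Log-transform and scale growth rates, with normality checks
#'
#' Applies the log10 transform used for the analysis phenotype, z-scores
#' it over the cohort, and reports Shapiro-Wilk normality statistics for
#' both the raw and transformed vectors. The normality report is
#' informational only; it never switches the transform automatically.
#'
#' @param rates positive growth rates (cm/day).
#' @param ids optional individual labels used in error messages.
#' @return A list with `log_growth`, `scaled_growth` (mean 0, SD 1) and
#'   `normality`, a data.frame with Shapiro-Wilk `W` and `p` for the raw
#'   and log10 scales.
#' @export
transform_growth <- function(rates, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(rates))
  bad <- which(!is.finite(rates) | rates <= 0)
  if (length(bad))
    stop("non-positive growth rate for individual(s): ",
         paste(ids[bad], collapse = ", "))
  if (stats::sd(rates) == 0)
    stop("all growth rates identical: z-scoring is undefined")
  lg <- log10(rates)
  sw_raw <- stats::shapiro.test(rates)
  sw_log <- stats::shapiro.test(lg)
  list(
    log_growth = lg,
    scaled_growth = as.vector(scale(lg)),
    normality = data.frame(
      scale = c("raw", "log10"),
      W = c(unname(sw_raw$statistic), unname(sw_log$statistic)),
      p = c(sw_raw$p.value, sw_log$p.value)
    )
  )
}

#' Build the analysis phenotype table
#'
#' Turns a field-measurement table (`id`, `site`, `plot`, `distance_cm`,
#' `days`) into the analysis phenotype: elongation rate, its log10
#' transform and the cohort z-score, carrying the Shapiro-Wilk normality
#' report as an attribute.
#'
#' @param df a data.frame with columns `id`, `site`, `plot`,
#'   `distance_cm`, `days`.
#' @param offset_cm hole-punch offset passed to [elongation_rate()].
#' @return A data.frame of class `phenotype_table` with added columns
#'   `growth_rate`, `log_growth`, `scaled_growth`; attribute
#'   `normality` holds the Shapiro-Wilk report.
#' @export
phenotype_table <- function(df, offset_cm = 5) {
  need <- c("id", "site", "plot", "distance_cm", "days")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicated individual IDs in phenotype table")
  df$growth_rate <- elongation_rate(df$distance_cm, df$days, offset_cm)
  tr <- transform_growth(df$growth_rate, ids = df$id)
  df$log_growth <- tr$log_growth
  df$scaled_growth <- tr$scaled_growth
  attr(df, "normality") <- tr$normality
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' One-way ANOVA of log growth across sites and plots
#'
#' Tests for differences in log growth across field sites, and across
#' plot labels nested within site (each site:plot combination treated as
#' one group, matching a one-way layout).
#'
#' @param pheno a [phenotype_table].
#' @return A data.frame with one row per factor (`site`,
#'   `plot_within_site`): `df1`, `df2`, `F`, `p`.
#' @export
site_anova <- function(pheno) {
  stopifnot(inherits(pheno, "phenotype_table"))
  one_way <- function(fac, label) {
    fac <- factor(fac)
    if (nlevels(fac) < 2)
      stop("factor '", label, "' has a single level; ANOVA undefined")
    if (any(table(fac) < 2))
      stop("factor '", label, "' has a group with fewer than 2 members")
    fit <- stats::aov(pheno$log_growth ~ fac)
    s <- summary(fit)[[1]]
    data.frame(factor = label, df1 = s$Df[1], df2 = s$Df[2],
               F = s$`F value`[1], p = s$`Pr(>F)`[1])
  }
  rbind(one_way(pheno$site, "site"),
        one_way(interaction(pheno$site, pheno$plot, drop = TRUE),
                "plot_within_site"))
}

#' Genomic relationship (A) matrix, VanRaden method 1
#'
#' Additive genomic relationships among individuals: with per-locus
#' allele dosage d in [0, 2] (twice the stored minor-allele dosage) and
#' observed allele frequency p_l, `A = W W' / (2 * sum p_l (1 - p_l))`
#' with `W[i,l] = d[i,l] - 2 p_l`. Monomorphic loci contribute nothing
#' and are skipped. Missing dosages must be imputed first (done
#' internally by locus-mean imputation when present).
#'
#' @param geno a [dosage_matrix].
#' @return A symmetric positive semi-definite matrix of class
#'   `relatedness_matrix` with individual IDs as dimnames; diagonal is
#'   approximately 1 + inbreeding.
#' @export
relatedness_matrix <- function(geno) {
  stopifnot(inherits(geno, "dosage_matrix"))
  d <- 2 * complete_matrix(geno)
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all loci are monomorphic; relatedness undefined")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(d, 2, 2 * p)
  A <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(A) <- list(geno$individual_ids, geno$individual_ids)
  class(A) <- c("relatedness_matrix", "matrix")
  A
}

#' Mantel test of growth differences against genomic relatedness
#'
#' Correlates pairwise genetic distance, taken as `max(A) - A`, with
#' pairwise absolute differences in log growth, and assesses
#' significance by permuting individual labels of one matrix. The
#' one-sided p-value is `(1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param A a [relatedness_matrix].
#' @param pheno a [phenotype_table] in the same individual order.
#' @param n_perm number of permutations (at least 99).
#' @param seed optional RNG seed.
#' @return A list with `r` (Pearson correlation of the off-diagonal
#'   distances), `p` and `n_perm`.
#' @export
mantel_growth_vs_relatedness <- function(A, pheno, n_perm = 9999,
                                         seed = NULL) {
  stopifnot(inherits(A, "relatedness_matrix"),
            inherits(pheno, "phenotype_table"))
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (nrow(A) != nrow(pheno)) stop("A and pheno disagree on cohort size")
  if (!is.null(rownames(A)) && !identical(rownames(A), pheno$id))
    stop("individual order of A and pheno must match")
  if (!is.null(seed)) set.seed(seed)
  Dg <- max(A) - unclass(A)
  lg <- pheno$log_growth
  Dy <- abs(outer(lg, lg, "-"))
  low <- lower.tri(Dg)
  r_obs <- stats::cor(Dg[low], Dy[low])
  n <- nrow(Dg)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    o <- sample.int(n)
    stats::cor(Dg[o, o][low], Dy[low])
  }, numeric(1))
  list(r = r_obs,
       p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
       n_perm = n_perm)
}
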