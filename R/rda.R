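#' Redundancy analysis of genotypes constrained by growth
#'
#' Constrained ordination of the (centered, complete) dosage matrix on a
#' single phenotype variable. With one predictor the fitted matrix
#' `G_hat = P_x G_c` (projection of each locus onto the phenotype) has
#' rank one, so there is exactly one constrained axis; its per-locus
#' loadings are the entries of the right singular vector of `G_hat`,
#' which are proportional to the per-locus covariance between dosage
#' and the phenotype. The axis is oriented so that the individual
#' scores correlate non-negatively with the phenotype.
#'
#' @param geno a [dosage_matrix].
#' @param x phenotype vector (conventionally scaled log growth) or a
#'   [phenotype_table] (its `scaled_growth` column is used).
#' @param scale_loci scale each locus to unit variance before the
#'   analysis (default `FALSE`: center only, the convention of
#'   constrained-ordination software).
#' @param sd_cut loading cutoff in standard deviations for candidate
#'   flagging (see [rda_candidates()]).
#' @return A list of class `rda_result`: `axis_scores` (individuals on
#'   the constrained axis), `loadings` (data.frame with `locus_id`,
#'   `loading`, `zscore`, `candidate`), `mean_loading`, `sd_loading`,
#'   `singular_value`, `prop_variance` (share of total genotypic
#'   variance captured by the constrained axis), `scale_loci`, `sd_cut`.
#' @export
rda_scan <- function(geno, x, scale_loci = FALSE, sd_cut = 2.5) {
  stopifnot(inherits(geno, "dosage_matrix"))
  if (inherits(x, "phenotype_table")) x <- x$scaled_growth
  x <- as.numeric(x)
  V <- complete_matrix(geno)
  if (length(x) != nrow(V)) stop("x length must match cohort size")
  xc <- x - mean(x)
  if (all(xc == 0)) stop("constraining variable x is constant")
  Gc <- sweep(V, 2, colMeans(V))
  if (scale_loci) {
    s <- sqrt(colSums(Gc^2) / (nrow(Gc) - 1))
    if (any(s == 0)) stop("cannot scale zero-variance loci")
    Gc <- sweep(Gc, 2, s, "/")
  }
  # rank-1 fitted matrix x_c b' with b the per-locus projection slopes
  b <- as.vector(crossprod(Gc, xc)) / sum(xc^2)
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("phenotype is orthogonal to every locus; no axis")
  loading <- b / nb
  sv <- sqrt(sum(xc^2)) * nb
  axis_scores <- xc * nb              # = u * singular value
  res <- structure(list(
    axis_scores = stats::setNames(axis_scores, geno$individual_ids),
    loadings = data.frame(locus_id = geno$locus_ids, loading = loading,
                          stringsAsFactors = FALSE),
    mean_loading = mean(loading),
    sd_loading = stats::sd(loading),
    singular_value = sv,
    prop_variance = sv^2 / sum(Gc^2),
    scale_loci = scale_loci,
    sd_cut = sd_cut
  ), class = "rda_result")
  cand <- rda_candidates(res, sd_cut = sd_cut)
  res$loadings$zscore <- cand$zscore
  res$loadings$candidate <- cand$candidate
  res
}

#' Flag candidate loci by the loading outlier rule
#'
#' A locus is a candidate when its loading on the constrained axis lies
#' more than `sd_cut` standard deviations from the mean loading (the
#' conventional +-2.5 SD screen for constrained-ordination outliers).
#'
#' @param res an [rda_scan()] result, or a bare numeric vector of
#'   loadings.
#' @param sd_cut cutoff in standard deviations (0 flags every locus).
#' @return A data.frame with `locus_id` (when available), `loading`,
#'   `zscore` (centered loading in SD units), `margin`
#'   (`|zscore| - sd_cut`) and logical `candidate`.
#' @export
rda_candidates <- function(res, sd_cut = 2.5) {
  if (inherits(res, "rda_result")) {
    loading <- res$loadings$loading
    ids <- res$loadings$locus_id
  } else {
    loading <- as.numeric(res)
    ids <- names(res)
  }
  mu <- mean(loading)
  s <- stats::sd(loading)
  z <- if (s == 0) rep(0, length(loading)) else (loading - mu) / s
  out <- data.frame(loading = loading, zscore = z,
                    margin = abs(z) - sd_cut,
                    candidate = abs(z) > sd_cut)
  if (!is.null(ids)) out <- cbind(locus_id = ids, out,
                                  stringsAsFactors = FALSE)
  out
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: 1 constrained axis, %.2f%% of genotypic variance\n",
              100 * x$prop_variance))
  cat(sprintf("  %d of %d loci beyond +-%.1f SD of the loading distribution\n",
              sum(x$loadings$candidate), nrow(x$loadings), x$sd_cut))
  invisible(x)
}
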