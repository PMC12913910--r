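# Vectorized per-locus simple linear regression of y on each dosage
# column. Handles missing dosages by per-locus complete-case sums.
# Returns beta, se, t, p, and the per-locus sample size.
ols_scan <- function(V, y) {
  M <- !is.na(V)
  V0 <- V
  V0[!M] <- 0
  n_l <- colSums(M)
  Sx <- colSums(V0)
  Sxx <- colSums(V0 * V0)
  Sy <- as.vector(crossprod(M, y))
  Syy <- as.vector(crossprod(M, y * y))
  Sxy <- as.vector(crossprod(V0, y))
  sxx <- Sxx - Sx^2 / n_l
  sxy <- Sxy - Sx * Sy / n_l
  syy <- Syy - Sy^2 / n_l
  ok <- n_l >= 3 & sxx > 0
  beta <- se <- tt <- p <- rep(NA_real_, ncol(V))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- pmax(syy[ok] - beta[ok] * sxy[ok], 0)
  df <- n_l[ok] - 2
  se[ok] <- sqrt(rss / df / sxx[ok])
  tt[ok] <- beta[ok] / se[ok]
  p[ok] <- pmax(2 * stats::pt(abs(tt[ok]), df, lower.tail = FALSE),
                .Machine$double.xmin)
  # constant phenotype within a locus's complete cases: degenerate, p = 1
  degy <- ok & syy <= 0
  tt[degy] <- 0
  p[degy] <- 1
  list(beta = beta, se = se, t = tt, p = p, n = n_l, ok = ok)
}

# t statistics for many phenotype vectors at once (complete dosage
# matrix); used by the permutation null. Y is individuals x m.
ols_scan_t_multi <- function(V, Y) {
  n <- nrow(V)
  Vc <- sweep(V, 2, colMeans(V))
  Yc <- sweep(Y, 2, colMeans(Y))
  sxx <- colSums(Vc * Vc)
  syy <- colSums(Yc * Yc)
  Sxy <- crossprod(Vc, Yc)              # loci x m
  r2 <- sweep(Sxy^2, 1, sxx, "/")
  r2 <- sweep(r2, 2, syy, "/")
  r2 <- pmin(r2, 1)
  sign(Sxy) * sqrt(r2 * (n - 2) / pmax(1 - r2, .Machine$double.eps))
}

#' Per-SNP linear-model association scan (GWAS)
#'
#' Fits an ordinary least squares model `log_growth ~ dosage`
#' independently at every locus, with no kinship or structure
#' adjustment (appropriate when relatedness shows no association with
#' the phenotype). P-values are two-sided t-tests on n-2 degrees of
#' freedom; q-values control the FDR and are flagged at the two
#' conventional thresholds 0.05 and 0.1.
#'
#' @param geno a [dosage_matrix].
#' @param pheno a [phenotype_table] in matching individual order.
#' @param use `"imputed"` (default: locus-mean imputation, consistent
#'   with the matrix-based methods) or `"complete"` (per-locus
#'   complete-case regression).
#' @param fdr_method passed to [fdr_qvalues()].
#' @return A data.frame of class `gwas_result`: `locus_id`, `n`, `beta`
#'   (log10 cm/day per dosage unit), `se`, `t`, `p`, `q`, `sig_q05`,
#'   `sig_q10`. The FDR method actually used is stored in attribute
#'   `fdr_method`; zero-variance loci (none expected after filtering)
#'   are flagged by `NA` statistics with a warning.
#' @export
gwas_scan <- function(geno, pheno, use = c("imputed", "complete"),
                      fdr_method = c("storey", "bh")) {
  stopifnot(inherits(geno, "dosage_matrix"),
            inherits(pheno, "phenotype_table"))
  use <- match.arg(use)
  if (nrow(geno$values) != nrow(pheno))
    stop("genotypes and phenotype disagree on cohort size")
  if (nrow(pheno) < 3) stop("need at least 3 individuals")
  V <- if (use == "imputed") complete_matrix(geno) else geno$values
  y <- pheno$log_growth
  sc <- ols_scan(V, y)
  if (any(!sc$ok))
    warning(sum(!sc$ok), " zero-variance or under-observed loci skipped")
  qv <- fdr_qvalues(sc$p[sc$ok], method = fdr_method)
  q <- rep(NA_real_, length(sc$p))
  q[sc$ok] <- qv
  out <- data.frame(locus_id = geno$locus_ids, n = sc$n,
                    beta = sc$beta, se = sc$se, t = sc$t, p = sc$p, q = q,
                    sig_q05 = !is.na(q) & q < 0.05,
                    sig_q10 = !is.na(q) & q < 0.10,
                    stringsAsFactors = FALSE)
  attr(out, "fdr_method") <- attr(qv, "method")
  attr(out, "use") <- use
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' FDR q-values (Storey with Benjamini-Hochberg fallback)
#'
#' Storey q-values estimate the null proportion pi0 from the p-value
#' distribution via the smoother method (a df-3 cubic spline through
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` on a lambda grid,
#' evaluated at the largest lambda), then set
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`. Benjamini-Hochberg is
#' the special case pi0 = 1 and is used as a fallback whenever pi0
#' estimation is unstable (fewer than 100 p-values, or a non-positive
#' estimate).
#'
#' @param p p-values in (0, 1].
#' @param method `"storey"` (default) or `"bh"`.
#' @return q-values in the input order; attributes `method` (the method
#'   actually used) and `pi0`.
#' @export
fdr_qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  pi0 <- 1
  used <- "bh"
  if (method == "storey" && m >= 100) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lam, pi0_lam, df = 3)
    pi0_hat <- stats::predict(sp, x = max(lam))$y
    if (is.finite(pi0_hat) && pi0_hat > 0) {
      pi0 <- min(pi0_hat, 1)
      used <- "storey"
    }
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "method") <- used
  attr(q, "pi0") <- pi0
  q
}

#' Write association results as TSV
#'
#' @param result a `gwas_result`, `lfmm_result` or the loading table of
#'   an `rda_result` (any data.frame).
#' @param path output path.
#' @export
write_assoc_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
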