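#' Ridge latent factor mixed model fit
#'
#' Fits the latent factor mixed model with genotypes as the response:
#' minimizes `||G_c - x B' - U V'||_F^2 + lambda ||B||_F^2` over the
#' per-locus phenotype effects `B` (loci x 1), the latent scores `U`
#' (individuals x K) and loadings `V` (loci x K). Two solvers are
#' provided and agree at the global minimum:
#'
#' * `"analytic"` (default): the exact solution. Profiling out `B` turns
#'   the problem into a weighted low-rank approximation
#'   `min_W ||D (G_c - W)||_F^2` with the positive-definite reweighting
#'   `D^2 = Q diag(lambda / (lambda + sigma^2)) Q' + (I - Q Q')`, where
#'   `x = Q sigma` is the thin SVD of the explanatory variable. Since
#'   `D` is invertible, the optimal rank-K `W` is `D^{-1}` applied to
#'   the truncated SVD of `D G_c`, and `B` follows by ridge regression
#'   on the residual.
#' * `"als"`: block-coordinate descent alternating exact solves — the
#'   truncated SVD of `G_c - x B'` for `(U, V)` and per-locus ridge
#'   regression for `B` — until the relative objective change falls
#'   below `tol`. The objective is asserted non-increasing at every
#'   iteration.
#'
#' @param G_c centered (and complete) individuals x loci genotype
#'   matrix.
#' @param x explanatory phenotype vector (conventionally the scaled log
#'   growth).
#' @param K number of latent factors (K = 0 reduces to per-locus ridge
#'   regression of genotype on phenotype).
#' @param lambda ridge penalty (> 0); the conventional default is 1e-5.
#' @param solver `"analytic"` or `"als"`.
#' @param tol relative objective-change convergence tolerance (ALS).
#' @param max_iter maximum ALS iterations.
#' @return A list of class `lfmm_fit`: `K`, `lambda`, `U`, `V`, `B`,
#'   `objective` (the final penalized objective; for ALS the full
#'   trajectory is in `trajectory`), `solver`, `iterations`.
#' @export
lfmm_ridge <- function(G_c, x, K, lambda = 1e-5,
                       solver = c("analytic", "als"),
                       tol = 1e-8, max_iter = 500) {
  solver <- match.arg(solver)
  G_c <- as.matrix(G_c)
  x <- as.numeric(x)
  n <- nrow(G_c); L <- ncol(G_c)
  stopifnot(length(x) == n, lambda > 0, K >= 0)
  if (K >= min(n, L))
    stop("K must be smaller than min(n_individuals, n_loci) = ", min(n, L))

  obj_fun <- function(B, U, V) {
    W <- if (K > 0) U %*% t(V) else 0
    sum((G_c - tcrossprod(x, B) - W)^2) + lambda * sum(B^2)
  }
  s2 <- sum(x^2)
  if (s2 == 0) stop("explanatory variable x is identically zero")

  if (solver == "analytic") {
    q <- x / sqrt(s2)
    a <- sqrt(lambda / (lambda + s2))
    U <- matrix(0, n, 0); V <- matrix(0, L, 0)
    if (K > 0) {
      qtG <- crossprod(q, G_c)                       # 1 x L
      DG <- G_c + q %*% ((a - 1) * qtG)
      sv <- svd(DG, nu = K, nv = K)
      Ud <- sv$u[, seq_len(K), drop = FALSE] %*%
        diag(sv$d[seq_len(K)], K, K)
      # W = D^{-1} (Ud V'); fold D^{-1} into the factor scores
      U <- Ud + q %*% ((1 / a - 1) * crossprod(q, Ud))
      V <- sv$v[, seq_len(K), drop = FALSE]
    }
    R <- if (K > 0) G_c - tcrossprod(U, V) else G_c
    B <- as.vector(crossprod(R, x)) / (s2 + lambda)
    fit <- list(K = K, lambda = lambda, U = U, V = V, B = B,
                objective = obj_fun(B, U, V), solver = "analytic",
                iterations = 1L, trajectory = NULL)
  } else {
    B <- numeric(L)
    U <- matrix(0, n, 0); V <- matrix(0, L, 0)
    traj <- obj_fun(B, U, V)
    for (it in seq_len(max_iter)) {
      if (K > 0) {
        sv <- svd(G_c - tcrossprod(x, B), nu = K, nv = K)
        U <- sv$u[, seq_len(K), drop = FALSE] %*%
          diag(sv$d[seq_len(K)], K, K)
        V <- sv$v[, seq_len(K), drop = FALSE]
      }
      R <- if (K > 0) G_c - tcrossprod(U, V) else G_c
      B <- as.vector(crossprod(R, x)) / (s2 + lambda)
      o <- obj_fun(B, U, V)
      if (o > traj[length(traj)] * (1 + 1e-12) + 1e-12)
        stop("ALS objective increased at iteration ", it,
             " (", traj[length(traj)], " -> ", o, ")")
      converged <- abs(traj[length(traj)] - o) <=
        tol * max(traj[length(traj)], 1e-300)
      traj <- c(traj, o)
      if (converged) break
      if (it == max_iter) {
        cond <- simpleError(paste0("ALS did not converge in ", max_iter,
                                   " iterations"))
        cond$trajectory <- traj
        stop(cond)
      }
    }
    fit <- list(K = K, lambda = lambda, U = U, V = V, B = B,
                objective = traj[length(traj)], solver = "als",
                iterations = length(traj) - 1L, trajectory = traj)
  }
  class(fit) <- "lfmm_fit"
  fit
}

#' Genomic inflation factor
#'
#' `median(z^2)` divided by the median of the chi-square distribution
#' with one degree of freedom (0.4549364). Values near 1 indicate
#' calibrated test statistics; values well above 1 indicate confounding
#' inflation.
#'
#' @param z a vector of z (or t) statistics.
#' @return The genomic inflation factor (positive scalar).
#' @export
genomic_inflation <- function(z) {
  z <- z[is.finite(z)]
  if (!length(z)) stop("no finite statistics")
  stats::median(z^2) / stats::qchisq(0.5, df = 1)
}

#' Per-SNP association tests from a ridge LFMM fit
#'
#' Regresses each genotype column on the phenotype and the estimated
#' latent scores `[x, U]` and converts the t statistic of the phenotype
#' coefficient to an exactly standard-normal score (via the t tail
#' probability) — the per-locus `z`. The genomic inflation factor then
#' recalibrates the scores: calibrated `p` is the upper chi-square(1)
#' tail of `z^2 / gif`. The normal-score conversion matters at small n:
#' squared t statistics have a median a few percent above the
#' chi-square(1) median, which would otherwise masquerade as
#' confounding inflation. q-values control the FDR; loci are flagged at
#' q < 0.05.
#'
#' @param fit an [lfmm_ridge()] fit.
#' @param G_c the centered genotype matrix the model was fitted to.
#' @param x the phenotype vector used in the fit.
#' @param fdr_method passed to [fdr_qvalues()].
#' @return A data.frame of class `lfmm_result`: `locus_id` (when
#'   `G_c` has column names), `z`, `p_raw` (uncalibrated t-test
#'   p-value), `p` (GIF-calibrated), `q`, `sig_q05`. Attributes: `gif`,
#'   `K`, `lambda`, `fdr_method`.
#' @export
lfmm_test <- function(fit, G_c, x, fdr_method = c("storey", "bh")) {
  stopifnot(inherits(fit, "lfmm_fit"))
  G_c <- as.matrix(G_c)
  n <- nrow(G_c)
  X <- cbind(`(Intercept)` = 1, x = as.numeric(x), fit$U)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design [x, U] is rank-deficient; tests undefined")
  df <- n - ncol(X)
  if (df <= 0) stop("not enough individuals for ", ncol(X), " regressors")
  XtXinv <- chol2inv(qr.R(qrX))
  B <- XtXinv %*% crossprod(X, G_c)
  res <- G_c - X %*% B
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tt <- as.vector(B[2, ] / se)
  # exact normal scores; log-scale tail keeps extreme statistics finite
  lp <- stats::pt(abs(tt), df, lower.tail = FALSE, log.p = TRUE)
  z <- sign(tt) * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  gif <- genomic_inflation(z)
  p_raw <- pmin(2 * exp(lp), 1)
  p <- stats::pchisq(z^2 / gif, df = 1, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  q <- fdr_qvalues(p, method = fdr_method)
  out <- data.frame(
    locus_id = if (is.null(colnames(G_c))) paste0("L", seq_len(ncol(G_c)))
               else colnames(G_c),
    z = z, p_raw = p_raw, p = p, q = as.vector(q),
    sig_q05 = as.vector(q) < 0.05,
    stringsAsFactors = FALSE)
  attr(out, "gif") <- gif
  attr(out, "K") <- fit$K
  attr(out, "lambda") <- fit$lambda
  attr(out, "fdr_method") <- attr(q, "method")
  class(out) <- c("lfmm_result", "data.frame")
  out
}

#' Run the ridge LFMM association scan on a cohort
#'
#' Convenience wrapper: centers the (imputed) dosage matrix, fits
#' [lfmm_ridge()] with the scaled log growth as the explanatory
#' variable, and runs [lfmm_test()]. The number of latent factors is
#' the principal unreported tuning choice for this method; when `K` is
#' `NULL` it is chosen by [choose_k()] and recorded in the result
#' attributes.
#'
#' @param geno a [dosage_matrix].
#' @param pheno a [phenotype_table].
#' @param K latent factor count, or `NULL` for automatic selection.
#' @param lambda ridge penalty.
#' @param fdr_method passed to [fdr_qvalues()].
#' @return An `lfmm_result` (see [lfmm_test()]); attribute `K_auto`
#'   records whether K was chosen automatically.
#' @export
lfmm_scan <- function(geno, pheno, K = NULL, lambda = 1e-5,
                      fdr_method = c("storey", "bh")) {
  stopifnot(inherits(geno, "dosage_matrix"),
            inherits(pheno, "phenotype_table"))
  V <- complete_matrix(geno)
  G_c <- sweep(V, 2, colMeans(V))
  colnames(G_c) <- geno$locus_ids
  x <- pheno$scaled_growth
  auto <- is.null(K)
  if (auto) {
    K <- choose_k(G_c)
    message("LFMM latent factor count chosen automatically: K = ", K,
            " (override via the K argument; this setting materially ",
            "affects which loci are significant)")
  }
  fit <- lfmm_ridge(G_c, x, K = K, lambda = lambda)
  out <- lfmm_test(fit, G_c, x, fdr_method = fdr_method)
  attr(out, "K_auto") <- auto
  out
}

#' Recommend a latent factor count from the singular value spectrum
#'
#' Scree-based elbow rule: the candidate K is the position of the
#' largest consecutive singular-value ratio `s_k / s_{k+1}` among the
#' leading values; when no ratio clearly exceeds the bulk spectrum
#' (ratio < 1.2) there is no elbow and the fallback K = 1 is returned.
#' Always overridable in configuration.
#'
#' @param G_c centered genotype matrix.
#' @param k_max largest K considered.
#' @return Recommended K (integer >= 1); attribute `ratios` holds the
#'   inspected consecutive ratios.
#' @export
choose_k <- function(G_c, k_max = 10) {
  G_c <- as.matrix(G_c)
  d <- svd(G_c, nu = 0, nv = 0)$d
  if (max(d) == 0) stop("constant genotype matrix; spectrum undefined")
  m <- min(k_max + 1, sum(d > 1e-12))
  if (m < 2) stop("spectrum too short to assess an elbow")
  ratios <- d[seq_len(m - 1)] / d[2:m]
  k <- which.max(ratios)
  if (ratios[k] < 1.2) k <- 1L
  structure(as.integer(k), ratios = ratios)
}
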