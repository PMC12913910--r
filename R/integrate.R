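#' Cross-method concordance of candidate loci
#'
#' Classifies every locus by which detection methods flag it — GWAS at
#' the relaxed FDR < 0.10 threshold (the strict 0.05 flag is kept
#' alongside), LFMM at FDR < 0.05, and the RDA loading screen — into
#' concordance classes none/single/double/triple, and collapses flagged
#' loci that share a ddRADtag (the `tag` part of `"tag:pos"`) into
#' regions, since SNPs on one tag are tightly linked.
#'
#' @param gwas a `gwas_result`.
#' @param lfmm an `lfmm_result`.
#' @param rda an `rda_result`.
#' @return A list of class `concordance_report`: `loci` (per-locus
#'   data.frame with method flags, `n_methods` and `class`), `sets`
#'   (character vectors `single`, `double`, `triple` of locus IDs — each
#'   class exclusive), and `regions` (tag-collapsed data.frame for
#'   flagged loci: `tag`, `n_loci`, `members`, `best_class`).
#' @export
concordance <- function(gwas, lfmm, rda) {
  stopifnot(inherits(gwas, "gwas_result"), inherits(lfmm, "lfmm_result"),
            inherits(rda, "rda_result"))
  ids <- gwas$locus_id
  if (!identical(sort(ids), sort(lfmm$locus_id)) ||
      !identical(sort(ids), sort(rda$loadings$locus_id)))
    stop("the three methods were not run on the same locus universe")
  li <- lfmm[match(ids, lfmm$locus_id), ]
  ri <- rda$loadings[match(ids, rda$loadings$locus_id), ]
  flags <- cbind(gwas_q10 = gwas$sig_q10,
                 lfmm_q05 = li$sig_q05,
                 rda = ri$candidate)
  flags[is.na(flags)] <- FALSE
  n_methods <- rowSums(flags)
  cls <- c("none", "single", "double", "triple")[n_methods + 1]
  loci <- data.frame(locus_id = ids, tag = sub(":[^:]*$", "", ids),
                     gwas_q05 = gwas$sig_q05, flags,
                     n_methods = n_methods, class = cls,
                     stringsAsFactors = FALSE)
  flagged <- loci[loci$n_methods > 0, ]
  regions <- if (nrow(flagged)) {
    do.call(rbind, lapply(split(flagged, flagged$tag), function(d) {
      data.frame(tag = d$tag[1], n_loci = nrow(d),
                 members = paste(d$locus_id, collapse = ","),
                 best_class = c("single", "double", "triple")[max(d$n_methods)],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(tag = character(0), n_loci = integer(0),
               members = character(0), best_class = character(0))
  }
  rownames(regions) <- NULL
  structure(list(
    loci = loci,
    sets = list(single = ids[n_methods == 1],
                double = ids[n_methods == 2],
                triple = ids[n_methods == 3]),
    regions = regions
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  n <- vapply(x$sets, length, integer(1))
  cat(sprintf("concordance: %d single, %d double, %d triple-concordant loci\n",
              n["single"], n["double"], n["triple"]))
  cat(sprintf("  flagged loci collapse to %d ddRADtag regions\n",
              nrow(x$regions)))
  invisible(x)
}

#' Phenotype-randomization null distribution of discovery counts
#'
#' Permutes log growth across individuals (genotypes fixed), reruns the
#' per-SNP association scan with FDR control, and records the number of
#' loci passing `q < alpha` in each permutation. The resulting count
#' distribution quantifies how many discoveries pure chance produces at
#' this sample size; the observed (unpermuted) count is compared
#' against it.
#'
#' @param geno a [dosage_matrix].
#' @param pheno a [phenotype_table].
#' @param n_iter number of permutations (>= 100; conventionally 1000).
#' @param seed optional RNG seed.
#' @param fdr_method FDR procedure; the same method is used for the
#'   observed scan and every permutation (mixing methods is refused by
#'   construction).
#' @param alpha FDR discovery threshold.
#' @return A list of class `null_count_distribution`: `counts` (length
#'   `n_iter`), `observed` (discovery count on the unpermuted
#'   phenotype), and `fractions` with `le1` (permutations with at most
#'   one discovery), `eq0` (none), `ge_observed` (at least the observed
#'   count), plus `n_iter`, `alpha`, `fdr_method`, `seed`.
#' @export
randomization_null <- function(geno, pheno, n_iter = 1000, seed = NULL,
                               fdr_method = c("storey", "bh"),
                               alpha = 0.05) {
  stopifnot(inherits(geno, "dosage_matrix"),
            inherits(pheno, "phenotype_table"))
  fdr_method <- match.arg(fdr_method)
  if (n_iter < 100) stop("n_iter must be at least 100")
  y <- pheno$log_growth
  if (stats::sd(y) == 0) stop("constant phenotype; permutation null undefined")
  if (!is.null(seed)) set.seed(seed)
  V <- complete_matrix(geno)
  n <- nrow(V)
  # canonical individual order: the drawn permutations, and hence the
  # count distribution, are invariant to the input row order
  o <- order(geno$individual_ids)
  V <- V[o, , drop = FALSE]
  y <- y[o]
  df <- n - 2

  count_disc <- function(p) sum(fdr_qvalues(p, method = fdr_method) < alpha)
  t_obs <- ols_scan_t_multi(V, matrix(y, ncol = 1))
  observed <- count_disc(2 * stats::pt(abs(t_obs[, 1]), df, lower.tail = FALSE))

  counts <- integer(n_iter)
  block <- 100L
  done <- 0L
  while (done < n_iter) {
    m <- min(block, n_iter - done)
    Y <- vapply(seq_len(m), function(i) y[sample.int(n)], numeric(n))
    Tm <- ols_scan_t_multi(V, Y)
    P <- 2 * stats::pt(abs(Tm), df, lower.tail = FALSE)
    counts[done + seq_len(m)] <- apply(P, 2, count_disc)
    done <- done + m
  }
  structure(list(
    counts = counts,
    observed = observed,
    fractions = list(le1 = mean(counts <= 1),
                     eq0 = mean(counts == 0),
                     ge_observed = mean(counts >= observed)),
    n_iter = n_iter, alpha = alpha, fdr_method = fdr_method, seed = seed
  ), class = "null_count_distribution")
}

#' @export
print.null_count_distribution <- function(x, ...) {
  cat(sprintf(paste0(
    "phenotype-randomization null (%d iterations, %s FDR < %.2f):\n",
    "  %.1f%% of randomizations had <= 1 discovery (%.1f%% had none)\n",
    "  observed count %d; %.1f%% of randomizations reached it\n"),
    x$n_iter, x$fdr_method, x$alpha, 100 * x$fractions$le1,
    100 * x$fractions$eq0, x$observed, 100 * x$fractions$ge_observed))
  invisible(x)
}

#' Per-locus coefficient of determination with growth
#'
#' Squared Pearson correlation between dosage and log growth at each
#' requested locus — identical to the R-squared of a per-locus simple
#' regression (the per-locus effect-size summary reported for candidate
#' loci). Computed on the mean-imputed matrix, the same input the
#' matrix-based methods and the polygenic score use.
#'
#' @param geno a [dosage_matrix].
#' @param pheno a [phenotype_table].
#' @param loci locus IDs (default: all loci).
#' @return A data.frame with `locus_id` and `r2`.
#' @export
per_locus_r2 <- function(geno, pheno, loci = NULL) {
  stopifnot(inherits(geno, "dosage_matrix"),
            inherits(pheno, "phenotype_table"))
  if (is.null(loci)) loci <- geno$locus_ids
  j <- match(loci, geno$locus_ids)
  if (anyNA(j)) stop("unknown locus ID: ",
                     paste(loci[is.na(j)], collapse = ", "))
  y <- pheno$log_growth
  V <- complete_matrix(geno)
  r2 <- vapply(j, function(l) stats::cor(V[, l], y)^2, numeric(1))
  data.frame(locus_id = loci, r2 = r2, stringsAsFactors = FALSE)
}

#' Site-by-genotype interaction ANCOVA
#'
#' For each requested locus, fits `log_growth ~ site + dosage +
#' site:dosage` and reports the interaction F test (sequential ANOVA,
#' interaction last), alongside the site and dosage main effects. A
#' significant interaction would indicate that the genotype-growth
#' relationship differs among sites. Loci at which some site carries a
#' single genotype class leave the interaction inestimable and are
#' flagged rather than dropped.
#'
#' @param geno a [dosage_matrix].
#' @param pheno a [phenotype_table].
#' @param loci locus IDs to test.
#' @return A data.frame with per-locus `F_site`, `p_site`, `F_dosage`,
#'   `p_dosage`, `F_interaction`, `p_interaction`, `df_interaction` and
#'   logical `estimable`.
#' @export
site_interaction_ancova <- function(geno, pheno, loci) {
  stopifnot(inherits(geno, "dosage_matrix"),
            inherits(pheno, "phenotype_table"))
  site <- factor(pheno$site)
  if (nlevels(site) < 2) stop("only one site; interaction undefined")
  j <- match(loci, geno$locus_ids)
  if (anyNA(j)) stop("unknown locus ID: ",
                     paste(loci[is.na(j)], collapse = ", "))
  y <- pheno$log_growth
  out <- lapply(seq_along(j), function(k) {
    g <- geno$values[, j[k]]
    keep <- !is.na(g)
    per_site_classes <- tapply(g[keep], droplevels(site[keep]),
                               function(v) length(unique(v)))
    estimable <- all(per_site_classes >= 2) &&
      nlevels(droplevels(site[keep])) >= 2
    row <- data.frame(locus_id = loci[k], F_site = NA_real_,
                      p_site = NA_real_, F_dosage = NA_real_,
                      p_dosage = NA_real_, F_interaction = NA_real_,
                      p_interaction = NA_real_, df_interaction = NA_integer_,
                      estimable = estimable, stringsAsFactors = FALSE)
    if (!estimable) return(row)
    fit <- stats::lm(y[keep] ~ site[keep] + g[keep] + site[keep]:g[keep])
    a <- stats::anova(fit)
    if (nrow(a) < 4 || any(is.na(a$`F value`[1:3]))) {
      row$estimable <- FALSE
      return(row)
    }
    row$F_site <- a$`F value`[1]; row$p_site <- a$`Pr(>F)`[1]
    row$F_dosage <- a$`F value`[2]; row$p_dosage <- a$`Pr(>F)`[2]
    row$F_interaction <- a$`F value`[3]; row$p_interaction <- a$`Pr(>F)`[3]
    row$df_interaction <- a$Df[3]
    row
  })
  do.call(rbind, out)
}

#' Polygenic score model from selected loci
#'
#' Builds the polygenic prediction used to assess the joint
#' contribution of multi-method candidate loci: a ridge LFMM refit
#' restricted to the selected loci supplies per-locus coefficients, each
#' individual's score is the coefficient-weighted sum of its dosages
#' (z-scaled), and predictive strength is the coefficient of
#' determination from an OLS fit of observed scaled growth on the
#' score, with its F-test p-value. A plain ridge regression of growth
#' on the selected dosages is available as an alternative coefficient
#' source.
#'
#' @param geno a [dosage_matrix].
#' @param pheno a [phenotype_table].
#' @param selected_loci non-empty character vector of locus IDs.
#' @param K latent factor count for the restricted LFMM refit; capped
#'   at `length(selected_loci) - 1` (a single selected locus forces
#'   K = 0, making the score proportional to that locus's dosage).
#'   The default is 0: with only a handful of selected loci the latent
#'   factor is not identifiable separately from the signal itself and,
#'   under a small ridge penalty, absorbs the phenotype-aligned
#'   component, collapsing the score (see the methods vignette).
#' @param lambda ridge penalty.
#' @param method `"lfmm"` (default) or `"ridge"` (growth regressed on
#'   dosages with an L2 penalty).
#' @return A list of class `polygenic_model`: `locus_ids`,
#'   `coefficients`, `score` (z-scaled per individual), `r2`, `p`,
#'   `K`, `lambda`, `method`.
#' @export
polygenic_fit <- function(geno, pheno, selected_loci, K = 0,
                          lambda = 1e-5, method = c("lfmm", "ridge")) {
  stopifnot(inherits(geno, "dosage_matrix"),
            inherits(pheno, "phenotype_table"))
  method <- match.arg(method)
  if (length(selected_loci) < 1) stop("selected locus set is empty")
  j <- match(selected_loci, geno$locus_ids)
  if (anyNA(j)) stop("unknown locus ID: ",
                     paste(selected_loci[is.na(j)], collapse = ", "))
  V <- complete_matrix(geno)[, j, drop = FALSE]
  Vc <- sweep(V, 2, colMeans(V))
  x <- pheno$scaled_growth
  if (method == "lfmm") {
    K_eff <- min(K, length(j) - 1L, nrow(V) - 1L)
    fit <- lfmm_ridge(Vc, x, K = max(K_eff, 0L), lambda = lambda)
    coefs <- fit$B
  } else {
    K_eff <- 0L
    coefs <- solve(crossprod(Vc) + lambda * diag(length(j)),
                   crossprod(Vc, x))[, 1]
  }
  raw_score <- as.vector(Vc %*% coefs)
  if (stats::sd(raw_score) == 0)
    stop("degenerate polygenic score (all coefficients zero?)")
  score <- as.vector(scale(raw_score))
  lmfit <- stats::lm(x ~ score)
  s <- summary(lmfit)
  structure(list(
    locus_ids = selected_loci,
    coefficients = stats::setNames(coefs, selected_loci),
    score = stats::setNames(score, geno$individual_ids),
    r2 = s$r.squared,
    p = stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                  lower.tail = FALSE),
    K = K_eff, lambda = lambda, method = method
  ), class = "polygenic_model")
}

#' @export
print.polygenic_model <- function(x, ...) {
  cat(sprintf(paste0(
    "polygenic model (%s, %d loci, K = %d): observed~predicted ",
    "R^2 = %.4f (p = %.3g)\n"),
    x$method, length(x$locus_ids), x$K, x$r2, x$p))
  invisible(x)
}
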