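#' Configuration for a synthetic ddRAD cohort
#'
#' Defines the study conditions the generator emulates: a small wild
#' cohort (~52 diploid individuals from 3 sites x 3 plots) genotyped at
#' ~5,000 biallelic ddRAD SNPs, with weak latent population structure, a
#' handful of mutually correlated causal loci whose marginal effects on
#' log growth overlap (each explaining ~25% of variation, jointly ~50%),
#' 5% missing calls, and read depths around 27.5x. Growth rates span
#' roughly 0.12-0.46 cm/day over a 79-day monitoring period.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_loci number of biallelic SNPs.
#' @param n_sites number of field sites.
#' @param n_plots_per_site plots nested within each site.
#' @param maf_range range the ancestral minor allele frequencies are
#'   drawn from (uniform).
#' @param k_latent number of latent structure factors.
#' @param latent_geno_weight strength of the latent perturbation on
#'   genotype frequencies (logistic scale); the default is small,
#'   matching the weak structure typical of a single connected
#'   population.
#' @param n_causal number of planted causal loci (0 for a global null).
#' @param per_locus_r2 target marginal squared correlation between each
#'   causal locus and log growth.
#' @param joint_r2 target joint (in-sample) variance in log growth
#'   explained by the causal loci together. Because causal loci are made
#'   mutually correlated, `n_causal * per_locus_r2` may exceed
#'   `joint_r2`.
#' @param latent_pheno_r2 variance in log growth explained by the first
#'   latent factor (default 0; set > 0 to create a confounded scenario
#'   in which structure drives both genotypes and phenotype).
#' @param missing_rate fraction of genotype calls masked at random
#'   (missing completely at random).
#' @param mean_depth mean simulated read depth (negative binomial).
#' @param growth_range attainable growth rates in cm/day; emitted rates
#'   are clipped to this interval.
#' @param days elapsed days between hole-punch measurements.
#' @param seed RNG seed (`NULL` = leave the RNG state alone).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 52, n_loci = 5000, n_sites = 3,
                       n_plots_per_site = 3, maf_range = c(0.05, 0.5),
                       k_latent = 1, latent_geno_weight = 0.3,
                       n_causal = 5, per_locus_r2 = 0.25, joint_r2 = 0.5,
                       latent_pheno_r2 = 0, missing_rate = 0.05,
                       mean_depth = 27.5, growth_range = c(0.12, 0.46),
                       days = 79, seed = NULL) {
  stopifnot(n_individuals >= 1, n_loci >= 1, n_sites >= 1,
            n_plots_per_site >= 1, k_latent >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_causal >= 0, per_locus_r2 >= 0, per_locus_r2 < 1,
            joint_r2 >= 0, joint_r2 < 1,
            latent_pheno_r2 >= 0, latent_pheno_r2 < 1,
            missing_rate >= 0, missing_rate < 1,
            mean_depth > 0, length(growth_range) == 2,
            growth_range[1] > 0, growth_range[1] < growth_range[2],
            days > 0)
  if (maf_range[2] < 0.03)
    stop("maf_range lies entirely below the MAF filter floor of 0.03; ",
         "no locus could survive filtering")
  structure(as.list(environment()), class = "sim_config")
}

# Solve for v, the share of phenotypic variance carried by the shared
# liability, such that k causal loci each with marginal R2 = plr2 reach a
# joint in-sample R2 of jr2 at sample size n. Under the construction
# g_j = c*z + noise (c^2 = plr2/v, pairwise cor c^2), the population joint
# R2 is k*plr2 / (1 + (k-1)*plr2/v), and the expected in-sample R2 adds
# approximately (1 - R2)*k/(n-1).
solve_liability_share <- function(k, plr2, jr2, n) {
  if (k == 0 || plr2 == 0) return(0)
  f <- function(v) {
    pop <- k * plr2 / (1 + (k - 1) * plr2 / v)
    pop + (1 - pop) * k / (n - 1) - jr2
  }
  lo <- plr2 * (1 + 1e-9)
  if (lo >= 1 || f(1) * f(lo) > 0) {
    pop_max <- k * plr2 / (1 + (k - 1) * plr2)
    stop(sprintf(paste0(
      "per_locus_r2 = %.3g is incompatible with joint_r2 = %.3g at ",
      "n_causal = %d: achievable joint R2 lies in (%.3g, %.3g]"),
      plr2, jr2, k, plr2 + (1 - plr2) * k / (n - 1),
      pop_max + (1 - pop_max) * k / (n - 1)))
  }
  stats::uniroot(f, c(lo, 1), tol = 1e-10)$root
}

# Analytic correlation between a two-copy threshold-model dosage and the
# shared standard-normal liability z. Each allele copy is
# 1{rho*z + sqrt(1-rho^2)*eps < qnorm(p)}; copies share z.
copula_cor_gz <- function(rho, p) {
  t <- stats::qnorm(p)
  cov_gz <- -rho * stats::dnorm(t)
  f <- function(z) stats::pnorm((t - rho * z) / sqrt(1 - rho^2))^2 * stats::dnorm(z)
  p11 <- stats::integrate(f, -8, 8)$value
  var_g <- (2 * p * (1 - p) + 2 * (p11 - p^2)) / 4
  cov_gz / sqrt(var_g)
}

# rho achieving |cor(g, z)| = target at minor allele frequency p
solve_copula_rho <- function(p, target) {
  g <- function(rho) abs(copula_cor_gz(rho, p)) - target
  if (g(0.999) < 0)
    stop(sprintf(paste0(
      "requested per-locus correlation %.3f with the liability is not ",
      "attainable at MAF %.2f (maximum ~%.3f); lower per_locus_r2 or ",
      "raise joint_r2"), target, p, abs(copula_cor_gz(0.999, p))))
  stats::uniroot(g, c(1e-6, 0.999), tol = 1e-9)$root
}

# dosages for one causal locus given the liability vector z
draw_causal_dosage <- function(z, p, rho) {
  n <- length(z)
  t <- stats::qnorm(p)
  x1 <- as.numeric(rho * z + sqrt(1 - rho^2) * stats::rnorm(n) < t)
  x2 <- as.numeric(rho * z + sqrt(1 - rho^2) * stats::rnorm(n) < t)
  (x1 + x2) / 2
}

#' Generate synthetic genotypes with planted structure and causal loci
#'
#' Draws diploid minor-allele dosages per locus from binomial(2, p_il)/2,
#' where p_il combines an ancestral frequency with a low-rank logistic
#' perturbation `qlogis(p_l) + w * u_i . f_l` (u, f standard normal)
#' encoding weak latent population structure. Causal loci are drawn from
#' a Gaussian-copula threshold model conditional on a shared standard
#' normal liability, so that their marginal correlations with the
#' phenotype overlap (see [generate_phenotype()]). Calls are masked
#' missing completely at random, and every emitted locus is guaranteed
#' to pass MAF >= 0.03 and <= 10% missingness after masking (failing
#' loci are redrawn). Locus IDs follow the ddRAD `"tag:pos"` convention
#' with at least one pair of SNPs sharing a tag.
#'
#' @param cfg a [sim_config].
#' @return A list with elements `geno` (a [dosage_matrix]) and `truth`
#'   (class `sim_truth`): causal locus IDs and indices, the liability
#'   vector, per-causal-locus copula parameters, latent scores `u`
#'   (individuals x k) and loadings `f`, plus slots filled by
#'   [generate_phenotype()].
#' @export
generate_genotypes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_individuals
  L <- cfg$n_loci
  if (cfg$n_causal > L) stop("n_causal exceeds n_loci")

  u <- matrix(stats::rnorm(n * cfg$k_latent), n, cfg$k_latent)
  f <- matrix(stats::rnorm(L * cfg$k_latent), L, cfg$k_latent)
  p0 <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])

  draw_neutral <- function(idx) {
    eta <- matrix(stats::qlogis(p0[idx]), n, length(idx), byrow = TRUE) +
      cfg$latent_geno_weight * (u %*% t(f[idx, , drop = FALSE]))
    matrix(stats::rbinom(n * length(idx), 2, as.vector(stats::plogis(eta))),
           n, length(idx)) / 2
  }
  G <- draw_neutral(seq_len(L))

  # planted causal architecture: shared liability + calibrated copula
  z <- stats::rnorm(n)
  causal_idx <- integer(0)
  causal_p <- numeric(0)
  causal_rho <- numeric(0)
  effect_sign <- numeric(0)
  target_c <- 0
  v_share <- 0
  if (cfg$n_causal > 0 && cfg$per_locus_r2 > 0) {
    v_share <- solve_liability_share(cfg$n_causal, cfg$per_locus_r2,
                                     cfg$joint_r2, n)
    target_c <- sqrt(cfg$per_locus_r2 / v_share)
    causal_idx <- sample.int(L, cfg$n_causal)
    # causal MAFs drawn high enough that the copula can reach target_c
    lo <- max(0.3, cfg$maf_range[1])
    if (lo >= cfg$maf_range[2]) lo <- cfg$maf_range[1]
    causal_p <- stats::runif(cfg$n_causal, lo, cfg$maf_range[2])
    causal_rho <- vapply(causal_p, solve_copula_rho, numeric(1),
                         target = target_c)
    effect_sign <- sample(c(-1, 1), cfg$n_causal, replace = TRUE)
    for (j in seq_along(causal_idx)) {
      # threshold model gives cor(g, z) < 0; flip z to set the sign
      G[, causal_idx[j]] <- draw_causal_dosage(-effect_sign[j] * z,
                                               causal_p[j], causal_rho[j])
    }
    p0[causal_idx] <- causal_p
  } else if (cfg$n_causal > 0) {
    causal_idx <- sample.int(L, cfg$n_causal)
    effect_sign <- rep(0, cfg$n_causal)
    causal_p <- p0[causal_idx]
    causal_rho <- rep(0, cfg$n_causal)
  }

  # MCAR missingness
  if (cfg$missing_rate > 0) {
    G[matrix(stats::runif(n * L) < cfg$missing_rate, n, L)] <- NA
  }

  # enforce the emitted-locus contract: MAF >= 0.03, missingness <= 0.10
  for (round in seq_len(200)) {
    maf <- dosage_maf(G)
    miss <- colMeans(is.na(G))
    bad <- which(is.na(maf) | maf < 0.03 | miss > 0.10)
    if (length(bad) == 0L) break
    bad_causal <- intersect(bad, causal_idx)
    bad_neutral <- setdiff(bad, causal_idx)
    if (length(bad_neutral)) {
      p0[bad_neutral] <- stats::runif(length(bad_neutral),
                                      max(0.10, cfg$maf_range[1]),
                                      cfg$maf_range[2])
      f[bad_neutral, ] <- stats::rnorm(length(bad_neutral) * cfg$k_latent)
      G[, bad_neutral] <- draw_neutral(bad_neutral)
    }
    for (j in match(bad_causal, causal_idx)) {
      G[, causal_idx[j]] <- draw_causal_dosage(-effect_sign[j] * z,
                                               causal_p[j], causal_rho[j])
    }
    if (cfg$missing_rate > 0 && length(bad)) {
      G[, bad][matrix(stats::runif(n * length(bad)) < cfg$missing_rate,
                      n, length(bad))] <- NA
    }
    if (round == 200L)
      stop("could not generate loci passing MAF/missingness constraints; ",
           "maf_range or missing_rate is infeasible")
  }

  # orient so the coded allele is the realized minor allele
  flip <- colMeans(G, na.rm = TRUE) > 0.5
  G[, flip] <- 1 - G[, flip, drop = FALSE]

  locus_ids <- make_tag_ids(L)
  individual_ids <- sprintf("ind_%02d", seq_len(n))
  geno <- dosage_matrix(G, locus_ids = locus_ids,
                        individual_ids = individual_ids)
  truth <- structure(list(
    causal_locus_ids = locus_ids[causal_idx],
    causal_idx = causal_idx,
    causal_flipped = unname(flip[causal_idx]),
    effect_sign = effect_sign,
    liability = z,
    latent_scores = u,
    latent_loadings = f,
    liability_share = v_share,
    target_cor = target_c,
    causal_maf = causal_p,
    causal_rho = causal_rho,
    causal_effects = NULL,
    realized_per_locus_r2 = NULL,
    realized_joint_r2 = NULL
  ), class = "sim_truth")
  list(geno = geno, truth = truth)
}

# ddRADtag-style locus IDs: most tags carry one SNP, some two or three;
# at least one tag is guaranteed to carry two SNPs
make_tag_ids <- function(L) {
  sizes <- integer(0)
  while (sum(sizes) < L) {
    sizes <- c(sizes, sample(1:3, 64, replace = TRUE,
                             prob = c(0.80, 0.15, 0.05)))
  }
  sizes <- sizes[cumsum(sizes) - sizes < L]
  extra <- sum(sizes) - L
  if (extra > 0) sizes[length(sizes)] <- sizes[length(sizes)] - extra
  if (L >= 2 && all(sizes == 1L)) sizes <- c(2L, sizes[-(1:2)])
  tags <- sample.int(999999, length(sizes))
  unlist(mapply(function(tag, k) {
    paste0(tag, ":", sort(sample.int(140, k)))
  }, tags, sizes, SIMPLIFY = FALSE))[seq_len(L)]
}

#' Generate the growth phenotype for a synthetic cohort
#'
#' Builds log growth from the cohort's shared liability: the liability
#' explains a calibrated share of phenotypic variance such that each
#' causal locus's marginal squared correlation with log growth is close
#' to `per_locus_r2` while the joint in-sample R-squared is close to
#' `joint_r2`. When `latent_pheno_r2 > 0` the first latent structure
#' factor also loads on the phenotype (a confounded scenario). Log
#' growth is mapped to the configured growth-rate interval (clipped at
#' the interval ends), and hole-punch distances are reconstructed as
#' `5 + rate * days`. Site and plot labels are assigned with zero site
#' effect.
#'
#' @param geno,truth output of [generate_genotypes()].
#' @param cfg the same [sim_config] used to generate the genotypes.
#' @return A list with `pheno` (a [phenotype_table]) and `truth` (the
#'   input truth with `causal_effects`, `realized_per_locus_r2` and
#'   `realized_joint_r2` filled in from the emitted data).
#' @export
generate_phenotype <- function(geno, truth, cfg) {
  stopifnot(inherits(geno, "dosage_matrix"), inherits(truth, "sim_truth"),
            inherits(cfg, "sim_config"))
  n <- nrow(geno$values)
  v <- truth$liability_share
  if (v + cfg$latent_pheno_r2 >= 1)
    stop("joint_r2 share plus latent_pheno_r2 must be < 1")
  y <- sqrt(v) * truth$liability +
    sqrt(1 - v - cfg$latent_pheno_r2) * stats::rnorm(n)
  if (cfg$latent_pheno_r2 > 0) {
    u1 <- truth$latent_scores[, 1]
    y <- y + sqrt(cfg$latent_pheno_r2) * (u1 - mean(u1)) / stats::sd(u1)
  }

  lr <- log10(cfg$growth_range)
  mu <- mean(lr)
  sigma <- diff(lr) / 6  # +-3 SD spans the interval; clipping is rare
  log_growth <- mu + sigma * as.vector(scale(y))
  rate <- pmin(pmax(10^log_growth, cfg$growth_range[1]), cfg$growth_range[2])
  distance_cm <- 5 + rate * cfg$days

  # balanced site/plot labels, zero site effect
  site_lab <- paste0("S", (seq_len(n) - 1L) %% cfg$n_sites + 1L)
  plot_lab <- paste0("P", ((seq_len(n) - 1L) %/% cfg$n_sites) %%
                       cfg$n_plots_per_site + 1L)

  pheno <- phenotype_table(data.frame(
    id = geno$individual_ids, site = site_lab, plot = plot_lab,
    distance_cm = distance_cm, days = cfg$days,
    stringsAsFactors = FALSE))

  lg <- pheno$log_growth
  if (length(truth$causal_idx)) {
    gc_ <- geno$values[, truth$causal_idx, drop = FALSE]
    truth$realized_per_locus_r2 <- vapply(seq_len(ncol(gc_)), function(j) {
      stats::cor(gc_[, j], lg, use = "complete.obs")^2
    }, numeric(1))
    gi <- gc_
    for (j in seq_len(ncol(gi))) {
      m <- is.na(gi[, j]); gi[m, j] <- mean(gi[, j], na.rm = TRUE)
    }
    fit <- stats::lm(lg ~ gi)
    truth$realized_joint_r2 <- summary(fit)$r.squared
    truth$causal_effects <- unname(stats::coef(fit)[-1])
  } else {
    truth$realized_per_locus_r2 <- numeric(0)
    truth$realized_joint_r2 <- 0
    truth$causal_effects <- numeric(0)
  }
  list(pheno = pheno, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper chaining [generate_genotypes()] and
#' [generate_phenotype()].
#'
#' @param cfg a [sim_config].
#' @return A list with `geno`, `pheno`, `truth` and the `cfg` used.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  g <- generate_genotypes(cfg)
  ph <- generate_phenotype(g$geno, g$truth, cfg)
  list(geno = g$geno, pheno = ph$pheno, truth = ph$truth, cfg = cfg)
}

#' Write a synthetic cohort to disk
#'
#' Emits a VCF 4.2 (CHROM = ddRADtag ID, POS = within-tag position, GT
#' and simulated DP per sample), a phenotype CSV with header
#' `id,site,plot,distance_cm,days`, and a truth JSON. Re-reading the VCF
#' through [read_vcf()] and [filter_sites()] with a pass-through
#' [filter_config] reproduces the dosage matrix exactly, missing entries
#' included.
#'
#' @param geno a [dosage_matrix].
#' @param pheno a [phenotype_table].
#' @param truth a `sim_truth` (optional; skipped when `NULL`).
#' @param dir output directory (created if needed).
#' @param mean_depth mean of the negative-binomial simulated DP values.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_cohort <- function(geno, pheno, truth = NULL, dir,
                         mean_depth = 27.5) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  vcf_path <- file.path(dir, "genotypes.vcf")
  pheno_path <- file.path(dir, "phenotype.csv")
  truth_path <- file.path(dir, "truth.json")

  dp <- matrix(stats::rnbinom(length(geno$values), mu = mean_depth, size = 8),
               nrow(geno$values), ncol(geno$values))
  write_vcf(geno, vcf_path, dp = dp)

  utils::write.csv(pheno[, c("id", "site", "plot", "distance_cm", "days")],
                   pheno_path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    tr <- truth
    tr$latent_scores <- as.vector(tr$latent_scores)
    tr$latent_loadings <- NULL
    jsonlite::write_json(unclass(tr), truth_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(list(vcf = vcf_path, phenotype = pheno_path,
                 truth = if (is.null(truth)) NULL else truth_path))
}

#' Write a dosage matrix as a VCF 4.2 file
#'
#' The coded (minor) allele is emitted as ALT, so that re-reading and
#' re-coding with the tie-toward-ALT convention reproduces the dosage
#' matrix exactly.
#'
#' @param geno a [dosage_matrix].
#' @param path output path (plain text `.vcf`).
#' @param dp optional individuals x loci integer matrix of per-genotype
#'   depths; omitted from the file when `NULL`.
#' @export
write_vcf <- function(geno, path, dp = NULL) {
  stopifnot(inherits(geno, "dosage_matrix"))
  v <- geno$values
  tag <- sub(":[^:]*$", "", geno$locus_ids)
  pos <- sub("^.*:", "", geno$locus_ids)
  gt_codes <- c(`0` = "0/0", `0.5` = "0/1", `1` = "1/1")
  fmt_cell <- function(d, depth) {
    g <- ifelse(is.na(d), "./.", gt_codes[as.character(d)])
    if (is.null(depth)) g else paste0(g, ":", ifelse(is.na(d), ".", depth))
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=kelpgrowth_simdata",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(dp)) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$individual_ids), collapse = "\t")
  )
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  body <- vapply(seq_len(ncol(v)), function(l) {
    cells <- fmt_cell(v[, l], if (is.null(dp)) NULL else dp[, l])
    paste(c(tag[l], pos[l], geno$locus_ids[l], "A", "C", ".", "PASS", ".",
            fmt, cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `genotypes.vcf` and `phenotype.csv`.
#' @param filter a [filter_config]; the default is a pass-through
#'   configuration that reproduces the stored matrix exactly (no depth
#'   masking, no site removal).
#' @return A list with `geno` (a [dosage_matrix]) and `pheno` (a
#'   [phenotype_table]).
#' @export
read_cohort <- function(dir, filter = filter_config(min_depth = 0,
                                                    max_depth_factor = Inf,
                                                    max_missing = 1,
                                                    min_maf = 0)) {
  rec <- read_vcf(file.path(dir, "genotypes.vcf"))
  geno <- filter_sites(rec, filter)
  pheno <- phenotype_table(utils::read.csv(file.path(dir, "phenotype.csv"),
                                           stringsAsFactors = FALSE))
  list(geno = geno, pheno = pheno)
}
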