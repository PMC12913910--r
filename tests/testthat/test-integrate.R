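# build minimal method-result objects over a shared locus universe with
# prescribed flag sets, to exercise the set algebra directly
fake_methods <- function(ids, gwas_set, lfmm_set, rda_set) {
  gw <- data.frame(locus_id = ids, n = 52, beta = 0, se = 1, t = 0, p = 0.5,
                   q = 0.5, sig_q05 = FALSE, sig_q10 = ids %in% gwas_set,
                   stringsAsFactors = FALSE)
  class(gw) <- c("gwas_result", "data.frame")
  lf <- data.frame(locus_id = ids, z = 0, p_raw = 0.5, p = 0.5, q = 0.5,
                   sig_q05 = ids %in% lfmm_set, stringsAsFactors = FALSE)
  class(lf) <- c("lfmm_result", "data.frame")
  rd <- structure(list(loadings = data.frame(
    locus_id = ids, loading = 0, zscore = 0,
    candidate = ids %in% rda_set, stringsAsFactors = FALSE),
    sd_cut = 2.5), class = "rda_result")
  list(gw = gw, lf = lf, rd = rd)
}

test_that("concordance classes follow set algebra and partition the universe", {
  ids <- c("1:1", "2:1", "3:1", "4:1")
  fm <- fake_methods(ids, gwas_set = c("1:1", "2:1", "3:1"),
                     lfmm_set = c("2:1", "3:1"), rda_set = "3:1")
  cc <- concordance(fm$gw, fm$lf, fm$rd)
  expect_equal(cc$sets$triple, "3:1")
  expect_equal(cc$sets$double, "2:1")
  expect_equal(cc$sets$single, "1:1")
  expect_equal(cc$loci$class[cc$loci$locus_id == "4:1"], "none")
  expect_setequal(unlist(lapply(split(cc$loci, cc$loci$class),
                                function(d) d$locus_id)), ids)

  # disjoint sets produce no double/triple concordance
  fm2 <- fake_methods(ids, "1:1", "2:1", "3:1")
  cc2 <- concordance(fm2$gw, fm2$lf, fm2$rd)
  expect_length(cc2$sets$double, 0)
  expect_length(cc2$sets$triple, 0)
  expect_error(concordance(fm$gw, fm$lf[1:3, ], fm$rd), "universe")
})

test_that("loci sharing a ddRADtag collapse into one region", {
  ids <- c("55183:7", "55183:146", "900:3")
  fm <- fake_methods(ids, gwas_set = ids, lfmm_set = ids,
                     rda_set = "55183:7")
  cc <- concordance(fm$gw, fm$lf, fm$rd)
  expect_equal(nrow(cc$regions), 2)
  r <- cc$regions[cc$regions$tag == "55183", ]
  expect_equal(r$n_loci, 2)
  expect_equal(r$best_class, "triple")
  expect_match(r$members, "55183:7")
  expect_match(r$members, "55183:146")
})

test_that("the randomization null is deterministic and internally consistent", {
  sim <- small_cohort(seed = 91, n_loci = 250)
  n1 <- randomization_null(sim$geno, sim$pheno, n_iter = 120, seed = 5)
  n2 <- randomization_null(sim$geno, sim$pheno, n_iter = 120, seed = 5)
  expect_identical(n1$counts, n2$counts)
  expect_lte(n1$fractions$eq0, n1$fractions$le1)
  expect_equal(n1$fractions$le1, mean(n1$counts <= 1))
  expect_gte(n1$fractions$ge_observed, 0)
  expect_error(randomization_null(sim$geno, sim$pheno, n_iter = 50),
               "at least 100")
  ph_const <- sim$pheno
  ph_const$log_growth <- 1
  expect_error(randomization_null(sim$geno, ph_const), "constant")
})

test_that("permuted-count summaries are exchangeable in individual labels", {
  sim <- small_cohort(seed = 93, n_loci = 200)
  o <- sample(seq_len(nrow(sim$pheno)))
  g2 <- subset_dosage(sim$geno, individuals = o)
  ph2 <- phenotype_table(as.data.frame(sim$pheno)[o, c("id", "site", "plot",
                                                       "distance_cm", "days")])
  n1 <- randomization_null(sim$geno, sim$pheno, n_iter = 150, seed = 6)
  n2 <- randomization_null(g2, ph2, n_iter = 150, seed = 6)
  expect_equal(sort(n1$counts), sort(n2$counts))
  expect_equal(n1$observed, n2$observed)
})

test_that("per-locus coefficients of determination match the correlation oracle", {
  g <- c(0, 0, 0.5, 0.5, 1, 1)
  y <- c(1.0, 1.2, 2.0, 2.2, 3.0, 3.2)
  ph <- pheno_from_rates(10^(y / 10 - 1))
  geno <- dosage_matrix(cbind(a = g, b = 1 - g),
                        locus_ids = c("5:1", "5:2"))
  r2 <- per_locus_r2(geno, ph)
  expect_equal(r2$r2[1], stats::cor(g, ph$log_growth)^2, tolerance = 1e-12)
  expect_equal(r2$r2[2], r2$r2[1], tolerance = 1e-12)  # complement collinear
  # perfectly collinear dosage
  ph_lin <- pheno_from_rates(10^(g / 10 - 1))
  expect_equal(per_locus_r2(geno, ph_lin)$r2[1], 1, tolerance = 1e-12)
  # independent vectors: expected R2 near 1/(n-1)
  set.seed(95)
  r2null <- replicate(400, {
    stats::cor(sample(c(0, 0.5, 1), 52, TRUE), stats::rnorm(52))^2
  })
  expect_lt(abs(mean(r2null) - 1 / 51), 0.006)
})

test_that("site-interaction ANCOVA is calibrated under parallel slopes and powered under reversal", {
  # null: same slope in all sites
  pint <- vapply(1:40, function(r) {
    set.seed(700 + r)
    g <- sample(c(0, 0.5, 1), 52, TRUE)
    site <- paste0("S", (0:51) %% 3 + 1)
    y <- 0.1 * g + stats::rnorm(52, 0, 0.1)
    ph <- pheno_from_rates(10^(y - 0.8), site = site)
    geno <- dosage_matrix(matrix(g, ncol = 1), locus_ids = "7:1")
    site_interaction_ancova(geno, ph, "7:1")$p_interaction
  }, numeric(1))
  expect_gt(stats::ks.test(pint, "punif")$p.value, 0.01)

  # strong slope reversal in one site
  hits <- vapply(1:25, function(r) {
    set.seed(800 + r)
    g <- sample(c(0, 0.5, 1), 52, TRUE)
    site <- paste0("S", (0:51) %% 3 + 1)
    slope <- ifelse(site == "S1", -0.4, 0.4)
    y <- slope * g + stats::rnorm(52, 0, 0.1)
    ph <- pheno_from_rates(10^(y / 2 - 0.8), site = site)
    geno <- dosage_matrix(matrix(g, ncol = 1), locus_ids = "7:1")
    site_interaction_ancova(geno, ph, "7:1")$p_interaction < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # a site with a single genotype class leaves the interaction inestimable
  g <- c(rep(0, 18), sample(c(0, 0.5, 1), 34, replace = TRUE))
  site <- c(rep("S1", 18), paste0("S", (0:33) %% 2 + 2))
  set.seed(97)
  ph <- pheno_from_rates(exp(stats::rnorm(52, log(0.25), 0.3)), site = site)
  geno <- dosage_matrix(matrix(g, ncol = 1), locus_ids = "7:1")
  res <- site_interaction_ancova(geno, ph, "7:1")
  expect_false(res$estimable)
  expect_true(is.na(res$p_interaction))
  ph1 <- pheno_from_rates(exp(stats::rnorm(10, log(0.25), 0.2)),
                          site = rep("S1", 10))
  expect_error(site_interaction_ancova(
    dosage_matrix(matrix(sample(c(0, 0.5, 1), 10, TRUE), ncol = 1),
                  locus_ids = "7:1"), ph1, "7:1"), "one site")
})

test_that("polygenic identities hold: single locus and perfect prediction", {
  sim <- small_cohort(seed = 99, n_loci = 150)
  one <- sim$truth$causal_locus_ids[1]
  pg1 <- polygenic_fit(sim$geno, sim$pheno, one)
  expect_equal(pg1$r2, per_locus_r2(sim$geno, sim$pheno, one)$r2,
               tolerance = 1e-10)
  # predictions equal to observations give R-squared 1
  ph_lin <- pheno_from_rates(10^(c(0, 0, 0.5, 0.5, 1, 1) / 10 - 1))
  geno_lin <- dosage_matrix(matrix(c(0, 0, 0.5, 0.5, 1, 1), ncol = 1),
                            locus_ids = "9:1")
  expect_equal(suppressWarnings(polygenic_fit(geno_lin, ph_lin, "9:1")$r2), 1,
               tolerance = 1e-10)
  expect_error(polygenic_fit(sim$geno, sim$pheno, character(0)), "empty")
})

test_that("the multi-locus refit never undercuts the best single locus in sample", {
  for (seed in c(101, 103)) {
    sim <- small_cohort(seed = seed, n_loci = 150)
    loci <- sim$truth$causal_locus_ids
    pg <- polygenic_fit(sim$geno, sim$pheno, loci, method = "ridge",
                        lambda = 1e-8)
    best_single <- max(per_locus_r2(sim$geno, sim$pheno, loci)$r2)
    expect_gte(pg$r2 + 1e-10, best_single)
  }
})

test_that("polygenic refit on truth loci recovers the planted joint signal", {
  r2 <- vapply(1:25, function(r) {
    sim <- simulate_cohort(sim_config(n_loci = 150, seed = 2000 + r))
    polygenic_fit(sim$geno, sim$pheno, sim$truth$causal_locus_ids)$r2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.5), 0.15)
})
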