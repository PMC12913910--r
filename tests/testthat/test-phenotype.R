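test_that("elongation rate reproduces the hole-punch arithmetic", {
  expect_equal(elongation_rate(5.0, 79), 0)
  expect_equal(elongation_rate(14.48, 79), 0.12, tolerance = 1e-12)
  expect_equal(elongation_rate(41.34, 79), 0.46, tolerance = 1e-12)
  # linear in distance, inversely proportional to days
  expect_equal(elongation_rate(5 + 2 * 9.48, 79),
               2 * elongation_rate(14.48, 79), tolerance = 1e-12)
  expect_equal(elongation_rate(14.48, 158),
               elongation_rate(14.48, 79) / 2, tolerance = 1e-12)
  expect_error(elongation_rate(4.9, 79), "regress")
  expect_error(elongation_rate(14, 0), "days")
})

test_that("growth transform z-scores exactly and names degenerate individuals", {
  set.seed(4)
  rates <- exp(stats::rnorm(52, log(0.25), 0.3))
  tr <- transform_growth(rates)
  expect_equal(mean(tr$scaled_growth), 0, tolerance = 1e-12)
  expect_equal(stats::sd(tr$scaled_growth), 1, tolerance = 1e-12)
  expect_equal(tr$log_growth, log10(rates))
  expect_equal(tr$normality$scale, c("raw", "log10"))
  expect_error(transform_growth(rep(0.2, 10)), "identical")
  expect_error(transform_growth(c(0.1, -0.2, 0.3), ids = c("a", "b", "c")),
               "\\bb\\b")
})

test_that("lognormal growth passes normality after log transform in >= 90% of cohorts", {
  pass <- vapply(1:100, function(r) {
    set.seed(500 + r)
    rates <- exp(stats::rnorm(52, log(0.25), 0.3))
    tr <- transform_growth(rates)
    tr$normality$p[tr$normality$scale == "log10"] > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("site ANOVA matches the two-group t-test identity and detects planted effects", {
  set.seed(11)
  y <- stats::rnorm(30)
  ph <- pheno_from_rates(10^(y / 10 - 0.6), site = rep(c("S1", "S2"), each = 15),
                         plot = rep(c("P1", "P2"), 15))
  a <- site_anova(ph)
  tt <- stats::t.test(ph$log_growth ~ ph$site, var.equal = TRUE)
  expect_equal(a$F[a$factor == "site"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(a$p[a$factor == "site"], tt$p.value, tolerance = 1e-10)

  # shuffled identical groups: no site signal
  set.seed(12)
  ph0 <- pheno_from_rates(sample(rep(c(0.15, 0.2, 0.25, 0.3), 13)))
  a0 <- site_anova(ph0)
  expect_gt(a0$p[1], 0.05)

  # planted 1-SD site effect at n = 52: significant with high power
  hits <- vapply(1:20, function(r) {
    set.seed(600 + r)
    site <- paste0("S", (0:51) %% 3 + 1)
    mu <- c(S1 = -1, S2 = 0, S3 = 1)[site]
    ph1 <- pheno_from_rates(10^(-0.6 + 0.05 * (mu + stats::rnorm(52))),
                            site = site)
    site_anova(ph1)$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(site_anova(pheno_from_rates(c(0.1, 0.2, 0.3), site = rep("S1", 3))),
               "single level")
})

test_that("relatedness matrix has VanRaden structure", {
  set.seed(3)
  v <- matrix(sample(c(0, 0.5, 1), 20 * 400, replace = TRUE), 20, 400)
  v[2, ] <- v[1, ]  # identical pair
  A <- relatedness_matrix(dosage_matrix(v))
  expect_equal(unclass(A), t(unclass(A)))
  expect_equal(A[1, 2], A[1, 1], tolerance = 1e-12)
  expect_equal(A[1, 2], A[2, 2], tolerance = 1e-12)
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # independent genotypes: off-diagonal mean near zero at L = 5000
  sim <- simulate_cohort(sim_config(latent_geno_weight = 0, n_causal = 0,
                                    seed = 14))
  A2 <- relatedness_matrix(sim$geno)
  expect_lt(abs(mean(A2[lower.tri(A2)])), 0.02)
  expect_error(relatedness_matrix(dosage_matrix(matrix(0, 4, 3))),
               "monomorphic")
})

test_that("Mantel test is exact on proportional distances and matches vegan", {
  n <- 20
  set.seed(6)
  rates <- exp(stats::rnorm(n, log(0.25), 0.3))
  ph <- pheno_from_rates(rates)
  Dy <- abs(outer(ph$log_growth, ph$log_growth, "-"))
  A <- max(Dy) - Dy            # so that max(A) - A is exactly Dy
  diag(A) <- max(Dy)
  dimnames(A) <- list(ph$id, ph$id)
  class(A) <- c("relatedness_matrix", "matrix")
  m <- mantel_growth_vs_relatedness(A, ph, n_perm = 199, seed = 2)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_equal(m$p, 1 / 200)

  skip_if_not_installed("vegan")
  sim <- small_cohort(seed = 15, n_loci = 200)
  A2 <- relatedness_matrix(sim$geno)
  m2 <- mantel_growth_vs_relatedness(A2, sim$pheno, n_perm = 99, seed = 3)
  Dg <- max(A2) - unclass(A2)
  Dy2 <- abs(outer(sim$pheno$log_growth, sim$pheno$log_growth, "-"))
  vg <- vegan::mantel(stats::as.dist(Dg), stats::as.dist(Dy2),
                      permutations = 99)
  expect_equal(m2$r, unname(vg$statistic), tolerance = 1e-10)
  expect_true(abs(m2$r) <= 1)
  expect_error(mantel_growth_vs_relatedness(A2, sim$pheno, n_perm = 50),
               "at least 99")
})

test_that("Mantel p-values are uniform under a simulated null", {
  mp <- vapply(1:150, function(r) {
    set.seed(300 + r)
    G <- matrix(stats::rbinom(20 * 300, 2, 0.3) / 2, 20, 300)
    geno <- dosage_matrix(G)
    A <- relatedness_matrix(geno)
    ph <- pheno_from_rates(exp(stats::rnorm(20, log(0.25), 0.3)))
    mantel_growth_vs_relatedness(A, ph, n_perm = 199, seed = 400 + r)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(mp, "punif"))$p.value, 0.01)
})

test_that("phenotype statistics are invariant to row order", {
  sim <- small_cohort(seed = 25, n_loci = 150)
  o <- sample(seq_len(nrow(sim$pheno)))
  ph2 <- phenotype_table(as.data.frame(sim$pheno)[o, c("id", "site", "plot",
                                                       "distance_cm", "days")])
  a1 <- site_anova(sim$pheno)
  a2 <- site_anova(ph2)
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  g2 <- subset_dosage(sim$geno, individuals = ph2$id)
  m1 <- mantel_growth_vs_relatedness(relatedness_matrix(sim$geno), sim$pheno,
                                     n_perm = 99, seed = 5)
  m2 <- mantel_growth_vs_relatedness(relatedness_matrix(g2), ph2,
                                     n_perm = 99, seed = 5)
  expect_equal(m1$r, m2$r, tolerance = 1e-10)
})
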