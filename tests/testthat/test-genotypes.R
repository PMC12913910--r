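test_that("filter cascade removes exactly the planted violations, in order", {
  fx <- write_violation_vcf(withr::local_tempfile(fileext = ".vcf"))
  rec <- read_vcf(fx$path)
  expect_length(rec$chrom, fx$n_input)

  geno <- filter_sites(rec, filter_config())
  log <- geno$filter_log
  expect_equal(log$input, fx$n_input)
  expect_equal(unname(log$removed["indel"]), fx$n_indel)
  expect_equal(unname(log$removed["multiallelic"]), fx$n_multi)
  expect_equal(unname(log$removed["missingness"]), fx$n_missing)
  expect_equal(unname(log$removed["maf"]), fx$n_maf)
  expect_equal(log$genotypes_depth_masked, fx$n_depth_masked)
  expect_equal(log$output, fx$n_kept)
  expect_equal(log$input - sum(log$removed), log$output)

  # depth-masked genotypes became missing on the retained sites
  expect_true(is.na(geno$values["s01", "104:30"]))
  expect_true(is.na(geno$values["s12", "105:41"]))
})

test_that("filter cascade is idempotent on its own output", {
  fx <- write_violation_vcf(withr::local_tempfile(fileext = ".vcf"))
  geno1 <- filter_sites(read_vcf(fx$path), filter_config())
  dp <- matrix(20L, nrow(geno1$values), ncol(geno1$values))
  dp[is.na(geno1$values)] <- NA
  rec2 <- records_from_dosage(geno1$values,
                              chrom = sub(":.*", "", geno1$locus_ids),
                              pos = sub(".*:", "", geno1$locus_ids),
                              dp = dp)
  geno2 <- filter_sites(rec2, filter_config())
  expect_equal(sum(geno2$filter_log$removed), 0)
  expect_equal(geno2$filter_log$genotypes_depth_masked, 0)
  expect_equal(unname(geno2$values), unname(geno1$values))
})

test_that("MAF and missingness thresholds follow the stated arithmetic at n = 52", {
  n <- 52
  # minor allele count 3 of 104: MAF 0.0288 < 0.03 -> removed
  g_maf <- c(0.5, 0.5, 0.5, rep(0, n - 3))
  # 6 of 52 missing (11.5%) -> removed; 5 of 52 (9.6%) -> retained
  g_m6 <- c(rep(NA, 6), rep(c(0, 0.5), (n - 6) / 2))
  g_m5 <- c(rep(NA, 5), rep(c(0, 0.5), 23), 0)
  g_ok <- rep(c(0, 0.5, 1, 0.5), n / 4)
  rec <- records_from_dosage(cbind(g_maf, g_m6, g_m5, g_ok))
  geno <- filter_sites(rec, filter_config())
  expect_equal(unname(geno$filter_log$removed["maf"]), 1)
  expect_equal(unname(geno$filter_log$removed["missingness"]), 1)
  expect_equal(geno$filter_log$output, 2)
})

test_that("minor-allele orientation counts the rarer allele, tie toward ALT", {
  n <- 10
  alt40 <- c(rep(1, 4), rep(0, 6))          # ALT freq 0.4 -> ALT minor
  alt60 <- c(rep(1, 6), rep(0, 4))          # ALT freq 0.6 -> REF minor
  tie <- c(rep(1, 5), rep(0, 5))            # exact tie -> ALT, logged
  rec <- records_from_dosage(cbind(alt40, alt60, tie))
  geno <- filter_sites(rec, filter_config())
  expect_equal(geno$coded_allele, c("ALT", "REF", "ALT"))
  expect_equal(unname(geno$values[, 1]), alt40)
  expect_equal(unname(geno$values[, 2]), 1 - alt60)  # complement when REF minor
  expect_equal(unname(geno$values[, 3]), tie)
  expect_equal(geno$filter_log$n_ties_alt, 1L)
  # dosage of one allele plus dosage of the other is 1 everywhere
  expect_true(all(geno$values + (1 - geno$values) == 1))
  expect_true(all(geno$maf >= 0.03 & geno$maf <= 0.5))
})

test_that("replicate error rate counts mismatches among comparable loci", {
  v <- matrix(0, 4, 300)
  v[2, ] <- v[1, ]                       # s2 identical to s1
  v[3, ] <- v[1, ]; v[3, 1:3] <- 0.5     # 3 mismatches vs s1
  v[4, ] <- NA                            # nothing comparable
  geno <- dosage_matrix(v, individual_ids = c("a", "b", "c", "d"),
                        locus_ids = paste0("t", 1:300, ":1"))
  res <- replicate_error_rate(geno, list(c("a", "b"), c("a", "c")))
  expect_equal(res$error_rate, c(0, 0.01))
  expect_equal(res$n_compared, c(300, 300))
  expect_error(replicate_error_rate(geno, list(c("a", "d"))),
               "disjoint missingness")
  expect_error(replicate_error_rate(geno, list(c("a", "zzz"))), "unknown")
})

test_that("mean imputation fills locus means and preserves column means", {
  sim <- small_cohort(seed = 31, n_loci = 150)
  imp <- impute_mean(sim$geno)
  expect_false(anyNA(imp$values))
  expect_equal(colMeans(imp$values),
               colMeans(sim$geno$values, na.rm = TRUE), tolerance = 1e-12)
  obs <- !is.na(sim$geno$values)
  expect_equal(imp$values[obs], sim$geno$values[obs])
  # complete input is returned unchanged
  full <- dosage_matrix(matrix(c(0, 1, 0.5, 1), 2, 2))
  expect_equal(impute_mean(full)$values, full$values)
  # half zeros, half ones -> imputed 0.5
  v <- matrix(c(0, 1, 0, 1, NA), 5, 1)
  expect_equal(impute_mean(dosage_matrix(v))$values[5, 1], 0.5)
})

test_that("malformed or empty VCF input errors informatively", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines("not a vcf at all", p)
  expect_error(read_vcf(p), "malformed|VCF")
  expect_error(read_vcf("/nonexistent/file.vcf"), "not found")
})
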