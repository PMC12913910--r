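# Shared fixtures, all built in code.

# small default-architecture cohort (fewer loci for speed)
small_cohort <- function(seed = 1, n_loci = 300, ...) {
  simulate_cohort(sim_config(n_loci = n_loci, seed = seed, ...))
}

# construct a vcf_records object directly (bypassing file I/O) from a
# dosage-style matrix; ALT is the coded allele
records_from_dosage <- function(dos, chrom = NULL, pos = NULL, dp = NULL,
                                ref = NULL, alt = NULL) {
  n <- nrow(dos); L <- ncol(dos)
  if (is.null(chrom)) chrom <- paste0("t", seq_len(L))
  if (is.null(pos)) pos <- rep(1L, L)
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("C", L)
  structure(list(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    alt_count = t(dos * 2),
    dp = if (is.null(dp)) NULL else t(dp),
    individual_ids = sprintf("ind_%02d", seq_len(n))
  ), class = "vcf_records")
}

# phenotype table from a raw growth-rate vector
pheno_from_rates <- function(rates, site = NULL, plot = NULL, days = 79) {
  n <- length(rates)
  if (is.null(site)) site <- paste0("S", (seq_len(n) - 1L) %% 3 + 1L)
  if (is.null(plot)) plot <- paste0("P", ((seq_len(n) - 1L) %/% 3) %% 3 + 1L)
  phenotype_table(data.frame(
    id = sprintf("ind_%02d", seq_len(n)), site = site, plot = plot,
    distance_cm = 5 + rates * days, days = days,
    stringsAsFactors = FALSE))
}

# VCF text fixture with one planted violation of each filter rule.
# 12 individuals; DP values chosen so the depth rule is exactly
# predictable and the cascade is idempotent on its own output.
write_violation_vcf <- function(path) {
  n <- 12
  samples <- sprintf("s%02d", seq_len(n))
  # genotypes for a clean biallelic site: 4 het, 2 hom-alt, 6 hom-ref
  clean_gt <- c(rep("0/1", 4), rep("1/1", 2), rep("0/0", 6))
  dp20 <- rep(20L, n)
  row <- function(chrom, pos, ref, alt, gt, dp) {
    cells <- paste0(gt, ":", dp)
    paste(c(chrom, pos, paste0(chrom, ":", pos), ref, alt, ".", "PASS", ".",
            "GT:DP", cells), collapse = "\t")
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    row("101", 10, "A", "C", clean_gt, dp20),                 # kept
    row("101", 55, "AT", "A", clean_gt, dp20),                # indel
    row("102", 7, "G", "GTT", clean_gt, dp20),                # indel
    row("103", 12, "A", "C,G", clean_gt, dp20),               # tri-allelic
    # depth violations: one DP below 5, one above 2 x mean depth; both
    # genotypes masked, site retained (1/12 missing = 8.3% <= 10%)
    row("104", 30, "T", "G", clean_gt, c(2L, rep(20L, n - 1))),
    row("105", 41, "C", "T", clean_gt, c(rep(20L, n - 1), 99L)),
    # missingness violation: 2 of 12 missing = 16.7% > 10%
    row("106", 5, "A", "G", c("./.", "./.", clean_gt[-(1:2)]), dp20),
    # MAF violation: monomorphic reference site
    row("107", 9, "G", "A", rep("0/0", n), dp20),
    row("108", 3, "T", "A", clean_gt, dp20)                   # kept
  )
  writeLines(lines, path)
  list(path = path, n_indel = 2L, n_multi = 1L, n_missing = 1L,
       n_maf = 1L, n_depth_masked = 2L, n_kept = 4L, n_input = 9L)
}

# scalar textbook OLS for one locus: the independent oracle
scalar_ols <- function(g, y) {
  keep <- !is.na(g)
  g <- g[keep]; y <- y[keep]
  n <- length(g)
  gm <- mean(g); ym <- mean(y)
  sxx <- sum((g - gm)^2)
  b <- sum((g - gm) * (y - ym)) / sxx
  a <- ym - b * gm
  rss <- sum((y - a - b * g)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tt <- b / se
  list(beta = b, se = se, t = tt,
       p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
}

# brute-force oracle: explicit projection matrix and full SVD
rda_oracle <- function(V, x) {
  xc <- x - mean(x)
  Gc <- sweep(V, 2, colMeans(V))
  Px <- tcrossprod(xc) / sum(xc^2)
  sv <- svd(Px %*% Gc)
  v1 <- sv$v[, 1]
  u1 <- sv$u[, 1]
  if (stats::cor(u1, x) < 0) { v1 <- -v1; u1 <- -u1 }
  list(loading = v1, d = sv$d, scores = u1 * sv$d[1])
}
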