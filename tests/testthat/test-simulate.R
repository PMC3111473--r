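test_that("epistatic simulator meets quotas and records the truth", {
  sim <- sim_epistatic_gwas(n_cases = 60, n_controls = 40, n_snps = 20,
                            risk_clauses = list(c(1, 2)), seed = 8)
  g <- sim$genotypes
  expect_equal(sum(g$status == "case"), 60)
  expect_equal(sum(g$status == "control"), 40)
  expect_equal(dim(g$values), c(100L, 20L))
  expect_equal(length(sim$truth$risk_carrier), 100L)
  # the truth flag reproduces the clause on the emitted genotypes
  carrier <- g$values[, 1] == 1 & g$values[, 2] == 1
  expect_equal(unname(sim$truth$risk_carrier), unname(carrier))
  # reproducibility
  sim2 <- sim_epistatic_gwas(n_cases = 60, n_controls = 40, n_snps = 20,
                             risk_clauses = list(c(1, 2)), seed = 8)
  expect_identical(sim$genotypes$values, sim2$genotypes$values)
})

test_that("risk-genotype enrichment in cases follows the closed form", {
  # P(case | carrier) = min(RR b, 1); P(case | non) = b; by Bayes the
  # carrier frequency among cases is q RR / (q RR + 1 - q) for RR b <= 1
  rr <- 3; b <- 0.2
  reps <- 40
  fr_case <- fr_ctrl <- q_hat <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- sim_epistatic_gwas(n_cases = 100, n_controls = 100, n_snps = 10,
                              maf_range = c(0.3, 0.4),
                              risk_clauses = list(c(1, 2)),
                              relative_risk = rr, baseline_prevalence = b,
                              seed = 400 + r)
    rc <- sim$truth$risk_carrier
    fr_case[r] <- mean(rc[sim$genotypes$status == "case"])
    fr_ctrl[r] <- mean(rc[sim$genotypes$status == "control"])
  }
  maf1 <- 0.4; maf2 <- 0.4 - 0.1 / 9
  q <- maf1^2 * maf2^2
  exp_case <- q * rr / (q * rr + 1 - q)
  exp_ctrl <- q * (1 - rr * b) / (q * (1 - rr * b) + (1 - q) * (1 - b))
  se_case <- sqrt(exp_case * (1 - exp_case) / (100 * reps))
  se_ctrl <- sqrt(exp_ctrl * (1 - exp_ctrl) / (100 * reps))
  expect_lt(abs(mean(fr_case) - exp_case), 4 * se_case)
  expect_lt(abs(mean(fr_ctrl) - exp_ctrl), 4 * se_ctrl)
  # degenerate case: relative risk 1 behaves like the null generator
  sim_flat <- sim_epistatic_gwas(n_cases = 200, n_controls = 200,
                                 n_snps = 10, maf_range = c(0.3, 0.4),
                                 risk_clauses = list(c(1, 2)),
                                 relative_risk = 1, seed = 77)
  rc <- sim_flat$truth$risk_carrier
  p_diff <- suppressWarnings(stats::prop.test(
    c(sum(rc[sim_flat$genotypes$status == "case"]),
      sum(rc[sim_flat$genotypes$status == "control"])),
    c(200, 200)))$p.value
  expect_gt(p_diff, 0.01)
})

test_that("null generator is calibrated: uniform Fisher p, HWE, target MAF", {
  sim <- sim_null_gwas(n_cases = 50, n_controls = 50, n_snps = 1000,
                       maf_range = c(0.2, 0.4), seed = 12)
  g <- sim$genotypes
  # per-SNP Fisher p behaves like a (conservative, discrete) null p-value:
  # type-I error at 0.05 no higher than nominal plus binomial slack, and the
  # mean reflects the discreteness-induced conservatism
  p <- fisher_exact_association(g)$p
  expect_lt(mean(p <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
  expect_gt(mean(p <= 0.05), 0.005)
  expect_gt(mean(p), 0.5)
  expect_lt(mean(p), 0.65)
  # realised MAF within 3 binomial standard errors of target
  target <- sim$truth$mafs$maf
  realised <- colMeans(g$values)
  se <- sqrt(target * (1 - target) / (2 * 100))
  expect_gt(mean(abs(realised - target) <= 3 * se), 0.98)
  # HWE: aggregate chi-square goodness of fit against Binomial(2, maf)
  chi <- vapply(seq_len(1000), function(j) {
    m <- target[j]
    obs <- c(sum(g$values[, j] == 0), sum(g$values[, j] == 0.5),
             sum(g$values[, j] == 1))
    expd <- 100 * c((1 - m)^2, 2 * m * (1 - m), m^2)
    sum((obs - expd)^2 / expd)
  }, numeric(1))
  # sum of 1000 ~chi2(2) variates: normal approximation band
  expect_lt(abs(sum(chi) - 2000), 4 * sqrt(2 * 2 * 1000))
  # labels are independent of genotypes by construction; reproducible
  sim2 <- sim_null_gwas(n_cases = 50, n_controls = 50, n_snps = 1000,
                        maf_range = c(0.2, 0.4), seed = 12)
  expect_identical(sim$genotypes$values, sim2$genotypes$values)
})

test_that("XOR design hides from centroids and shows in pairwise distances", {
  sim <- sim_xor_gwas(n_per_class = 40, seed = 4)
  g <- sim$genotypes
  focal <- sim$truth$focal
  case <- g$status == "case"
  # class-wise MAF difference exactly zero at both focal loci
  for (m in focal) {
    expect_identical(mean(g$values[case, m]), mean(g$values[!case, m]))
  }
  # equal centroids: pooled-class locus distance is identically zero
  f <- colMeans(g$values[!case, focal])
  gm <- colMeans(g$values[case, focal])
  d_all <- locus_distance(g$values[, focal],
                          matrix(f, sum(case) * 2, 2, byrow = TRUE),
                          matrix(gm, sum(case) * 2, 2, byrow = TRUE))
  expect_lt(max(abs(colMeans(d_all[case, ]) - colMeans(d_all[!case, ]))),
            1e-12)
  # pairwise mode separates the classes on the same data
  pw <- pairwise_distance_statistics(g, focal)
  p <- suppressWarnings(stats::wilcox.test(pw$D[case], pw$D[!case]))$p.value
  expect_lt(p, 0.01)
})

test_that("annotation fixture is consistent and round-trips through files", {
  d <- tempfile()
  ann <- make_annotation_fixture(n_pathways = 2, genes_per_pathway = 6,
                                 snps_per_gene = 1, dir = d)
  expect_equal(dplyr::n_distinct(ann$pathways$pathway), 2L)
  expect_equal(nrow(ann$gene_snps), 12L)
  files <- attr(ann, "files")
  pw <- read_pathways_gmt(files["gmt"])
  mp <- read_snp_gene_map(files["map"])
  expect_equal(pw, ann$pathways)
  expect_equal(mp, ann$gene_snps[order(ann$gene_snps$gene), ],
               ignore_attr = TRUE)
  # causal designation places the listed SNPs in pathway 1
  ann2 <- make_annotation_fixture(n_pathways = 4, genes_per_pathway = 12,
                                  snps_per_gene = 1,
                                  snp_ids = sprintf("snp%02d", 1:48),
                                  causal_snps = sprintf("snp%02d", 1:12))
  pw1_genes <- ann2$pathways$gene[ann2$pathways$pathway == "pathway01"]
  pw1_snps <- ann2$gene_snps$snp[ann2$gene_snps$gene %in% pw1_genes]
  expect_setequal(pw1_snps, sprintf("snp%02d", 1:12))
})
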