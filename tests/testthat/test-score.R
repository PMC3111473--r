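test_that("rank-sum hits its extremes and handles midrank ties", {
  expect_equal(pathway_rank_sum(c(3, 2, 1, 0),
                                c("case", "case", "control", "control")), 7)
  expect_equal(pathway_rank_sum(c(0, 1, 2, 3),
                                c("case", "case", "control", "control")), 3)
  # three tied values share midrank 3: W = 6
  expect_equal(pathway_rank_sum(c(1, 1, 1, 0),
                                c("case", "case", "control", "control")), 6)
})

test_that("rank-sum agrees with the counting oracle on random tied instances", {
  set.seed(31)
  for (r in 1:200) {
    n <- sample(4:14, 1)
    n_case <- if (n == 4) 2L else sample(2:(n - 2), 1)
    case <- seq_len(n) <= n_case
    # coarse grid forces frequent ties
    D <- sample(seq(0, 2, 0.5), n, replace = TRUE)
    W <- pathway_rank_sum(D, ifelse(case, "case", "control"))
    expect_equal(W, oracle_ranksum(D, case))
    W_ctrl <- pathway_rank_sum(D, ifelse(case, "control", "case"))
    expect_equal(W + W_ctrl, n * (n + 1) / 2)
    # W within its combinatorial range
    n1 <- n_case; n0 <- n - n_case
    expect_gte(W, n1 * (n1 + 1) / 2)
    expect_lte(W, n1 * (n1 + 1) / 2 + n1 * n0)
  }
})

test_that("rank-sum is invariant to shifting every D by a constant", {
  set.seed(13)
  D <- rnorm(20)
  st <- rep(c("case", "control"), 10)
  expect_equal(pathway_rank_sum(D + 5, st), pathway_rank_sum(D, st))
})

test_that("distinction score standardises against the ensemble", {
  expect_equal(distinction_score(60, c(45, 50, 55)), 2.0)
  w <- c(48, 50, 52)
  expect_equal(distinction_score(mean(w), w), 0)
  expect_error(distinction_score(10, c(5, 5, 5)), "zero variance")
  expect_error(distinction_score(10, 5), "at least 2")
})

null_fixture <- function(seed, n_cases = 15, n_controls = 15, n_genes = 8) {
  sim <- sim_null_gwas(n_cases = n_cases, n_controls = n_controls,
                       n_snps = n_genes, seed = seed)
  ann <- make_annotation_fixture(n_pathways = 2, genes_per_pathway = n_genes / 2,
                                 snp_ids = snp_ids(sim$genotypes))
  sel <- select_representative_snps(sim$genotypes, ann,
                                    qc_snps = snp_ids(sim$genotypes))
  list(genotypes = sim$genotypes, annotation = ann, selection = sel)
}

test_that("permutation ensemble is seed-reproducible and label-balanced", {
  fx <- null_fixture(21)
  e1 <- permutation_null(fx$genotypes, fx$selection, "pathway01",
                         n_perm = 15, seed = 99)
  e2 <- permutation_null(fx$genotypes, fx$selection, "pathway01",
                         n_perm = 15, seed = 99)
  expect_identical(e1$w_values, e2$w_values)
  # every permutation preserves class sizes
  expect_true(all(colSums(e1$perm_case) == sum(fx$genotypes$status == "case")))
  expect_error(permutation_null(fx$genotypes, fx$selection, "pathway01",
                                n_perm = 1), ">= 2")
})

test_that("null ensemble mean approximates the closed-form rank-sum mean", {
  fx <- null_fixture(22, n_cases = 20, n_controls = 20)
  e <- permutation_null(fx$genotypes, fx$selection, "pathway01",
                        n_perm = 300, seed = 7)
  n1 <- 20; N <- 40
  expected <- n1 * (N + 1) / 2   # 410
  se <- sqrt(n1 * n1 * (N + 1) / 12)  # null sd of W
  expect_lt(abs(mean(e$w_values) - expected), 4 * se / sqrt(300))
})

test_that("permuted labels re-select the alternate SNP when ordering flips", {
  true_case <- rep(c(TRUE, FALSE), each = 4)
  v <- cbind(snpT = as.numeric(true_case),
             snpO = c(1, 0, 1, 0, 0, 1, 0, 1),
             filler = rep(c(0, 0.5), 4))
  rownames(v) <- paste0("s", 1:8)
  g <- poda_genotypes(v, ifelse(true_case, "case", "control"))
  ann <- poda_annotation(
    pathways = tibble::tibble(pathway = "pw", source = "s",
                              gene = c("geneX", "geneF")),
    gene_snps = tibble::tibble(gene = c("geneX", "geneX", "geneF"),
                               snp = c("snpT", "snpO", "filler"))
  )
  sel <- select_representative_snps(g, ann, qc_snps = colnames(v))
  expect_equal(sel$snp_sets$pw, c("snpT", "filler"))
  e <- permutation_null(g, sel, "pw", n_perm = 60, seed = 3)
  picked <- vapply(e$snp_sets, function(s) "snpO" %in% s, logical(1))
  expect_true(any(picked))
})

test_that("resampling p-value brackets and tie handling behave", {
  fx <- null_fixture(23)
  rp <- resample_pvalue(fx$genotypes, fx$selection, "pathway01",
                        n_resample = 19, n_perm = 20, seed = 17)
  expect_gte(rp$p_resample, 1 / 20)
  expect_lte(rp$p_resample, 1)
  expect_equal(rp$p_resample, (rp$b + 1) / 20)
  # drawing the pathway itself ties and counts toward b: force it by using
  # a pool exactly the pathway's size
  sel_small <- fx$selection
  sel_small$pool <- sel_small$pool[
    sel_small$pool$snp %in% sel_small$snp_sets$pathway01, ]
  rp2 <- resample_pvalue(fx$genotypes, sel_small, "pathway01",
                         n_resample = 5, n_perm = 20, seed = 17)
  expect_equal(rp2$p_resample, 1)   # every draw is the pathway itself
  # pool smaller than the pathway is an error
  sel_small$pool <- sel_small$pool[1:2, ]
  expect_error(resample_pvalue(fx$genotypes, sel_small, "pathway01",
                               n_resample = 5, n_perm = 20), "pool")
})

test_that("union of pathways equals direct computation on the merged set", {
  fx <- null_fixture(24)
  sets <- fx$selection$snp_sets
  expect_equal(length(union(sets$pathway01, sets$pathway02)), 8L)
  cp <- combine_pathways(fx$genotypes, fx$selection,
                         c("pathway01", "pathway02"),
                         n_perm = 10, n_resample = 9, seed = 5)
  direct <- sample_distance_statistics(
    fx$genotypes, union(sets$pathway01, sets$pathway02))
  expect_equal(cp$profile$D, direct$D)
  expect_equal(cp$result$W, pathway_rank_sum(direct))
  # overlapping sets deduplicate
  expect_equal(length(unique(unlist(sets))), 8L)
})
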