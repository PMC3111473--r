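make_assoc_genotypes <- function() {
  # 8 samples, 4 cases; snpA perfectly tracks the labels, snpB is flat
  v <- cbind(
    snpA = c(1, 1, 1, 1, 0, 0, 0, 0),
    snpB = c(0.5, 0, 0.5, 0, 0.5, 0, 0.5, 0),
    snpC = c(1, 0.5, 1, 0, 0, 0.5, 0, 0.5)
  )
  rownames(v) <- paste0("s", 1:8)
  poda_genotypes(v, rep(c("case", "control"), each = 4))
}

test_that("Fisher association matches the hypergeometric enumeration oracle", {
  g <- make_assoc_genotypes()
  # balanced flat table -> no association
  expect_equal(fisher_exact_association(g, "snpB")$p, 1.0)
  # snpA gives the allele table [[8,0],[0,8]]; cross-check against the
  # enumeration oracle and against fisher.test on small random tables
  p_a <- fisher_exact_association(g, "snpA")$p
  expect_equal(p_a, oracle_fisher2x2(matrix(c(8, 0, 0, 8), 2, byrow = TRUE)))
  # the canonical 4/0|0/4 table: p = 2/70 by enumeration
  tab <- matrix(c(4, 0, 0, 4), 2, byrow = TRUE)
  expect_equal(oracle_fisher2x2(tab), 2 / 70)
  expect_equal(stats::fisher.test(tab)$p.value, 2 / 70)
  # label swap leaves the two-sided p unchanged
  swapped <- ifelse(g$status == "case", "control", "case")
  expect_equal(fisher_exact_association(g, "snpC")$p,
               fisher_exact_association(g, "snpC", status = swapped)$p)
})

test_that("random 2x2 allele tables agree with fisher.test", {
  set.seed(11)
  for (r in 1:25) {
    n_ca <- sample(3:10, 1); n_co <- sample(3:10, 1)
    y <- sample(c(0, 0.5, 1), n_ca + n_co, replace = TRUE)
    v <- matrix(y, ncol = 1, dimnames = list(paste0("s", seq_along(y)), "m"))
    g <- poda_genotypes(v, rep(c("case", "control"), c(n_ca, n_co)))
    mine <- fisher_exact_association(g, "m")$p
    minor_ca <- 2 * sum(y[1:n_ca]); minor_co <- 2 * sum(y[-(1:n_ca)])
    tab <- matrix(c(minor_ca, 2 * n_ca - minor_ca,
                    minor_co, 2 * n_co - minor_co), 2, byrow = TRUE)
    ref <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
      else stats::fisher.test(tab)$p.value
    expect_equal(mine, ref)
  }
})

test_that("zero-margin tables return p = 1 with a warning", {
  v <- matrix(0, 4, 1, dimnames = list(paste0("s", 1:4), "mono"))
  g <- poda_genotypes(v, c("case", "case", "control", "control"))
  expect_warning(p <- fisher_exact_association(g, "mono")$p, "zero-margin")
  expect_equal(p, 1)
})

test_that("per-gene selection takes the smallest p, ties lexicographically", {
  g <- make_assoc_genotypes()
  ann <- poda_annotation(
    pathways = tibble::tibble(pathway = "pw1", source = "s",
                              gene = c("gene1", "gene2")),
    gene_snps = tibble::tibble(gene = c("gene1", "gene1", "gene2"),
                               snp = c("snpA", "snpB", "snpC"))
  )
  sel <- select_representative_snps(g, ann, qc_snps = snp_ids(g))
  # snpA (associated) beats snpB (flat) for gene1
  expect_equal(sel$selection$snp[sel$selection$gene == "gene1"], "snpA")
  expect_equal(sel$snp_sets$pw1, c("snpA", "snpC"))
  # pool covers every mapped gene with a retained SNP
  expect_equal(nrow(sel$pool), 2L)

  # exact tie: duplicate snpA's genotypes under a new id sorting later
  v2 <- cbind(g$values, snpA2 = g$values[, "snpA"])
  g2 <- poda_genotypes(v2, g$status)
  ann2 <- poda_annotation(
    pathways = tibble::tibble(pathway = "pw1", source = "s",
                              gene = c("gene1", "gene2")),
    gene_snps = tibble::tibble(gene = c("gene1", "gene1", "gene2"),
                               snp = c("snpA2", "snpA", "snpC"))
  )
  sel2 <- select_representative_snps(g2, ann2, qc_snps = snp_ids(g2))
  expect_equal(sel2$selection$snp[sel2$selection$gene == "gene1"], "snpA")
})

test_that("pathways collapsing below 2 covered genes are excluded", {
  g <- make_assoc_genotypes()
  ann <- poda_annotation(
    pathways = tibble::tibble(
      pathway = c("pw1", "pw1", "pw2", "pw2"),
      source = "s",
      gene = c("gene1", "gene2", "gene1", "gene_unprobed")
    ),
    gene_snps = tibble::tibble(gene = c("gene1", "gene2"),
                               snp = c("snpA", "snpC"))
  )
  sel <- select_representative_snps(g, ann, qc_snps = snp_ids(g))
  expect_true("pw1" %in% names(sel$snp_sets))
  expect_false("pw2" %in% names(sel$snp_sets))
  expect_true("pw2" %in% sel$dropped_pathways)
})

test_that("selection responds to label permutation and is deterministic", {
  # gene with two SNPs: snpT tracks the true labels, snpP tracks a
  # specific permutation of them
  true_case <- rep(c(TRUE, FALSE), each = 4)
  perm_case <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  v <- cbind(snpP = as.numeric(perm_case), snpT = as.numeric(true_case))
  rownames(v) <- paste0("s", 1:8)
  g <- poda_genotypes(v, ifelse(true_case, "case", "control"))
  ann <- poda_annotation(
    pathways = tibble::tibble(pathway = "pw", source = "s",
                              gene = c("geneX", "geneY")),
    gene_snps = tibble::tibble(gene = c("geneX", "geneX", "geneY"),
                               snp = c("snpT", "snpP", "snpT"))
  )
  sel_true <- select_representative_snps(g, ann, qc_snps = snp_ids(g))
  expect_equal(sel_true$selection$snp[sel_true$selection$gene == "geneX"],
               "snpT")
  sel_perm <- select_representative_snps(
    g, ann, qc_snps = snp_ids(g),
    status = ifelse(perm_case, "case", "control"))
  expect_equal(sel_perm$selection$snp[sel_perm$selection$gene == "geneX"],
               "snpP")
  # identical inputs give identical selections
  sel_again <- select_representative_snps(g, ann, qc_snps = snp_ids(g))
  expect_identical(sel_true$selection, sel_again$selection)
})

test_that("genotypic 2x3 table option matches fisher.test on the same table", {
  g <- make_assoc_genotypes()
  p <- fisher_exact_association(g, "snpC", table = "genotypic")$p
  case <- g$status == "case"
  y <- g$values[, "snpC"]
  tab <- rbind(case = c(sum(case & y == 0), sum(case & y == 0.5),
                        sum(case & y == 1)),
               control = c(sum(!case & y == 0), sum(!case & y == 0.5),
                           sum(!case & y == 1)))
  expect_equal(p, stats::fisher.test(tab)$p.value)
})
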