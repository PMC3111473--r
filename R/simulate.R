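#' Simulate a case/control GWAS with epistatic risk loci
#'
#' Genotypes are binomial Hardy-Weinberg draws: each individual's value at a
#' locus with minor allele frequency m is Binomial(2, m)/2, giving the
#' \{0, 0.5, 1\} coding. Disease is assigned by a penetrance model: the
#' baseline probability is multiplied by `relative_risk` (capped at 1) for
#' individuals carrying the risk genotype, which is defined by `risk_clauses`
#' — a list of locus index sets, each clause requiring homozygous-minor
#' (value 1) at all its loci, clauses combined by OR. Individuals are drawn
#' from the population until exactly `n_cases` cases and `n_controls`
#' controls are collected.
#'
#' The default configuration matches the epistatic two-clause design: 50 HWE
#' loci with MAFs spanning 0.1-0.4, homozygous-minor at loci \{1,2\} or
#' \{1,3\} conferring a 3-fold relative risk, 250 cases and 250 controls.
#' Per-locus MAFs are evenly spaced across `maf_range` in descending order,
#' placing the interacting loci at the top of the range: the two-locus
#' homozygous-minor carrier frequency scales as maf^4, so risk loci near the
#' lower end of the range would make the risk genotype unobservably rare at
#' these sample sizes, while at ~0.4 the clause frequency is a few percent
#' and the per-SNP marginal association remains weak. Set
#' `maf_spacing = "uniform"` for random MAFs instead.
#'
#' @param n_cases,n_controls Sample quotas (defaults 250/250).
#' @param n_snps Number of loci (default 50).
#' @param maf_range Lower/upper minor allele frequency bounds, within
#'   (0, 0.5\] (default c(0.1, 0.4)).
#' @param risk_clauses List of integer vectors of locus indices; each clause
#'   requires homozygous-minor at all its loci (default
#'   `list(c(1, 2), c(1, 3))`).
#' @param relative_risk Risk ratio for risk-genotype carriers (default 3).
#' @param baseline_prevalence Disease probability for non-carriers (default
#'   0.2); `relative_risk * baseline_prevalence` must be at most 1.
#' @param maf_spacing `"even"` (deterministic, descending) or `"uniform"`
#'   (random draws within `maf_range`).
#' @param seed Optional RNG seed.
#' @param max_draws Cap on population draws before giving up (default 1e7).
#' @return List with `genotypes` (a [poda_genotypes] with status attached)
#'   and `truth` (per-locus MAF tibble, per-sample risk-carrier flag, and
#'   the generating parameters).
#' @examples
#' sim <- sim_epistatic_gwas(n_cases = 50, n_controls = 50, seed = 1)
#' table(sim$genotypes$status, sim$truth$risk_carrier)
#' @export
sim_epistatic_gwas <- function(n_cases = 250, n_controls = 250, n_snps = 50,
                               maf_range = c(0.1, 0.4),
                               risk_clauses = list(c(1, 2), c(1, 3)),
                               relative_risk = 3,
                               baseline_prevalence = 0.2,
                               maf_spacing = c("even", "uniform"),
                               seed = NULL, max_draws = 1e7) {
  maf_spacing <- match.arg(maf_spacing)
  stopifnot(n_cases >= 2, n_controls >= 2, n_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            relative_risk >= 1, baseline_prevalence > 0,
            relative_risk * baseline_prevalence <= 1)
  if (length(risk_clauses) &&
      max(unlist(risk_clauses)) > n_snps) {
    stop("risk clause refers to a locus beyond n_snps", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mafs <- switch(maf_spacing,
    even = seq(maf_range[2], maf_range[1], length.out = n_snps),
    uniform = stats::runif(n_snps, maf_range[1], maf_range[2])
  )
  snp_names <- sprintf("snp%02d", seq_len(n_snps))

  kept_g <- list()
  kept_case <- logical(0)
  kept_risk <- logical(0)
  n_drawn <- 0L
  chunk <- max(1000L, ceiling((n_cases + n_controls) / baseline_prevalence / 4))
  while (sum(kept_case) < n_cases || sum(!kept_case) < n_controls) {
    if (n_drawn >= max_draws) {
      stop("case/control quotas unreachable within ", max_draws,
           " population draws", call. = FALSE)
    }
    nb <- as.integer(min(chunk, max_draws - n_drawn))
    g <- matrix(stats::rbinom(nb * n_snps, 2, rep(mafs, each = nb)) / 2,
                nrow = nb, ncol = n_snps)
    risk <- rep(FALSE, nb)
    for (cl in risk_clauses) {
      risk <- risk | rowSums(g[, cl, drop = FALSE] == 1) == length(cl)
    }
    p_dis <- pmin(1, baseline_prevalence * ifelse(risk, relative_risk, 1))
    dis <- stats::runif(nb) < p_dis
    n_drawn <- n_drawn + nb
    need_case <- n_cases - sum(kept_case)
    need_ctrl <- n_controls - sum(!kept_case)
    take <- (dis & cumsum(dis) <= need_case) |
      (!dis & cumsum(!dis) <= need_ctrl)
    if (any(take)) {
      kept_g[[length(kept_g) + 1L]] <- g[take, , drop = FALSE]
      kept_case <- c(kept_case, dis[take])
      kept_risk <- c(kept_risk, risk[take])
    }
  }
  v <- do.call(rbind, kept_g)
  ord <- order(!kept_case)   # cases first, stable
  v <- v[ord, , drop = FALSE]
  kept_case <- kept_case[ord]
  kept_risk <- kept_risk[ord]
  rownames(v) <- ifelse(kept_case,
                        sprintf("case%03d", cumsum(kept_case)[kept_case]),
                        sprintf("ctrl%03d", cumsum(!kept_case)[!kept_case]))
  colnames(v) <- snp_names
  geno <- poda_genotypes(v, status = ifelse(kept_case, "case", "control"))
  list(
    genotypes = geno,
    truth = list(
      mafs = tibble::tibble(snp = snp_names, maf = mafs),
      risk_carrier = stats::setNames(kept_risk, rownames(v)),
      risk_clauses = risk_clauses,
      relative_risk = relative_risk,
      baseline_prevalence = baseline_prevalence,
      n_population_draws = n_drawn
    )
  )
}

#' Simulate a null case/control GWAS
#'
#' Binomial HWE genotypes as in [sim_epistatic_gwas()], with case/control
#' labels assigned independently of the genotypes (a random subset of
#' `n_cases` samples is labelled case). Used for type-I-error and
#' calibration checks.
#'
#' @inheritParams sim_epistatic_gwas
#' @return List with `genotypes` and `truth` (per-locus MAFs).
#' @export
sim_null_gwas <- function(n_cases = 250, n_controls = 250, n_snps = 50,
                          maf_range = c(0.1, 0.4),
                          maf_spacing = c("even", "uniform"), seed = NULL) {
  maf_spacing <- match.arg(maf_spacing)
  stopifnot(n_cases >= 2, n_controls >= 2, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  mafs <- switch(maf_spacing,
    even = seq(maf_range[2], maf_range[1], length.out = n_snps),
    uniform = stats::runif(n_snps, maf_range[1], maf_range[2])
  )
  n <- n_cases + n_controls
  v <- matrix(stats::rbinom(n * n_snps, 2, rep(mafs, each = n)) / 2,
              nrow = n, ncol = n_snps)
  status <- rep("control", n)
  status[sample.int(n, n_cases)] <- "case"
  rownames(v) <- sprintf("s%04d", seq_len(n))
  colnames(v) <- sprintf("snp%02d", seq_len(n_snps))
  list(
    genotypes = poda_genotypes(v, status = status),
    truth = list(mafs = tibble::tibble(snp = colnames(v), maf = mafs))
  )
}

#' Simulate the XOR epistasis counterexample
#'
#' Two focal loci with genotypes coded 0/1 (homozygous major/minor): every
#' control carries a concordant pair — half (0,0), half (1,1) — and every
#' case a discordant pair — half (0,1), half (1,0). Both loci then have MAF
#' exactly 0.5 in each class, so the case and control centroids coincide and
#' the centroid-based locus distance is identically zero, even though the
#' two classes are perfectly separable from the joint genotype. Null filler
#' loci (binomial HWE at `maf`) are appended. This is the canonical
#' configuration the pairwise-distance variant
#' ([pairwise_distance_statistics()]) can react to and the centroid
#' statistic cannot.
#'
#' @param n_per_class Samples per class (must be even so the halves are
#'   exact).
#' @param maf Minor allele frequency of the filler loci (default 0.3).
#' @param n_null_snps Number of filler loci (default 10).
#' @param seed Optional RNG seed (affects only the filler loci).
#' @return List with `genotypes` and `truth` (`focal` = the two focal SNP
#'   ids).
#' @export
sim_xor_gwas <- function(n_per_class, maf = 0.3, n_null_snps = 10,
                         seed = NULL) {
  stopifnot(n_per_class >= 2, n_per_class %% 2 == 0,
            maf > 0, maf <= 0.5, n_null_snps >= 0)
  if (!is.null(seed)) set.seed(seed)
  h <- n_per_class / 2
  ctrl_focal <- rbind(
    matrix(0, h, 2),
    matrix(1, h, 2)
  )
  case_focal <- rbind(
    cbind(rep(0, h), rep(1, h)),
    cbind(rep(1, h), rep(0, h))
  )
  focal <- rbind(case_focal, ctrl_focal)
  n <- 2 * n_per_class
  filler <- if (n_null_snps > 0) {
    matrix(stats::rbinom(n * n_null_snps, 2, maf) / 2, n, n_null_snps)
  } else {
    matrix(numeric(0), n, 0)
  }
  v <- cbind(focal, filler)
  rownames(v) <- c(sprintf("case%03d", seq_len(n_per_class)),
                   sprintf("ctrl%03d", seq_len(n_per_class)))
  colnames(v) <- sprintf("snp%02d", seq_len(2 + n_null_snps))
  status <- rep(c("case", "control"), each = n_per_class)
  list(
    genotypes = poda_genotypes(v, status = status),
    truth = list(focal = colnames(v)[1:2])
  )
}

#' Build a pathway/SNP-gene annotation fixture
#'
#' Partitions SNP ids into genes (`snps_per_gene` consecutive SNPs each) and
#' genes into pathways (`genes_per_pathway` consecutive genes each), so the
#' fixture is consistent with a simulated genotype matrix whose SNP ids are
#' `snp01, snp02, ...`. With `causal_snps`, the SNPs listed are placed first,
#' making pathway 1 the "causal" pathway covering exactly those loci.
#'
#' @param n_pathways,genes_per_pathway,snps_per_gene Positive counts.
#' @param snp_ids SNP ids to assign (default `sprintf("snp%02d", ...)` for as
#'   many as needed).
#' @param causal_snps Optional SNP ids to place in pathway 1 (their number
#'   must equal `genes_per_pathway * snps_per_gene`).
#' @param dir If given, writes `pathways.gmt` and `snp2gene.tsv` there.
#' @return A [poda_annotation] object (with a `files` attribute when `dir`
#'   was given).
#' @export
make_annotation_fixture <- function(n_pathways, genes_per_pathway,
                                    snps_per_gene = 1, snp_ids = NULL,
                                    causal_snps = NULL, dir = NULL) {
  stopifnot(n_pathways >= 1, genes_per_pathway >= 1, snps_per_gene >= 1)
  n_genes <- n_pathways * genes_per_pathway
  n_snps <- n_genes * snps_per_gene
  if (is.null(snp_ids)) {
    snp_ids <- sprintf("snp%02d", seq_len(n_snps))
  }
  if (length(snp_ids) < n_snps) {
    stop("need ", n_snps, " SNP ids, got ", length(snp_ids), call. = FALSE)
  }
  snp_ids <- snp_ids[seq_len(n_snps)]
  if (!is.null(causal_snps)) {
    if (length(causal_snps) != genes_per_pathway * snps_per_gene) {
      stop("`causal_snps` must fill pathway 1 exactly (",
           genes_per_pathway * snps_per_gene, " SNPs)", call. = FALSE)
    }
    snp_ids <- c(causal_snps, setdiff(snp_ids, causal_snps))
    if (length(snp_ids) < n_snps) {
      stop("not enough distinct SNP ids after placing the causal SNPs",
           call. = FALSE)
    }
    snp_ids <- snp_ids[seq_len(n_snps)]
  }
  genes <- sprintf("gene%03d", seq_len(n_genes))
  gene_snps <- tibble::tibble(
    gene = rep(genes, each = snps_per_gene),
    snp = snp_ids
  )
  pathways <- tibble::tibble(
    pathway = rep(sprintf("pathway%02d", seq_len(n_pathways)),
                  each = genes_per_pathway),
    source = "synthetic",
    gene = genes
  )
  ann <- poda_annotation(pathways, gene_snps)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gmt <- file.path(dir, "pathways.gmt")
    map <- file.path(dir, "snp2gene.tsv")
    write_pathways_gmt(ann$pathways, gmt)
    write_snp_gene_map(ann$gene_snps, map)
    attr(ann, "files") <- c(gmt = gmt, map = map)
  }
  ann
}
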