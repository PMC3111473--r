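#' Run the full analysis from files to result tables
#'
#' Orchestrates the complete procedure: read genotypes, phenotypes, gene
#' sets and the SNP-gene map; QC and per-gene SNP selection; per-pathway
#' distance profiles, distinction scores and resampling p-values; logistic
#' odds ratios with FDR adjustment; redundancy culling; cross-pathway D
#' correlation; and, optionally, successive top-k pathway unions. All
#' outputs are TSV/JSON files under `out_dir`, plus a `manifest.json`
#' echoing every effective parameter and seed so a run is reconstructible
#' from the manifest and the inputs.
#'
#' Input arguments accept either file paths or the corresponding in-memory
#' objects ([poda_genotypes], phenotype tibble, pathway tibble, gene-SNP
#' tibble). All referenced files are checked before any work starts, so a
#' bad path never leaves partial outputs.
#'
#' @param genotypes Genotype file path (VCF / PLINK-additive / TSV) or a
#'   [poda_genotypes] object.
#' @param phenotypes Phenotype table path or tibble (ignored when the
#'   genotype object already carries labels).
#' @param pathways GMT file path or pathway tibble.
#' @param snp_gene_map Two-column TSV path or gene-SNP tibble.
#' @param out_dir Output directory (created if needed).
#' @param max_missing,min_maf,n_perm,n_resample,seed,table As in [poda()].
#' @param cull_threshold,cull_orders Redundancy-culling parameters, see
#'   [pathway_overlap_cull()].
#' @param union_top If a number k >= 2, also writes the top-k successive
#'   union table.
#' @param write_d Also write the per-sample D matrix (default TRUE).
#' @param case_label,control_label Passed to [read_phenotypes()].
#' @return The [poda()] fit, invisibly.
#' @export
run_full_analysis <- function(genotypes, phenotypes = NULL, pathways,
                              snp_gene_map, out_dir,
                              max_missing = 0.10, min_maf = 0.01,
                              n_perm = 100, n_resample = 1000, seed = 1,
                              table = "allelic",
                              cull_threshold = 0.60, cull_orders = 25,
                              union_top = NULL, write_d = TRUE,
                              case_label = NULL, control_label = NULL) {
  # validate every referenced file up front: no partial outputs on bad config
  for (arg in list(genotypes, phenotypes, pathways, snp_gene_map)) {
    if (is.character(arg) && length(arg) == 1L && !file.exists(arg)) {
      stop("input file does not exist: ", arg, call. = FALSE)
    }
  }
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.null(genotypes$status)) {
    if (is.null(phenotypes)) {
      stop("phenotypes required (genotype input carries no labels)",
           call. = FALSE)
    }
    if (is.character(phenotypes)) {
      phenotypes <- read_phenotypes(phenotypes, case_label = case_label,
                                    control_label = control_label)
    }
    genotypes <- attach_phenotypes(genotypes, phenotypes)
  }
  if (is.character(pathways)) pathways <- read_pathways_gmt(pathways)
  if (is.character(snp_gene_map)) snp_gene_map <- read_snp_gene_map(snp_gene_map)
  annotation <- if (inherits(pathways, "poda_annotation")) pathways
    else poda_annotation(pathways, snp_gene_map)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  fit <- poda(genotypes, annotation,
              max_missing = max_missing, min_maf = min_maf,
              n_perm = n_perm, n_resample = n_resample, seed = seed,
              table = table)

  res_path <- file.path(out_dir, "results.tsv")
  d_path <- if (write_d) file.path(out_dir, "d_matrix.tsv") else NULL
  write_results(fit$results, res_path,
                d_matrix = if (write_d) fit$profiles else NULL,
                d_path = d_path)

  cull <- pathway_overlap_cull(
    fit$selection$snp_sets,
    stats::setNames(fit$results$DS, fit$results$pathway),
    threshold = cull_threshold, n_orders = cull_orders, seed = seed
  )
  cull_tbl <- tibble::tibble(
    pathway = c(cull$retained, cull$removed$pathway),
    status = c(rep("retained", length(cull$retained)),
               rep("removed", nrow(cull$removed))),
    partner = c(rep(NA_character_, length(cull$retained)),
                cull$removed$partner),
    overlap = c(rep(NA_real_, length(cull$retained)), cull$removed$overlap)
  )
  utils::write.table(cull_tbl, file.path(out_dir, "culling.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (ncol(fit$profiles) >= 2L) {
    r <- d_correlation_matrix(fit$profiles)
    utils::write.table(
      data.frame(pathway = rownames(r), r, check.names = FALSE),
      file.path(out_dir, "d_correlation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  union_path <- NULL
  if (!is.null(union_top) && union_top >= 2 && nrow(fit$results) >= 2) {
    un <- union_top_k(genotypes, fit, k_max = union_top, seed = seed + 1L)
    union_path <- file.path(out_dir, "union_top.tsv")
    utils::write.table(un, union_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("poda")),
    parameters = fit$params,
    cull = list(threshold = cull_threshold, n_orders = cull_orders,
                modal_frequency = cull$modal_frequency,
                retained = cull$retained),
    seed = seed,
    n_pathways_analysed = nrow(fit$results),
    dropped_pathways = fit$selection$dropped_pathways,
    outputs = c(results = res_path, d_matrix = d_path,
                culling = file.path(out_dir, "culling.tsv"),
                union_top = union_path)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(fit)
}

#' Generate simulated input files for an end-to-end run
#'
#' Writes a complete, self-consistent input set (genotype TSV, phenotype
#' TSV, GMT gene sets, SNP-gene map, truth record as JSON) for one of the
#' built-in designs:
#' \describe{
#'   \item{`epistatic`}{The epistatic two-clause design of
#'     [sim_epistatic_gwas()] (250/250 samples, 50 SNPs, 3-fold relative
#'     risk at homozygous-minor \{1,2\} or \{1,3\}), annotated as four
#'     12-gene pathways with the causal SNPs 1-12 in pathway 1.}
#'   \item{`null`}{Label-independent genotypes ([sim_null_gwas()]),
#'     annotated as two 20-gene pathways.}
#'   \item{`xor`}{The XOR counterexample ([sim_xor_gwas()]), annotated as
#'     two 6-gene pathways with the focal loci in pathway 1.}
#' }
#'
#' @param preset One of `"epistatic"`, `"null"`, `"xor"`.
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param ... Overrides passed on to the corresponding simulator.
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_simulation <- function(preset = c("epistatic", "null", "xor"), dir,
                           seed = 1, ...) {
  preset <- tryCatch(match.arg(preset), error = function(e) {
    stop("unknown preset; available: epistatic, null, xor", call. = FALSE)
  })
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- switch(preset,
    epistatic = sim_epistatic_gwas(seed = seed, ...),
    null = sim_null_gwas(seed = seed, ...),
    xor = sim_xor_gwas(n_per_class = 200, seed = seed, ...)
  )
  n_snps <- ncol(sim$genotypes$values)
  gpp <- switch(preset,           # scale the gene sets to the SNP count
    epistatic = min(12L, n_snps %/% 2L),
    null = min(20L, n_snps %/% 2L),
    xor = min(6L, n_snps %/% 2L)
  )
  ann <- make_annotation_fixture(
    n_pathways = max(2L, n_snps %/% gpp), genes_per_pathway = gpp,
    snps_per_gene = 1,
    snp_ids = colnames(sim$genotypes$values))
  g_path <- file.path(dir, "genotypes.tsv")
  p_path <- file.path(dir, "phenotypes.tsv")
  gmt_path <- file.path(dir, "pathways.gmt")
  map_path <- file.path(dir, "snp2gene.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_genotypes(sim$genotypes, g_path)
  utils::write.table(
    data.frame(sample = rownames(sim$genotypes$values),
               status = as.character(sim$genotypes$status)),
    p_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_pathways_gmt(ann$pathways, gmt_path)
  write_snp_gene_map(ann$gene_snps, map_path)
  jsonlite::write_json(c(sim$truth, list(preset = preset, seed = seed)),
                       truth_path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(c(genotypes = g_path, phenotypes = p_path, pathways = gmt_path,
              snp_gene_map = map_path, truth = truth_path))
}
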