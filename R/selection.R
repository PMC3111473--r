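#' Fisher's exact test of SNP-disease association
#'
#' Two-sided Fisher's exact p-value for each SNP. By default the allelic
#' 2x2 table is used: minor/major allele counts (twice the sum of the
#' 0/0.5/1 values, over non-missing samples) by case/control. The
#' `genotypic` option tests the 2x3 genotype-class table instead.
#' A table with a zero margin is uninformative and returns p = 1 with a
#' warning.
#'
#' @param genotypes A [poda_genotypes] object with phenotypes attached.
#' @param snps SNP ids to test (default: all).
#' @param table `"allelic"` (2x2 allele counts) or `"genotypic"` (2x3
#'   genotype counts).
#' @param status Optional label override (e.g. permuted labels).
#' @param quiet Suppress the zero-margin warning (used inside permutation
#'   loops).
#' @return A tibble with columns `snp` and `p`.
#' @export
fisher_exact_association <- function(genotypes, snps = NULL,
                                     table = c("allelic", "genotypic"),
                                     status = NULL, quiet = FALSE) {
  stopifnot(inherits(genotypes, "poda_genotypes"))
  table <- match.arg(table)
  if (is.null(status)) status <- need_status(genotypes)
  status <- as_status(status, nrow(genotypes$values))
  if (is.null(snps)) snps <- colnames(genotypes$values)
  missing_m <- setdiff(snps, colnames(genotypes$values))
  if (length(missing_m)) {
    stop("unknown SNP ids: ", paste(missing_m, collapse = ", "), call. = FALSE)
  }
  case <- status == "case"
  p <- vapply(snps, function(s) {
    fisher_snp_p(genotypes$values[, s], case, table = table, quiet = quiet)
  }, numeric(1))
  tibble::tibble(snp = snps, p = unname(p))
}

fisher_snp_p <- function(y, case, table = "allelic", quiet = FALSE) {
  obs <- !is.na(y)
  if (table == "allelic") {
    n_ca <- sum(case & obs)
    n_co <- sum(!case & obs)
    min_ca <- round(2 * sum(y[case & obs]))
    min_co <- round(2 * sum(y[!case & obs]))
    tab <- matrix(c(min_ca, 2 * n_ca - min_ca,
                    min_co, 2 * n_co - min_co),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("case", "control"), c("minor", "major")))
  } else {
    tab <- rbind(
      case = c(sum(case & obs & y == 0), sum(case & obs & y == 0.5),
               sum(case & obs & y == 1)),
      control = c(sum(!case & obs & y == 0), sum(!case & obs & y == 0.5),
                  sum(!case & obs & y == 1))
    )
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || ncol(tab) < 2) {
    if (!quiet) warning("zero-margin contingency table; p set to 1",
                        call. = FALSE)
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Select one representative SNP per gene and build pathway SNP sets
#'
#' For every gene with at least one QC-retained, genotyped SNP, picks the
#' SNP with the smallest Fisher's exact p-value (exact ties broken toward
#' the lexicographically smaller SNP id, so selection is deterministic and
#' independent of annotation order). A pathway's SNP set is the deduplicated
#' collection of its covered genes' representatives; pathways left with
#' fewer than 2 covered genes are excluded. The union of representatives
#' over all mapped genes forms the pool from which length-matched random
#' SNP sets are drawn during significance resampling.
#'
#' Picking one marker per gene is deliberate: it keeps within-gene linkage
#' disequilibrium from masquerading as a multi-gene signal. The chosen SNP
#' is the gene's most informative marker, not necessarily a significant one.
#'
#' @param genotypes A [poda_genotypes] object with phenotypes attached.
#' @param annotation A [poda_annotation] object.
#' @param qc_snps SNP ids that passed QC (default:
#'   [qc_filter_snps()] with its defaults).
#' @param table Fisher table form, see [fisher_exact_association()].
#' @param status Optional label override (e.g. permuted labels).
#' @return An object of class `poda_selection`: list with
#'   \describe{
#'     \item{selection}{tibble `pathway`, `source`, `gene`, `snp`, `p`.}
#'     \item{snp_sets}{named list, pathway -> deduplicated SNP id vector.}
#'     \item{pool}{tibble `gene`, `snp`, `p` — one representative per mapped
#'       gene (the resampling pool).}
#'     \item{dropped_pathways}{pathways excluded for covering < 2 genes.}
#'     \item{gene_candidates}{named list, gene -> QC-retained candidate SNP
#'       ids (kept for permutation re-selection).}
#'   }
#' @export
select_representative_snps <- function(genotypes, annotation, qc_snps = NULL,
                                       table = c("allelic", "genotypic"),
                                       status = NULL) {
  stopifnot(inherits(genotypes, "poda_genotypes"),
            inherits(annotation, "poda_annotation"))
  table <- match.arg(table)
  if (is.null(status)) status <- need_status(genotypes)
  status <- as_status(status, nrow(genotypes$values))
  if (is.null(qc_snps)) qc_snps <- qc_filter_snps(genotypes)
  usable <- intersect(qc_snps, colnames(genotypes$values))
  cand <- annotation$gene_snps[annotation$gene_snps$snp %in% usable, ]
  gene_candidates <- split(cand$snp, cand$gene)
  gene_candidates <- lapply(gene_candidates, function(s) sort(unique(s)))
  reps <- reselect_representatives(genotypes$values, status == "case",
                                   gene_candidates, table = table,
                                   compute_all_p = TRUE)
  pw <- dplyr::inner_join(annotation$pathways, reps, by = "gene")
  covered <- dplyr::count(pw, .data$pathway, name = "n_genes")
  dropped <- covered$pathway[covered$n_genes < 2L]
  all_pw <- unique(annotation$pathways$pathway)
  dropped <- union(dropped, setdiff(all_pw, covered$pathway))
  pw <- pw[!pw$pathway %in% dropped, , drop = FALSE]
  snp_sets <- lapply(split(pw$snp, pw$pathway), unique)
  structure(
    list(
      selection = tibble::as_tibble(pw),
      snp_sets = snp_sets,
      pool = reps,
      dropped_pathways = dropped,
      gene_candidates = gene_candidates,
      table = table
    ),
    class = "poda_selection"
  )
}

# Per-gene most-informative SNP under the given labels. Exact p ties break
# to the smaller SNP id (the candidate lists are pre-sorted and which.min
# takes the first minimum). Inside permutation loops (compute_all_p = FALSE)
# single-candidate genes skip the test: the choice cannot change.
reselect_representatives <- function(values, case, gene_candidates,
                                     table = "allelic",
                                     compute_all_p = FALSE) {
  genes <- names(gene_candidates)
  p_cache <- new.env(parent = emptyenv())
  snp_p <- function(s) {
    got <- get0(s, envir = p_cache)
    if (!is.null(got)) return(got)
    p <- fisher_snp_p(values[, s], case, table = table, quiet = TRUE)
    assign(s, p, envir = p_cache)
    p
  }
  rows <- lapply(genes, function(g) {
    snps <- gene_candidates[[g]]
    if (length(snps) == 1L) {
      p <- if (compute_all_p) snp_p(snps) else NA_real_
      list(gene = g, snp = snps, p = p)
    } else {
      p <- vapply(snps, snp_p, numeric(1))
      k <- which.min(p)
      list(gene = g, snp = snps[k], p = unname(p[k]))
    }
  })
  tibble::tibble(
    gene = vapply(rows, `[[`, character(1), "gene"),
    snp = vapply(rows, `[[`, character(1), "snp"),
    p = vapply(rows, `[[`, numeric(1), "p")
  )
}

#' @export
print.poda_selection <- function(x, ...) {
  cat("<poda_selection> ", length(x$snp_sets), " pathways; pool of ",
      nrow(x$pool), " per-gene representative SNPs\n", sep = "")
  if (length(x$dropped_pathways)) {
    cat("  dropped (<2 covered genes): ",
        paste(x$dropped_pathways, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
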