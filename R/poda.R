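#' Pathways of distinction analysis
#'
#' End-to-end analysis over all pathways covered by the annotation:
#' QC-filters the SNPs, selects one representative SNP per gene, computes
#' every sample's leave-one-out relative-distance statistic D per pathway,
#' summarises the case/control D difference as a Wilcoxon rank-sum W,
#' normalises W against a permuted-label ensemble (with per-permutation SNP
#' re-selection) into a distinction score DS, assigns each pathway a
#' length-matched resampling p-value, and models disease odds per unit D by
#' logistic regression with Benjamini-Hochberg adjustment across pathways.
#'
#' One set of `n_perm` label permutations and one set of random draws per
#' distinct pathway length are shared across pathways; this preserves the
#' per-pathway null semantics while keeping the run time proportional to the
#' number of permutations rather than pathways x permutations.
#'
#' @param genotypes A [poda_genotypes] object with phenotypes attached.
#' @param annotation A [poda_annotation] object.
#' @param max_missing,min_maf QC thresholds, see [qc_filter_snps()].
#' @param n_perm Label permutations for the distinction score (default 100).
#' @param n_resample Random SNP sets per pathway length (default 1000).
#' @param seed RNG seed covering permutations and resampling.
#' @param table Fisher table form for SNP selection (`"allelic"` or
#'   `"genotypic"`).
#' @param sd_floor,cap Degeneracy guards, see [sample_distance_statistics()].
#' @param qc_snps Optional pre-computed QC-retained SNP ids (skips
#'   [qc_filter_snps()]).
#' @return An object of class `poda_fit`: list with
#'   \describe{
#'     \item{results}{tibble, one row per analysed pathway: `pathway`,
#'       `source`, `n_genes`, `n_snps`, `W`, `DS`, `p_resample`, `OR`,
#'       `OR_p`, `separation`, `FDR_q`.}
#'     \item{profiles}{numeric matrix of per-sample D values (samples x
#'       pathways).}
#'     \item{selection}{the [select_representative_snps()] result.}
#'     \item{params}{effective parameters, including the seed.}
#'   }
#' @seealso [tidy.poda_fit()], [autoplot.poda_fit()], [combine_pathways()]
#' @examples
#' sim <- sim_null_gwas(n_cases = 25, n_controls = 25, n_snps = 12, seed = 1)
#' ann <- make_annotation_fixture(n_pathways = 2, genes_per_pathway = 6)
#' fit <- poda(sim$genotypes, ann, n_perm = 20, n_resample = 50, seed = 1)
#' tidy(fit)
#' @export
poda <- function(genotypes, annotation,
                 max_missing = 0.10, min_maf = 0.01,
                 n_perm = 100, n_resample = 1000, seed = NULL,
                 table = c("allelic", "genotypic"),
                 sd_floor = 1e-12, cap = 1e6, qc_snps = NULL) {
  stopifnot(inherits(genotypes, "poda_genotypes"),
            inherits(annotation, "poda_annotation"))
  table <- match.arg(table)
  if (n_perm < 2) stop("n_perm must be >= 2", call. = FALSE)
  if (n_resample < 1) stop("n_resample must be >= 1", call. = FALSE)
  case <- need_status(genotypes) == "case"
  if (!is.null(seed)) set.seed(seed)
  if (is.null(qc_snps)) {
    qc_snps <- qc_filter_snps(genotypes, max_missing = max_missing,
                              min_maf = min_maf)
  }
  selection <- select_representative_snps(genotypes, annotation,
                                          qc_snps = qc_snps, table = table)
  pathways <- names(selection$snp_sets)
  if (length(pathways) == 0L) {
    stop("no pathway covers >= 2 genes after QC and SNP mapping",
         call. = FALSE)
  }
  v <- genotypes$values
  pool_snps <- unique(selection$pool$snp)

  # shared permuted labelings; per permutation, re-select every mapped
  # gene's representative once and keep the leave-one-out distance matrix
  # over (pool U re-selected) SNPs
  perm_case <- replicate(n_perm, sample(case))
  rownames(perm_case) <- rownames(v)
  perm_data <- lapply(seq_len(n_perm), function(k) {
    ck <- perm_case[, k]
    reps <- reselect_representatives(v, ck, selection$gene_candidates,
                                     table = table)
    snps_k <- union(pool_snps, reps$snp)
    list(d = loo_d_matrix(v[, snps_k, drop = FALSE], ck),
         rep = stats::setNames(reps$snp, reps$gene),
         case = ck)
  })
  d_true <- loo_d_matrix(v[, pool_snps, drop = FALSE], case)

  # per-pathway observed statistics and permutation ensembles
  pw_genes <- split(selection$selection$gene, selection$selection$pathway)
  rows <- list()
  profiles <- matrix(NA_real_, nrow(v), length(pathways),
                     dimnames = list(rownames(v), pathways))
  for (pw in pathways) {
    set_true <- selection$snp_sets[[pw]]
    st <- standardised_mean(d_true[, match(set_true, pool_snps), drop = FALSE],
                            sd_floor = sd_floor, cap = cap)
    W <- sum(rank(st$D)[case])
    w_perm <- vapply(perm_data, function(pd) {
      set_k <- unique(unname(pd$rep[pw_genes[[pw]]]))
      subset_w(pd$d, match(set_k, colnames(pd$d)), pd$case, sd_floor, cap)
    }, numeric(1))
    DS <- distinction_score(W, w_perm)
    or <- logistic_odds_ratio(st$D, ifelse(case, "case", "control"))
    profiles[, pw] <- st$D
    rows[[pw]] <- tibble::tibble(
      pathway = pw,
      source = selection$selection$source[
        match(pw, selection$selection$pathway)],
      n_genes = length(pw_genes[[pw]]),
      n_snps = length(set_true),
      W = W, DS = DS,
      OR = or$OR, OR_p = or$OR_p, separation = or$separation
    )
  }
  results <- dplyr::bind_rows(rows)

  # length-matched resampling null, one batch of draws per distinct length
  sizes <- sort(unique(results$n_snps))
  ds_random <- lapply(stats::setNames(sizes, sizes), function(s) {
    vapply(seq_len(n_resample), function(b) {
      rows_b <- sample.int(nrow(selection$pool), s)
      snps_b <- unique(selection$pool$snp[rows_b])
      w_obs <- subset_w(d_true, match(snps_b, pool_snps), case, sd_floor, cap)
      w_null <- vapply(perm_data, function(pd) {
        subset_w(pd$d, match(snps_b, colnames(pd$d)), pd$case, sd_floor, cap)
      }, numeric(1))
      (w_obs - mean(w_null)) / stats::sd(w_null)
    }, numeric(1))
  })
  results$p_resample <- vapply(seq_len(nrow(results)), function(i) {
    dsr <- ds_random[[as.character(results$n_snps[i])]]
    (sum(dsr >= results$DS[i]) + 1) / (n_resample + 1)
  }, numeric(1))
  results$FDR_q <- bh_fdr(ifelse(is.na(results$OR_p), 1, results$OR_p))
  results <- results[, c("pathway", "source", "n_genes", "n_snps", "W", "DS",
                         "p_resample", "OR", "OR_p", "separation", "FDR_q")]
  structure(
    list(
      results = results,
      profiles = profiles,
      selection = selection,
      perm_case = perm_case,
      status = need_status(genotypes),
      params = list(max_missing = max_missing, min_maf = min_maf,
                    n_perm = n_perm, n_resample = n_resample, seed = seed,
                    table = table, sd_floor = sd_floor, cap = cap,
                    n_samples = nrow(v), n_cases = sum(case),
                    n_qc_snps = length(qc_snps),
                    pool_size = nrow(selection$pool))
    ),
    class = "poda_fit"
  )
}

#' @export
print.poda_fit <- function(x, ...) {
  cat("<poda_fit> ", nrow(x$results), " pathway(s), ",
      x$params$n_samples, " samples (", x$params$n_cases, " cases); ",
      x$params$n_perm, " permutations, ", x$params$n_resample,
      " resamples\n", sep = "")
  print(x$results)
  invisible(x)
}

#' Tidy the per-pathway result table
#'
#' @param x A `poda_fit` object.
#' @param ... Unused.
#' @return The per-pathway results tibble (one row per analysed pathway).
#' @method tidy poda_fit
#' @export
tidy.poda_fit <- function(x, ...) x$results

#' One-row summary of a fitted analysis
#'
#' @param x A `poda_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: sample/pathway counts, pool size, permutation
#'   and resampling depths, seed, and the number of pathways significant at
#'   `p_resample < 0.05`.
#' @method glance poda_fit
#' @export
glance.poda_fit <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x$results),
    n_samples = x$params$n_samples,
    n_cases = x$params$n_cases,
    pool_size = x$params$pool_size,
    n_perm = x$params$n_perm,
    n_resample = x$params$n_resample,
    n_signif_resample = sum(x$results$p_resample < 0.05),
    seed = if (is.null(x$params$seed)) NA_integer_ else x$params$seed
  )
}

#' Recompute the analysis on the union of several pathways' SNPs
#'
#' Combines pathways by taking the deduplicated union of their selected
#' SNPs (never by pooling their D values into one regression, which would
#' double-count shared SNPs) and recomputing D, W, the distinction score and
#' the resampling p-value exactly as for a single pathway; the permuted-label
#' ensemble re-selects representatives over the union of the pathways'
#' covered genes.
#'
#' @param genotypes A [poda_genotypes] object with phenotypes attached.
#' @param selection A [select_representative_snps()] result.
#' @param pathway_ids Two or more pathway ids present in `selection`.
#' @param n_perm,n_resample,seed,sd_floor,cap As in [poda()].
#' @return List with `result` (one-row tibble: `n_snps`, `W`, `DS`,
#'   `p_resample`, `OR`, `OR_p`, `separation`) and `profile` (the union's
#'   `poda_profile`).
#' @export
combine_pathways <- function(genotypes, selection, pathway_ids,
                             n_perm = 100, n_resample = 1000, seed = NULL,
                             sd_floor = 1e-12, cap = 1e6) {
  stopifnot(inherits(selection, "poda_selection"))
  if (length(pathway_ids) < 2L) stop("need >= 2 pathways to combine",
                                     call. = FALSE)
  missing_pw <- setdiff(pathway_ids, names(selection$snp_sets))
  if (length(missing_pw)) {
    stop("pathway(s) not in selection: ", paste(missing_pw, collapse = ", "),
         call. = FALSE)
  }
  union_set <- unique(unlist(selection$snp_sets[pathway_ids],
                             use.names = FALSE))
  sub <- selection$selection[selection$selection$pathway %in% pathway_ids, ]
  sub <- sub[!duplicated(sub$gene), ]
  sub$pathway <- ".union"
  sel_u <- selection
  sel_u$selection <- sub
  sel_u$snp_sets <- list(".union" = union_set)
  rp <- resample_pvalue(genotypes, sel_u, ".union",
                        n_resample = n_resample, n_perm = n_perm,
                        seed = seed, sd_floor = sd_floor, cap = cap)
  or <- logistic_odds_ratio(rp$profile)
  list(
    result = tibble::tibble(
      n_snps = length(union_set), W = rp$W, DS = rp$DS,
      p_resample = rp$p_resample,
      OR = or$OR, OR_p = or$OR_p, separation = or$separation
    ),
    profile = rp$profile
  )
}

#' Successive top-k pathway unions
#'
#' Orders the fitted pathways by descending odds ratio and, for k = 2 ...
#' `k_max`, recomputes the full analysis on the union of the top k pathways'
#' SNPs ("superpathways"). OR p-values across the reported unions are
#' BH-adjusted.
#'
#' @param genotypes A [poda_genotypes] object with phenotypes attached.
#' @param fit A [poda()] result.
#' @param k_max Largest union size (default: all fitted pathways).
#' @param n_perm,n_resample,seed As in [poda()].
#' @return Tibble with one row per k: `top_k`, `n_snps`, `DS`, `p_resample`,
#'   `OR`, `OR_p`, `FDR_q`.
#' @export
union_top_k <- function(genotypes, fit, k_max = NULL,
                        n_perm = NULL, n_resample = NULL, seed = NULL) {
  stopifnot(inherits(fit, "poda_fit"))
  ord <- fit$results$pathway[order(-fit$results$OR)]
  if (is.null(k_max)) k_max <- length(ord)
  k_max <- min(k_max, length(ord))
  if (k_max < 2L) stop("need >= 2 fitted pathways", call. = FALSE)
  if (is.null(n_perm)) n_perm <- fit$params$n_perm
  if (is.null(n_resample)) n_resample <- fit$params$n_resample
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(2:k_max, function(k) {
    cp <- combine_pathways(genotypes, fit$selection, ord[seq_len(k)],
                           n_perm = n_perm, n_resample = n_resample,
                           seed = NULL)
    dplyr::bind_cols(tibble::tibble(top_k = k), cp$result)
  })
  out <- dplyr::bind_rows(rows)
  out$FDR_q <- bh_fdr(ifelse(is.na(out$OR_p), 1, out$OR_p))
  out
}
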