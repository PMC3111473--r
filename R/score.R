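#' Wilcoxon rank-sum statistic over the per-sample distance values
#'
#' Ranks all samples' D values (ascending, midranks for ties) and sums the
#' ranks of the cases. Large W means the cases sit above the controls, i.e.
#' cases are closer to other cases than controls are.
#'
#' @param profile A `poda_profile` tibble (from
#'   [sample_distance_statistics()]), or a numeric vector of D values.
#' @param status Class labels, required when `profile` is a bare vector.
#' @return The rank-sum statistic W (numeric scalar).
#' @examples
#' pathway_rank_sum(c(3, 2, 1, 0), c("case", "case", "control", "control"))
#' @export
pathway_rank_sum <- function(profile, status = NULL) {
  if (is.data.frame(profile)) {
    D <- profile$D
    if (is.null(status)) status <- profile$status
  } else {
    D <- profile
  }
  if (is.null(status)) stop("`status` required", call. = FALSE)
  status <- as_status(status, length(D))
  sum(rank(D)[status == "case"])
}

#' Permuted-label null ensemble for a pathway's rank-sum statistic
#'
#' Repeats the whole per-pathway computation under permutations of the
#' case/control labels (class sizes preserved). Each permutation re-selects
#' the most informative SNP per gene under the permuted labels — so the
#' ensemble absorbs the selection advantage of large genes — then recomputes
#' the leave-one-out distance profile and its rank-sum statistic W.
#'
#' @param genotypes A [poda_genotypes] object with phenotypes attached.
#' @param selection A [select_representative_snps()] result.
#' @param pathway_id Pathway to analyse (must be present in `selection`).
#' @param n_perm Number of label permutations (default 100).
#' @param seed Optional RNG seed for reproducible permutations.
#' @param sd_floor,cap Degeneracy guards, see [sample_distance_statistics()].
#' @return An object of class `poda_ensemble`: list with `w_values`
#'   (length `n_perm`), `snp_sets` (per-permutation selected SNP sets),
#'   `perm_case` (samples x n_perm logical matrix of permuted case labels),
#'   `n_perm`, `seed`.
#' @export
permutation_null <- function(genotypes, selection, pathway_id,
                             n_perm = 100, seed = NULL,
                             sd_floor = 1e-12, cap = 1e6) {
  stopifnot(inherits(genotypes, "poda_genotypes"),
            inherits(selection, "poda_selection"))
  if (n_perm < 2) stop("n_perm must be >= 2 (the null sd is undefined below ",
                       "that)", call. = FALSE)
  if (!pathway_id %in% names(selection$snp_sets)) {
    stop("pathway not present in selection: ", pathway_id, call. = FALSE)
  }
  case <- need_status(genotypes) == "case"
  genes <- unique(selection$selection$gene[
    selection$selection$pathway == pathway_id])
  if (!is.null(seed)) set.seed(seed)
  perm_case <- replicate(n_perm, sample(case))
  rownames(perm_case) <- rownames(genotypes$values)
  ens <- ensemble_w(genotypes$values, perm_case, genes,
                    selection$gene_candidates, selection$table,
                    sd_floor = sd_floor, cap = cap)
  structure(
    list(w_values = ens$w, snp_sets = ens$sets, perm_case = perm_case,
         n_perm = n_perm, seed = seed, pathway_id = pathway_id),
    class = "poda_ensemble"
  )
}

# W under each permuted labeling, with per-permutation re-selection of the
# given genes' representative SNPs.
ensemble_w <- function(values, perm_case, genes, gene_candidates, table,
                       sd_floor = 1e-12, cap = 1e6) {
  cand <- gene_candidates[intersect(genes, names(gene_candidates))]
  w <- numeric(ncol(perm_case))
  sets <- vector("list", ncol(perm_case))
  for (k in seq_len(ncol(perm_case))) {
    ck <- perm_case[, k]
    reps <- reselect_representatives(values, ck, cand, table = table)
    set_k <- unique(reps$snp)
    d <- loo_d_matrix(values[, set_k, drop = FALSE], ck)
    D <- standardised_mean(d, sd_floor = sd_floor, cap = cap)$D
    w[k] <- sum(rank(D)[ck])
    sets[[k]] <- set_k
  }
  list(w = w, sets = sets)
}

#' Distinction score: rank-sum standardised against its permutation null
#'
#' \deqn{DS = (W - mean(W_{perm})) / sd(W_{perm}),} with the sample (n-1)
#' standard deviation over the permuted-label ensemble. DS is comparable
#' across pathways of different gene and SNP counts.
#'
#' @param W Observed rank-sum statistic.
#' @param ensemble A [permutation_null()] result, or a numeric vector of
#'   permuted-label W values.
#' @return The distinction score (numeric scalar).
#' @examples
#' distinction_score(60, c(45, 50, 55))
#' @export
distinction_score <- function(W, ensemble) {
  w <- if (inherits(ensemble, "poda_ensemble")) ensemble$w_values else ensemble
  if (length(w) < 2) stop("need at least 2 permutation W values", call. = FALSE)
  s <- stats::sd(w)
  if (s == 0) {
    stop("permutation ensemble has zero variance; increase n_perm",
         call. = FALSE)
  }
  (W - mean(w)) / s
}

# Rank-sum for each column-subset of a precomputed per-locus distance
# matrix. `d` is samples x pool-SNPs; dmean recycles correctly down columns.
subset_w <- function(d, cols, case, sd_floor = 1e-12, cap = 1e6) {
  sub <- d[, cols, drop = FALSE]
  used <- rowSums(!is.na(sub))
  d_mean <- rowMeans(sub, na.rm = TRUE)
  ss <- rowSums((sub - d_mean)^2, na.rm = TRUE)
  d_sd <- ifelse(used > 1L, sqrt(ss / pmax(used - 1L, 1L)), 0)
  D <- ifelse(d_sd < sd_floor,
              ifelse(abs(d_mean) < sd_floor, 0, sign(d_mean) * cap),
              d_mean / (d_sd / sqrt(used)))
  sum(rank(D)[case])
}

#' Length-matched resampling p-value for a pathway's distinction score
#'
#' Asks whether the pathway's DS is larger than expected of a random set of
#' as many SNPs, drawn from the pool of per-gene representative SNPs. For
#' each of `n_resample` draws the distinction score is recomputed (the
#' permuted-label ensemble is shared across draws by default); the p-value is
#' the add-one fraction \eqn{(b + 1) / (B + 1)} where b counts random sets
#' whose DS is at least the pathway's (ties count toward b, which is
#' conservative).
#'
#' @inheritParams permutation_null
#' @param n_resample Number of random SNP sets (default 1000).
#' @param ensemble Optional pre-computed [permutation_null()] result for this
#'   pathway; computed if missing.
#' @param share_ensemble If `TRUE` (default) the pathway's permuted labelings
#'   normalise every random set; if `FALSE`, fresh label permutations are
#'   drawn for every random set (slower, no sharing).
#' @return List with `p_resample`, `DS`, `W`, `b`, `ds_random` and the
#'   `ensemble` used.
#' @export
resample_pvalue <- function(genotypes, selection, pathway_id,
                            n_resample = 1000, n_perm = 100, seed = NULL,
                            ensemble = NULL, share_ensemble = TRUE,
                            sd_floor = 1e-12, cap = 1e6) {
  stopifnot(inherits(genotypes, "poda_genotypes"),
            inherits(selection, "poda_selection"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ensemble)) {
    ensemble <- permutation_null(genotypes, selection, pathway_id,
                                 n_perm = n_perm, seed = NULL,
                                 sd_floor = sd_floor, cap = cap)
  }
  case <- need_status(genotypes) == "case"
  snp_set <- selection$snp_sets[[pathway_id]]
  s <- length(snp_set)
  pool <- selection$pool
  if (nrow(pool) < s) {
    stop("representative-SNP pool (", nrow(pool), ") is smaller than the ",
         "pathway SNP count (", s, ")", call. = FALSE)
  }
  profile <- sample_distance_statistics(genotypes, snp_set,
                                        sd_floor = sd_floor, cap = cap)
  W <- pathway_rank_sum(profile)
  DS <- distinction_score(W, ensemble)

  pool_snps <- unique(pool$snp)
  d_true <- loo_d_matrix(genotypes$values[, pool_snps, drop = FALSE], case)
  perm_case <- ensemble$perm_case
  d_perm <- lapply(seq_len(ncol(perm_case)), function(k) {
    loo_d_matrix(genotypes$values[, pool_snps, drop = FALSE], perm_case[, k])
  })
  ds_random <- vapply(seq_len(n_resample), function(b) {
    rows <- sample.int(nrow(pool), s)
    cols <- match(unique(pool$snp[rows]), pool_snps)
    w_obs <- subset_w(d_true, cols, case, sd_floor, cap)
    pc <- if (share_ensemble) perm_case else {
      replicate(ensemble$n_perm, sample(case))
    }
    w_null <- if (share_ensemble) {
      vapply(seq_along(d_perm), function(k) {
        subset_w(d_perm[[k]], cols, perm_case[, k], sd_floor, cap)
      }, numeric(1))
    } else {
      vapply(seq_len(ncol(pc)), function(k) {
        dk <- loo_d_matrix(
          genotypes$values[, pool_snps[cols], drop = FALSE], pc[, k])
        subset_w(dk, seq_along(cols), pc[, k], sd_floor, cap)
      }, numeric(1))
    }
    (w_obs - mean(w_null)) / stats::sd(w_null)
  }, numeric(1))
  b <- sum(ds_random >= DS)
  list(
    p_resample = (b + 1) / (n_resample + 1),
    DS = DS, W = W, b = b,
    ds_random = ds_random,
    ensemble = ensemble,
    profile = profile
  )
}
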