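#' Per-locus relative distance to the case and control centroids
#'
#' For one individual's genotype value `y` at a locus (coded 0/0.5/1) and the
#' minor allele frequencies `f` (control pool) and `g` (case pool) at that
#' locus, the locus distance is
#' \deqn{d = |y - f| - |y - g|,}
#' i.e. distance-to-the-control-centroid minus distance-to-the-case-centroid.
#' Positive values mean the individual is closer to the cases. All arguments
#' recycle, so the function is vectorised over loci and samples.
#'
#' @param y Genotype value(s) in \{0, 0.5, 1\}.
#' @param f Control-pool minor allele frequency (in \[0, 1\]).
#' @param g Case-pool minor allele frequency (in \[0, 1\]).
#' @return Numeric value(s) in \[-1, 1\].
#' @examples
#' locus_distance(1, f = 0.2, g = 0.8)   # 0.6: closer to cases
#' locus_distance(0, f = 0.1, g = 0.4)   # -0.3: closer to controls
#' @export
locus_distance <- function(y, f, g) {
  stopifnot(all(f >= 0 & f <= 1, na.rm = TRUE),
            all(g >= 0 & g <= 1, na.rm = TRUE))
  abs(y - f) - abs(y - g)
}

# Leave-one-out per-locus distance matrix (samples x loci).
#
# For sample i at locus j, f_ij / g_ij are the control- / case-pool MAFs
# computed over non-missing samples with i removed from its own class pool.
# Loci where y_ij is missing, or where the leave-one-out pool has no
# observed genotype, yield NA.
loo_d_matrix <- function(v, case) {
  obs <- !is.na(v)
  m <- v
  m[!obs] <- 0
  n <- nrow(v)
  s <- ncol(v)
  ctrl <- !case
  f_num <- matrix(colSums(m[ctrl, , drop = FALSE]), n, s, byrow = TRUE)
  f_den <- matrix(colSums(obs[ctrl, , drop = FALSE]), n, s, byrow = TRUE)
  g_num <- matrix(colSums(m[case, , drop = FALSE]), n, s, byrow = TRUE)
  g_den <- matrix(colSums(obs[case, , drop = FALSE]), n, s, byrow = TRUE)
  f_num[ctrl, ] <- f_num[ctrl, , drop = FALSE] - m[ctrl, , drop = FALSE]
  f_den[ctrl, ] <- f_den[ctrl, , drop = FALSE] - obs[ctrl, , drop = FALSE]
  g_num[case, ] <- g_num[case, , drop = FALSE] - m[case, , drop = FALSE]
  g_den[case, ] <- g_den[case, , drop = FALSE] - obs[case, , drop = FALSE]
  d <- abs(v - f_num / f_den) - abs(v - g_num / g_den)
  d[!obs | f_den == 0 | g_den == 0] <- NA
  dimnames(d) <- dimnames(v)
  d
}

# Standardised mean of the per-locus distances, one value per sample.
# d_sd is the sample (n-1) standard deviation over the sample's non-missing
# loci; D = d_mean / (d_sd / sqrt(used_loci)). Degenerate samples (d_sd
# below sd_floor) get D = 0 when d_mean is also ~0, otherwise sign * cap.
standardised_mean <- function(d, sd_floor = 1e-12, cap = 1e6) {
  used <- rowSums(!is.na(d))
  if (any(used == 0L)) {
    stop("no usable loci for sample(s): ",
         paste(rownames(d)[used == 0L], collapse = ", "), call. = FALSE)
  }
  d_mean <- rowMeans(d, na.rm = TRUE)
  ss <- rowSums((d - d_mean)^2, na.rm = TRUE)
  d_sd <- ifelse(used > 1L, sqrt(ss / (used - 1L)), 0)
  D <- ifelse(
    d_sd < sd_floor,
    ifelse(abs(d_mean) < sd_floor, 0, sign(d_mean) * cap),
    d_mean / (d_sd / sqrt(used))
  )
  list(used_loci = unname(as.integer(used)), d_mean = unname(d_mean),
       d_sd = unname(d_sd), D = unname(D))
}

#' Leave-one-out distance profile for a SNP set
#'
#' For every sample, removes it from its own class pool, recomputes the
#' case- and control-pool MAFs over the remaining (non-missing) samples,
#' evaluates the per-locus distance [locus_distance()] at each non-missing
#' locus of the SNP set, and summarises them as the standardised mean
#' \deqn{D_i = \bar d_i / (sd(d_i) / \sqrt{s_i}),}
#' where \eqn{s_i} is the number of loci used for sample i and the standard
#' deviation is the sample (n-1) form. Positive \eqn{D_i} means sample i is
#' closer to the case centroid than to the control centroid, consistently
#' across the set.
#'
#' @param genotypes A [poda_genotypes] object with phenotypes attached.
#' @param snp_set Character vector of SNP ids (must exist in `genotypes`).
#' @param status Optional label override (e.g. permuted labels); defaults to
#'   the labels stored in `genotypes`.
#' @param sd_floor Degeneracy floor for the per-sample sd of the locus
#'   distances (default 1e-12).
#' @param cap Magnitude assigned to a sample whose distances are constant and
#'   non-zero (default 1e6).
#' @return A tibble of class `poda_profile` with columns `sample`, `status`,
#'   `used_loci`, `d_mean`, `d_sd`, `D`; the SNP set is kept in the
#'   `"snp_set"` attribute.
#' @examples
#' g <- sim_null_gwas(n_cases = 10, n_controls = 10, n_snps = 6, seed = 1)
#' prof <- sample_distance_statistics(g$genotypes, snp_ids(g$genotypes))
#' head(prof)
#' @export
sample_distance_statistics <- function(genotypes, snp_set, status = NULL,
                                       sd_floor = 1e-12, cap = 1e6) {
  stopifnot(inherits(genotypes, "poda_genotypes"))
  if (length(snp_set) == 0L) stop("empty SNP set", call. = FALSE)
  missing_m <- setdiff(snp_set, colnames(genotypes$values))
  if (length(missing_m)) {
    stop("SNP(s) absent from genotype matrix: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  if (is.null(status)) status <- need_status(genotypes)
  status <- as_status(status, nrow(genotypes$values))
  v <- genotypes$values[, snp_set, drop = FALSE]
  d <- loo_d_matrix(v, status == "case")
  st <- standardised_mean(d, sd_floor = sd_floor, cap = cap)
  out <- tibble::tibble(
    sample = rownames(v),
    status = status,
    used_loci = st$used_loci,
    d_mean = st$d_mean,
    d_sd = st$d_sd,
    D = st$D
  )
  attr(out, "snp_set") <- snp_set
  class(out) <- c("poda_profile", class(out))
  out
}

#' Pairwise-distance variant of the per-sample statistic
#'
#' Instead of distances to class centroids, computes for each sample the mean
#' sample-to-sample Manhattan distance (averaged per locus; loci missing in
#' either member of a pair are skipped) to all controls other than itself,
#' minus the mean distance to all cases other than itself. Positive values
#' mean closer to the cases. Unlike the centroid statistic, this variant can
#' react to class differences in dispersion around a common centroid
#' (XOR-type epistasis), at quadratic cost in the number of samples.
#'
#' @inheritParams sample_distance_statistics
#' @param metric Distance metric; only `"manhattan"` is implemented.
#' @return A tibble with columns `sample`, `status`, `D` (here the pairwise
#'   relative distance, on the per-locus scale).
#' @export
pairwise_distance_statistics <- function(genotypes, snp_set,
                                         status = NULL,
                                         metric = "manhattan") {
  stopifnot(inherits(genotypes, "poda_genotypes"))
  metric <- match.arg(metric)
  if (length(snp_set) == 0L) stop("empty SNP set", call. = FALSE)
  missing_m <- setdiff(snp_set, colnames(genotypes$values))
  if (length(missing_m)) {
    stop("SNP(s) absent from genotype matrix: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  if (is.null(status)) status <- need_status(genotypes)
  status <- as_status(status, nrow(genotypes$values))
  v <- genotypes$values[, snp_set, drop = FALSE]
  n <- nrow(v)
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (j in seq_len(ncol(v))) {
    y <- v[, j]
    ok <- !is.na(y)
    pair_ok <- outer(ok, ok, `&`)
    dj <- abs(outer(y, y, `-`))
    dj[!pair_ok] <- 0
    acc <- acc + dj
    cnt <- cnt + pair_ok
  }
  if (any(cnt[upper.tri(cnt)] == 0L)) {
    stop("sample pair(s) share no observed locus in the SNP set", call. = FALSE)
  }
  dist_mat <- acc / cnt
  case <- status == "case"
  stat <- vapply(seq_len(n), function(i) {
    others_ctrl <- !case & seq_len(n) != i
    others_case <- case & seq_len(n) != i
    mean(dist_mat[i, others_ctrl]) - mean(dist_mat[i, others_case])
  }, numeric(1))
  out <- tibble::tibble(sample = rownames(v), status = status, D = stat)
  attr(out, "snp_set") <- snp_set
  class(out) <- c("poda_profile", class(out))
  out
}
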