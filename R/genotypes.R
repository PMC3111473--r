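#' Case/control genotype container
#'
#' Bundles a samples-by-SNPs genotype matrix with the case/control status of
#' each sample. Genotypes are coded as the per-individual minor-allele
#' frequency: 0 (homozygous major), 0.5 (heterozygous), 1 (homozygous minor);
#' missing genotypes are `NA`. Under this coding the mean of a column over a
#' pool of samples is that pool's minor allele frequency, which is what the
#' centroid-distance statistic operates on.
#'
#' @param values Numeric matrix, samples in rows and SNPs in columns, with
#'   `rownames` = sample ids and `colnames` = SNP ids. Non-missing entries
#'   must be 0, 0.5 or 1.
#' @param status Character, factor or logical vector of length `nrow(values)`
#'   giving each sample's class; coerced to a factor with levels
#'   `c("control", "case")`. Logical `TRUE` means case. May be `NULL` for a
#'   genotype matrix read before its phenotype table (see
#'   [attach_phenotypes()]); all analysis functions require it.
#' @param snp_meta Optional tibble of per-SNP metadata (chromosome, position,
#'   alleles); must have one row per SNP in `values` order.
#'
#' @return An object of class `poda_genotypes`: a list with elements
#'   `values`, `status` (factor) and `snp_meta`.
#' @examples
#' g <- poda_genotypes(
#'   matrix(c(0, 0.5, 1, 0), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("rs1", "rs2"))),
#'   status = c("case", "control")
#' )
#' n_samples(g)
#' @export
poda_genotypes <- function(values, status = NULL, snp_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x SNPs)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids as rownames and SNP ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids in genotype matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate SNP ids in genotype matrix", call. = FALSE)
  }
  ok <- is.na(values) | values %in% c(0, 0.5, 1)
  if (!all(ok)) {
    bad <- unique(values[!ok])
    stop("genotype values must be 0, 0.5, 1 or NA; found: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(status)) status <- as_status(status, nrow(values))
  if (!is.null(snp_meta)) {
    snp_meta <- tibble::as_tibble(snp_meta)
    if (nrow(snp_meta) != ncol(values)) {
      stop("`snp_meta` must have one row per SNP", call. = FALSE)
    }
  }
  structure(
    list(values = values, status = status, snp_meta = snp_meta),
    class = "poda_genotypes"
  )
}

need_status <- function(genotypes) {
  if (is.null(genotypes$status)) {
    stop("genotypes carry no phenotype labels; attach them with ",
         "attach_phenotypes()", call. = FALSE)
  }
  genotypes$status
}

# Coerce any of the accepted status encodings to factor(control, case).
as_status <- function(status, n) {
  if (length(status) != n) {
    stop("`status` length (", length(status),
         ") does not match the number of samples (", n, ")", call. = FALSE)
  }
  if (is.logical(status)) {
    status <- ifelse(status, "case", "control")
  }
  status <- tolower(as.character(status))
  if (!all(status %in% c("case", "control"))) {
    stop("status labels must be 'case' or 'control' after mapping; found: ",
         paste(unique(setdiff(status, c("case", "control"))), collapse = ", "),
         call. = FALSE)
  }
  if (sum(status == "case") < 2 || sum(status == "control") < 2) {
    stop("need at least 2 cases and 2 controls (leave-one-out requires a ",
         "non-empty remainder pool)", call. = FALSE)
  }
  factor(status, levels = c("control", "case"))
}

#' @export
print.poda_genotypes <- function(x, ...) {
  lab <- if (is.null(x$status)) {
    "no phenotypes attached"
  } else {
    paste0(sum(x$status == "case"), " cases / ",
           sum(x$status == "control"), " controls")
  }
  cat("<poda_genotypes> ", nrow(x$values), " samples (", lab, ") x ",
      ncol(x$values), " SNPs\n", sep = "")
  miss <- mean(is.na(x$values))
  cat("  missingness: ", format(round(100 * miss, 2)), "%\n", sep = "")
  invisible(x)
}

#' @rdname poda_genotypes
#' @param x A `poda_genotypes` object.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname poda_genotypes
#' @export
n_snps <- function(x) ncol(x$values)

#' @rdname poda_genotypes
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname poda_genotypes
#' @export
snp_ids <- function(x) colnames(x$values)

#' Minor allele frequency over a sample pool
#'
#' The MAF of a SNP over a pool is the mean of the \{0, 0.5, 1\} genotype
#' values over the pool's non-missing samples.
#'
#' @param genotypes A [poda_genotypes] object.
#' @param snps SNP ids (default: all SNPs).
#' @param samples Sample ids defining the pool (default: all samples).
#' @return A tibble with columns `snp`, `maf` and `n_obs` (non-missing count).
#' @examples
#' g <- sim_null_gwas(n_cases = 5, n_controls = 5, n_snps = 3, seed = 1)
#' compute_maf(g$genotypes)
#' @export
compute_maf <- function(genotypes, snps = NULL, samples = NULL) {
  stopifnot(inherits(genotypes, "poda_genotypes"))
  v <- genotypes$values
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, rownames(v))
    if (length(missing_s)) {
      stop("unknown sample ids: ", paste(missing_s, collapse = ", "),
           call. = FALSE)
    }
    v <- v[samples, , drop = FALSE]
  }
  if (nrow(v) == 0L) stop("empty sample subset", call. = FALSE)
  if (!is.null(snps)) {
    missing_m <- setdiff(snps, colnames(v))
    if (length(missing_m)) {
      stop("unknown SNP ids: ", paste(missing_m, collapse = ", "),
           call. = FALSE)
    }
    v <- v[, snps, drop = FALSE]
  }
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0L)) {
    stop("MAF undefined (all genotypes missing in subset) for SNP(s): ",
         paste(colnames(v)[n_obs == 0L], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    snp = colnames(v),
    maf = unname(colMeans(v, na.rm = TRUE)),
    n_obs = unname(as.integer(n_obs))
  )
}

#' Quality-control filter for SNPs
#'
#' Retains a SNP iff its missing fraction over all samples is at most
#' `max_missing` and its MAF is at least `min_maf` within the cases and
#' within the controls separately (near-monomorphic SNPs in either class
#' carry no distance information for that class).
#'
#' @param genotypes A [poda_genotypes] object.
#' @param max_missing Maximum tolerated missing-call fraction (default 0.10).
#' @param min_maf Minimum class-wise minor allele frequency (default 0.01).
#' @return Character vector of retained SNP ids (warns when empty).
#' @examples
#' g <- sim_null_gwas(n_cases = 20, n_controls = 20, n_snps = 5, seed = 1)
#' qc_filter_snps(g$genotypes)
#' @export
qc_filter_snps <- function(genotypes, max_missing = 0.10, min_maf = 0.01) {
  stopifnot(inherits(genotypes, "poda_genotypes"))
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  v <- genotypes$values
  case <- need_status(genotypes) == "case"
  miss_frac <- colMeans(is.na(v))
  # a class with zero observed calls for a SNP fails the MAF criterion
  maf_class <- function(rows) {
    sub <- v[rows, , drop = FALSE]
    n <- colSums(!is.na(sub))
    m <- colMeans(sub, na.rm = TRUE)
    ifelse(n == 0L, -Inf, m)
  }
  keep <- miss_frac <= max_missing &
    maf_class(case) >= min_maf &
    maf_class(!case) >= min_maf
  out <- colnames(v)[keep]
  if (length(out) == 0L) {
    warning("no SNPs pass QC (max_missing = ", max_missing,
            ", min_maf = ", min_maf, ")", call. = FALSE)
  }
  out
}

#' Subset a genotype container by SNPs and/or samples
#'
#' @param x A `poda_genotypes` object.
#' @param samples,snps Ids to keep (default: all, in stored order).
#' @param ... Unused.
#' @export
subset.poda_genotypes <- function(x, samples = NULL, snps = NULL, ...) {
  v <- x$values
  st <- x$status
  meta <- x$snp_meta
  if (!is.null(samples)) {
    idx <- match(samples, rownames(v))
    if (anyNA(idx)) {
      stop("unknown sample ids: ",
           paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    v <- v[idx, , drop = FALSE]
    st <- st[idx]
  }
  if (!is.null(snps)) {
    jdx <- match(snps, colnames(v))
    if (anyNA(jdx)) {
      stop("unknown SNP ids: ",
           paste(snps[is.na(jdx)], collapse = ", "), call. = FALSE)
    }
    v <- v[, jdx, drop = FALSE]
    if (!is.null(meta)) meta <- meta[jdx, , drop = FALSE]
  }
  poda_genotypes(v, st, meta)
}
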