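#' Read a genotype matrix
#'
#' Reads biallelic SNP genotypes from one of three plain-text formats and
#' returns them coded as per-individual minor-allele frequencies
#' \{0, 0.5, 1\} with `NA` for missing calls. The minor allele at each SNP is
#' defined by its frequency in the full (cases + controls pooled) sample:
#' after loading, every SNP's pooled mean value is at most 0.5 (up to ties at
#' exactly 0.5).
#'
#' Formats:
#' \describe{
#'   \item{`vcf`}{A VCF with GT fields. Multi-allelic records are skipped
#'     with a warning; `./.` becomes `NA`. At an exact 50/50 allele
#'     frequency the ALT allele stays the minor allele, so re-loading is
#'     deterministic.}
#'   \item{`plink_additive`}{A PLINK `.raw`-style table: header starting with
#'     `FID IID` (further non-genotype columns such as PAT/MAT/SEX/PHENOTYPE
#'     are dropped), then one column per SNP with additive counts 0/1/2 or
#'     NA.}
#'   \item{`tsv`}{A plain matrix: first column sample id, one column per SNP,
#'     additive counts 0/1/2 or NA.}
#' }
#'
#' @param path Path to the file.
#' @param format One of `"vcf"`, `"plink_additive"`, `"tsv"`, or `"auto"`
#'   (by file extension: `.vcf` / `.raw` / anything else is TSV).
#' @return A [poda_genotypes] object without phenotype labels (attach them
#'   with [attach_phenotypes()]).
#' @seealso [read_phenotypes()], [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink_additive", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genotype file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
      else if (grepl("\\.raw$", path, ignore.case = TRUE)) "plink_additive"
      else "tsv"
  }
  switch(format,
    vcf = read_genotypes_vcf(path),
    plink_additive = read_genotypes_additive(path, plink = TRUE),
    tsv = read_genotypes_additive(path, plink = FALSE)
  )
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("no variant records in VCF: ", path, call. = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    warning(sum(!bi), " multi-allelic record(s) skipped (method is defined ",
            "for biallelic SNPs)", call. = FALSE)
    vcf <- vcf[bi, ]
  }
  if (nrow(vcf@fix) == 0L) {
    stop("no usable biallelic SNPs in VCF: ", path, call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  # count ALT alleles from the GT string; any missing allele call -> NA
  alt_count <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(is.na(g) | !grepl("^[01]/[01]$", g), NA_real_,
           (as.numeric(substr(g, 1, 1)) + as.numeric(substr(g, 3, 3))) / 2)
  }
  m <- apply(gt, 2, alt_count)               # SNPs x samples -> numeric
  m <- matrix(m, nrow = nrow(gt), dimnames = list(ids, colnames(gt)))
  v <- t(m)                                   # samples x SNPs, values 0/0.5/1
  alt_freq <- colMeans(v, na.rm = TRUE)
  # flip only when ALT is strictly the major allele; at an exact 50/50 tie
  # the ALT allele stays the minor one, so re-loading is deterministic
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  v[, flip] <- 1 - v[, flip, drop = FALSE]
  meta <- tibble::tibble(
    snp = ids,
    chrom = fix[, "CHROM"],
    pos = suppressWarnings(as.integer(fix[, "POS"])),
    major = unname(ifelse(flip, fix[, "ALT"], fix[, "REF"])),
    minor = unname(ifelse(flip, fix[, "REF"], fix[, "ALT"]))
  )
  poda_genotypes(v, status = NULL, snp_meta = meta)
}

read_genotypes_additive <- function(path, plink = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "."))
  if (plink) {
    if (!all(c("FID", "IID") %in% names(df)[1:2])) {
      stop("PLINK additive file must start with FID and IID columns: ", path,
           call. = FALSE)
    }
    ids <- as.character(df$IID)
    drop <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(df))
    df <- df[, setdiff(names(df), drop), drop = FALSE]
    # .raw headers encode the counted allele as SNP_A; keep the SNP id part
    names(df) <- sub("_[ACGT]$", "", names(df))
  } else {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  if (ncol(df) == 0L) stop("no SNP columns in genotype file: ", path, call. = FALSE)
  v <- as.matrix(df)
  if (!is.numeric(v)) {
    stop("non-numeric genotype entries in ", path, call. = FALSE)
  }
  bad <- !is.na(v) & !(v %in% c(0, 1, 2))
  if (any(bad)) {
    stop("additive genotype entries must be 0, 1, 2 or NA in ", path,
         call. = FALSE)
  }
  v <- v / 2
  rownames(v) <- ids
  freq <- colMeans(v, na.rm = TRUE)
  flip <- !is.na(freq) & freq > 0.5   # exact ties keep file orientation
  v[, flip] <- 1 - v[, flip, drop = FALSE]
  poda_genotypes(v, status = NULL)
}

#' Write a genotype matrix to TSV
#'
#' Writes additive minor-allele counts (0/1/2, `NA` for missing), the format
#' [read_genotypes()] reads back exactly (the stored coding is already
#' minor-allele oriented, so re-loading never flips a SNP).
#'
#' @param genotypes A [poda_genotypes] object.
#' @param path Output path.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "poda_genotypes"))
  counts <- genotypes$values * 2
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a case/control phenotype table
#'
#' Reads a two-column table (sample id, status). Status labels are mapped to
#' case/control: the strings "case"/"control" (any capitalisation) are
#' recognised directly; numeric codings require an explicit mapping via
#' `case_label` / `control_label` (e.g. `case_label = "1", control_label =
#' "0"`).
#'
#' @param path Path to a TSV/whitespace table, with or without a header line.
#' @param case_label,control_label Optional declared status codes.
#' @return A tibble with columns `sample` and `status`
#'   (factor control/case), at least 2 of each class.
#' @export
read_phenotypes <- function(path, case_label = NULL, control_label = NULL) {
  if (!file.exists(path)) stop("cannot read phenotype file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("phenotype table needs two columns (sample, status)",
                          call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("sample", "status")
  # tolerate a header line
  if (tolower(df$sample[1]) %in% c("sample", "sample_id", "id", "iid") ||
      tolower(df$status[1]) %in% c("status", "phenotype", "pheno", "class")) {
    df <- df[-1, , drop = FALSE]
  }
  raw <- df$status
  mapped <- rep(NA_character_, length(raw))
  if (!is.null(case_label)) mapped[raw == as.character(case_label)] <- "case"
  if (!is.null(control_label)) mapped[raw == as.character(control_label)] <- "control"
  std <- tolower(raw) %in% c("case", "control")
  mapped[is.na(mapped) & std] <- tolower(raw[is.na(mapped) & std])
  if (anyNA(mapped)) {
    stop("unrecognised status label(s): ",
         paste(unique(raw[is.na(mapped)]), collapse = ", "),
         "; declare them with case_label/control_label", call. = FALSE)
  }
  if (sum(mapped == "case") < 2 || sum(mapped == "control") < 2) {
    stop("need at least 2 cases and 2 controls (leave-one-out requires a ",
         "non-empty remainder pool)", call. = FALSE)
  }
  tibble::tibble(sample = df$sample,
                 status = factor(mapped, levels = c("control", "case")))
}

#' Attach phenotypes to a genotype matrix
#'
#' Aligns a phenotype table to the genotype sample order (every genotyped
#' sample must appear exactly once in the phenotype table and vice versa) and
#' stores the status factor in the container.
#'
#' @param genotypes A [poda_genotypes] object.
#' @param phenotypes A tibble as returned by [read_phenotypes()], or any
#'   data frame with columns `sample` and `status`.
#' @return The genotype object with `status` filled in, samples in genotype
#'   order.
#' @export
attach_phenotypes <- function(genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "poda_genotypes"))
  phenotypes <- tibble::as_tibble(phenotypes)
  if (!all(c("sample", "status") %in% names(phenotypes))) {
    stop("phenotypes must have columns `sample` and `status`", call. = FALSE)
  }
  gids <- rownames(genotypes$values)
  missing_p <- setdiff(gids, phenotypes$sample)
  extra_p <- setdiff(phenotypes$sample, gids)
  if (length(missing_p) || length(extra_p)) {
    stop("sample mismatch between genotypes and phenotypes; ",
         "genotyped but unphenotyped: [",
         paste(utils::head(missing_p, 5), collapse = ", "),
         if (length(missing_p) > 5) ", ..." else "",
         "]; phenotyped but ungenotyped: [",
         paste(utils::head(extra_p, 5), collapse = ", "),
         if (length(extra_p) > 5) ", ..." else "", "]", call. = FALSE)
  }
  st <- phenotypes$status[match(gids, phenotypes$sample)]
  poda_genotypes(genotypes$values, st, genotypes$snp_meta)
}

#' Write a pathway result table
#'
#' Writes the per-pathway summary as a TSV with columns Pathway, Source,
#' Length, DS, p_DS, OR, FDR_OR, sorted by descending odds ratio. A
#' companion per-sample distance-statistic matrix (samples x pathways) can be
#' written alongside.
#'
#' @param results A tibble with columns `pathway`, `source`, `n_snps`, `DS`,
#'   `p_resample`, `OR`, `FDR_q` (as produced by [poda()] /
#'   [tidy.poda_fit()]).
#' @param path Output TSV path.
#' @param d_matrix Optional numeric matrix of per-sample D values (samples in
#'   rows, pathways in columns).
#' @param d_path Path for the companion matrix (required with `d_matrix`).
#' @export
write_results <- function(results, path, d_matrix = NULL, d_path = NULL) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0L) stop("empty result table", call. = FALSE)
  need <- c("pathway", "source", "n_snps", "DS", "p_resample", "OR", "FDR_q")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    stop("result table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- results[order(-results$OR), need]
  names(out) <- c("Pathway", "Source", "Length", "DS", "p_DS", "OR", "FDR_OR")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(d_matrix)) {
    if (is.null(d_path)) stop("`d_path` required when writing the D matrix",
                              call. = FALSE)
    df <- data.frame(sample = rownames(d_matrix), d_matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, d_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
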