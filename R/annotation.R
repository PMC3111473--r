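#' Pathway and SNP-gene annotation container
#'
#' Holds the two mappings the analysis needs: pathway -> genes (from a GMT
#' gene-set file) and gene -> SNPs (from a two-column map). Both are stored
#' as long tibbles so they compose with dplyr verbs.
#'
#' @param pathways Tibble with columns `pathway`, `source`, `gene` (one row
#'   per pathway-gene pair, no duplicates within a pathway).
#' @param gene_snps Tibble with columns `gene`, `snp` (one row per gene-SNP
#'   pair; a SNP may map to several genes but at most once per gene).
#' @return An object of class `poda_annotation`.
#' @seealso [read_pathways_gmt()], [read_snp_gene_map()]
#' @export
poda_annotation <- function(pathways, gene_snps) {
  pathways <- tibble::as_tibble(pathways)
  gene_snps <- tibble::as_tibble(gene_snps)
  if (!all(c("pathway", "gene") %in% names(pathways))) {
    stop("`pathways` needs columns pathway and gene", call. = FALSE)
  }
  if (!"source" %in% names(pathways)) pathways$source <- NA_character_
  pathways <- pathways[, c("pathway", "source", "gene")]
  if (anyDuplicated(pathways[, c("pathway", "gene")])) {
    stop("duplicate gene within a pathway", call. = FALSE)
  }
  if (!all(c("gene", "snp") %in% names(gene_snps))) {
    stop("`gene_snps` needs columns gene and snp", call. = FALSE)
  }
  gene_snps <- gene_snps[, c("gene", "snp")]
  if (anyDuplicated(gene_snps)) {
    stop("duplicate (gene, snp) pair in map", call. = FALSE)
  }
  structure(list(pathways = pathways, gene_snps = gene_snps),
            class = "poda_annotation")
}

#' @export
print.poda_annotation <- function(x, ...) {
  cat("<poda_annotation> ", dplyr::n_distinct(x$pathways$pathway),
      " pathways over ", dplyr::n_distinct(x$pathways$gene), " genes; ",
      dplyr::n_distinct(x$gene_snps$gene), " genes mapped to ",
      dplyr::n_distinct(x$gene_snps$snp), " SNPs\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' `name <tab> description <tab> gene1 <tab> gene2 ...`. The description
#' field is kept as the set's source. Genes duplicated within a line are
#' dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `pathway`, `source`, `gene`, suitable for
#'   [poda_annotation()].
#' @export
read_pathways_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(tibble::tibble(pathway = character(), source = character(),
                          gene = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3L)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(n_fields < 3L), collapse = ", "), call. = FALSE)
  }
  dup_lines <- which(vapply(parts, function(p) anyDuplicated(p[-(1:2)]) > 0,
                            logical(1)))
  if (length(dup_lines)) {
    warning("duplicated gene(s) within GMT line(s) ",
            paste(dup_lines, collapse = ", "), "; deduplicated", call. = FALSE)
  }
  purrr::map_dfr(parts, function(p) {
    tibble::tibble(pathway = p[1], source = p[2], gene = unique(p[-(1:2)]))
  })
}

#' Read a SNP-to-gene map
#'
#' Two-column TSV: SNP id, gene id (a header line `snp<tab>gene` is
#' tolerated). Exact duplicate rows are dropped; a SNP may map to several
#' genes. SNPs absent from a genotype matrix are kept in the map and simply
#' find no genotype at selection time.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene`, `snp`.
#' @export
read_snp_gene_map <- function(path) {
  if (!file.exists(path)) stop("cannot read SNP-gene map: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed SNP-gene map line(s) (need exactly 2 tab-separated ",
         "fields): line ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- tibble::tibble(
    snp = vapply(parts, `[`, character(1), 1L),
    gene = vapply(parts, `[`, character(1), 2L)
  )
  if (tolower(df$snp[1]) %in% c("snp", "snp_id") ||
      tolower(df$gene[1]) %in% c("gene", "gene_id")) {
    df <- df[-1, , drop = FALSE]
  }
  dplyr::distinct(df[, c("gene", "snp")])
}

#' Write gene sets to a GMT file
#'
#' @param pathways Tibble with columns `pathway`, `source`, `gene`.
#' @param path Output path.
#' @export
write_pathways_gmt <- function(pathways, path) {
  pathways <- tibble::as_tibble(pathways)
  by_pw <- split(pathways, factor(pathways$pathway,
                                  levels = unique(pathways$pathway)))
  lines <- vapply(by_pw, function(d) {
    src <- d$source[1]
    if (is.na(src)) src <- "na"
    paste(c(d$pathway[1], src, d$gene), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a SNP-to-gene map to TSV
#'
#' @param gene_snps Tibble with columns `gene`, `snp`.
#' @param path Output path.
#' @export
write_snp_gene_map <- function(gene_snps, path) {
  gene_snps <- tibble::as_tibble(gene_snps)
  writeLines(paste(gene_snps$snp, gene_snps$gene, sep = "\t"), path)
  invisible(path)
}
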