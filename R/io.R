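# Text I/O for the PLINK-adjacent dialects the pipeline exchanges:
# dosage/variant TSVs, .bim/.fam-style tables, summary-stats TSV, VCF.

#' Write a TSV with header, no quoting, NA as "NA"
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as dosage + variant TSVs
#'
#' `<prefix>.dosage.tsv` holds `individual_id` plus one column per variant id;
#' `<prefix>.variants.tsv` holds id, chrom, pos, a1, a2.
#'
#' @param panel a `genotype_panel`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- data.frame(individual_id = rownames(panel$dosage),
                  panel$dosage, check.names = FALSE,
                  stringsAsFactors = FALSE)
  p1 <- paste0(prefix, ".dosage.tsv")
  p2 <- paste0(prefix, ".variants.tsv")
  write_tsv(d, p1)
  write_tsv(panel$variants, p2)
  invisible(c(p1, p2))
}

#' Read a genotype panel from dosage + variant TSVs
#' @param dosage_path TSV with `individual_id` column then variant columns.
#' @param variants_path TSV with id, chrom, pos, a1, a2.
#' @return a `genotype_panel`.
#' @export
read_dosage_panel <- function(dosage_path, variants_path) {
  d <- utils::read.delim(dosage_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  v <- utils::read.delim(variants_path, stringsAsFactors = FALSE)
  ids <- d$individual_id
  d$individual_id <- NULL
  m <- as.matrix(d)
  cols <- match(v$id, colnames(m))
  if (anyNA(cols))
    stop("dosage columns do not cover the variant table")
  genotype_panel(m[, cols, drop = FALSE], v, as.character(ids))
}

#' Read PLINK-style .bim / .fam tables
#'
#' `.bim`: six headerless columns (chrom, id, cm, pos, a1, a2). `.fam`: six
#' headerless columns (fid, iid, pat, mat, sex, phenotype).
#'
#' @param path file path.
#' @return data.frame with named columns.
#' @export
read_bim <- function(path) {
  x <- utils::read.table(path, stringsAsFactors = FALSE)
  if (ncol(x) != 6) stop(".bim-style table must have 6 columns")
  names(x) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  x
}

#' @rdname read_bim
#' @export
read_fam <- function(path) {
  x <- utils::read.table(path, stringsAsFactors = FALSE)
  if (ncol(x) != 6) stop(".fam-style table must have 6 columns")
  names(x) <- c("fid", "iid", "pat", "mat", "sex", "phenotype")
  x
}

#' Read GWAS summary statistics
#'
#' Required header: SNP, CHR, BP, A1, A2, BETA, SE, P. A1 is the effect
#' allele the BETA applies to.
#'
#' @param path TSV file.
#' @return a `summary_stats` data.frame (columns id, chrom, pos, a1, a2,
#'   beta, se, p).
#' @export
read_summary_stats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")
  if (!all(req %in% names(x)))
    stop("summary-stats file must have header columns ",
         paste(req, collapse = ", "))
  summary_stats(data.frame(id = x$SNP, chrom = as.character(x$CHR),
                           pos = x$BP, a1 = x$A1, a2 = x$A2,
                           beta = x$BETA, se = x$SE, p = x$P,
                           stringsAsFactors = FALSE))
}

#' Write GWAS summary statistics in SNP/CHR/BP/A1/A2/BETA/SE/P dialect
#' @param stats a `summary_stats` object.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  write_tsv(data.frame(SNP = stats$id, CHR = stats$chrom, BP = stats$pos,
                       A1 = stats$a1, A2 = stats$a2, BETA = stats$beta,
                       SE = stats$se, P = stats$p), path)
}

#' Read a VCF into a genotype panel
#'
#' Parses GT fields; dosage counts copies of the VCF ALT allele, which is
#' taken as the panel effect allele (A1). Missing GT becomes `NA`. Requires
#' the vcfR package.
#'
#' @param path VCF file (plain text or gzipped).
#' @return a `genotype_panel`.
#' @export
read_vcf_panel <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_panel requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  clean <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  dos <- matrix(unname(map[clean]), nrow = nrow(gt), dimnames = dimnames(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.numeric(fix$POS),
                         a1 = fix$ALT, a2 = fix$REF,
                         stringsAsFactors = FALSE)
  genotype_panel(t(dos), variants, colnames(gt))
}

#' Write a genotype panel as a minimal VCF (GT fields, hard calls)
#' @param panel a `genotype_panel`.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_vcf_panel <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- apply(panel$dosage, 2, function(g) {
    out <- gt_code[as.character(g)]
    out[is.na(out)] <- "./."
    out
  })
  body <- t(body)  # variants x individuals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(panel$dosage)),
                     collapse = "\t")), con)
  lines <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                 v$id, v$a2, v$a1, ".", "PASS", ".", "GT",
                 apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
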