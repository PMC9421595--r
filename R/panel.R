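#' Construct a genotype panel
#'
#' A genotype panel couples an individuals-by-variants dosage matrix (entries
#' 0/1/2, `NA` for missing calls) with per-variant metadata: variant id,
#' chromosome, 1-based physical position, effect allele (A1) and other allele
#' (A2). It is the substrate for variant QC, LD, principal components and
#' polygenic scoring.
#'
#' @param dosage numeric matrix, individuals in rows and variants in columns;
#'   entries in \{0, 1, 2\} or `NA`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`;
#'   one row per dosage column, ids unique.
#' @param individuals character vector of unique individual ids; defaults to
#'   the dosage rownames or `ind1..indN`.
#' @return an object of class `genotype_panel` with elements `dosage`
#'   (dimnames set to individual and variant ids) and `variants`.
#' @examples
#' g <- matrix(c(0, 1, 2, 1), nrow = 2)
#' v <- data.frame(id = c("v1", "v2"), chrom = c(1, 1), pos = c(100, 200),
#'                 a1 = c("A", "G"), a2 = c("C", "T"))
#' genotype_panel(g, v)
#' @export
genotype_panel <- function(dosage, variants, individuals = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "a1", "a2")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(variants),
         " variant records")
  if (anyDuplicated(variants$id))
    stop("variant ids are not unique")
  if (any(variants$pos < 0))
    stop("variant positions must be non-negative")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && any(bad < 0 | bad > 2))
    stop("dosages must lie in [0, 2]")
  if (is.null(individuals)) {
    individuals <- rownames(dosage) %||% paste0("ind", seq_len(nrow(dosage)))
  }
  if (length(individuals) != nrow(dosage) || anyDuplicated(individuals))
    stop("individual ids must be unique and match the dosage row count")
  dimnames(dosage) <- list(individuals, variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.numeric(variants$pos)
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "variants\n")
  nmiss <- sum(is.na(x$dosage))
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  cat("  missing dosages:", nmiss,
      sprintf("(%.3f%%)", 100 * nmiss / length(x$dosage)), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a panel to a set of variant ids (order preserved as given)
#' @param panel a `genotype_panel`.
#' @param ids variant ids to keep.
#' @return a `genotype_panel` restricted to `ids`.
#' @export
subset_variants <- function(panel, ids) {
  stopifnot(inherits(panel, "genotype_panel"))
  miss <- setdiff(ids, panel$variants$id)
  if (length(miss))
    stop("unknown variant ids: ", paste(utils::head(miss, 5), collapse = ", "))
  idx <- match(ids, panel$variants$id)
  genotype_panel(panel$dosage[, idx, drop = FALSE],
                 panel$variants[idx, , drop = FALSE],
                 rownames(panel$dosage))
}

#' Per-variant minor allele frequency
#'
#' Computed on non-missing dosages: allele-1 frequency `mean(g)/2`, folded to
#' the minor side.
#'
#' @param panel a `genotype_panel`.
#' @return named numeric vector of MAFs.
#' @export
panel_maf <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  af <- colMeans(panel$dosage, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Per-variant call rate (fraction of non-missing dosages)
#' @param panel a `genotype_panel`.
#' @return named numeric vector in [0, 1].
#' @export
panel_call_rate <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  colMeans(!is.na(panel$dosage))
}
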