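#' GWAS summary statistics table
#'
#' Validates and classes a per-variant effect table: id, chromosome, 1-based
#' position, effect allele `a1` (the allele `beta` counts), other allele
#' `a2`, effect size `beta` (log-odds from a case-control GWAS), standard
#' error `se`, p-value `p`.
#'
#' @param x data.frame with columns id, chrom, pos, a1, a2, beta, se, p.
#' @return a `summary_stats` data.frame.
#' @export
summary_stats <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "a1", "a2", "beta", "se", "p")
  if (!all(req %in% names(x)))
    stop("summary stats need columns ", paste(req, collapse = ", "))
  if (anyDuplicated(x$id)) stop("variant ids must be unique")
  if (any(!is.finite(x$p)) || any(x$p <= 0 | x$p > 1))
    stop("p-values must lie in (0, 1]")
  if (!all(unlist(x[c("a1", "a2")]) %in% c("A", "C", "G", "T")))
    stop("alleles must be single bases A/C/G/T")
  x$chrom <- as.character(x$chrom)
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' A genomic region (1-based, inclusive on both ends)
#' @param chrom chromosome label.
#' @param start,end 1-based bounds, start <= end.
#' @return a `genomic_region` list.
#' @export
genomic_region <- function(chrom, start, end) {
  if (start > end) stop("region start must not exceed end")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_region")
}

#' The APOE region on GRCh37 (chr19:44,400,000-46,500,000)
#'
#' Excluded by default when scoring Alzheimer's disease PRS, because the
#' strong APOE signal and its extended LD would otherwise dominate the score.
#'
#' @return a `genomic_region`.
#' @export
apoe_region <- function() genomic_region("19", 44400000, 46500000)

#' Drop variants inside a genomic region
#'
#' Removes variants whose chromosome matches the region and whose position
#' lies within its inclusive bounds; all other rows pass through in order.
#'
#' @param stats a `summary_stats` object.
#' @param region a `genomic_region`.
#' @return filtered `summary_stats`.
#' @export
exclude_region <- function(stats, region) {
  stopifnot(inherits(stats, "summary_stats"), inherits(region, "genomic_region"))
  drop <- stats$chrom == region$chrom &
    stats$pos >= region$start & stats$pos <= region$end
  out <- stats[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(stats)
  out
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the remaining variant with the
#' smallest GWAS p-value as an index, then discard every remaining variant on
#' the same chromosome within `window_kb` of it whose LD r-squared with the
#' index is at least `r2_max`. Ties on p are broken by smaller genomic
#' position, then id, so the result is deterministic.
#'
#' @param stats a `summary_stats` object (variants must exist in `panel`).
#' @param panel a `genotype_panel` supplying dosages for LD.
#' @param r2_max LD pruning threshold (default 0.1).
#' @param window_kb window in kilobases (default 1000).
#' @return character vector of retained (index) variant ids, in genomic order
#'   of the input table.
#' @export
clump <- function(stats, panel, r2_max = 0.1, window_kb = 1000) {
  stopifnot(inherits(stats, "summary_stats"), inherits(panel, "genotype_panel"))
  if (nrow(stats) == 0L) return(character(0))
  miss <- setdiff(stats$id, panel$variants$id)
  if (length(miss))
    stop("summary-stats variants absent from panel: ",
         paste(utils::head(miss, 5), collapse = ", "))
  ord <- order(stats$p, stats$pos, stats$id)
  window_bp <- window_kb * 1000
  dosage <- panel$dosage[, match(stats$id, panel$variants$id), drop = FALSE]
  r2 <- NULL  # computed lazily: most panels never need the full matrix
  alive <- rep(TRUE, nrow(stats))
  keep <- logical(nrow(stats))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & stats$chrom == stats$chrom[i] &
                    abs(stats$pos - stats$pos[i]) <= window_bp)
    if (!length(near)) next
    if (is.null(r2)) r2 <- ld_matrix(dosage)
    alive[near[r2[i, near] >= r2_max]] <- FALSE
  }
  stats$id[keep]
}

#' Polygenic score as a weighted dosage sum
#'
#' `score_j = sum_i beta_i * dosage_ij` over the weighted variants, counting
#' copies of each stats effect allele. If the panel codes the opposite allele
#' as A1 the dosage is reflected (2 - G). A missing dosage contributes its
#' variant's mean dosage `2 * maf` (mean imputation). Strand-ambiguous
#' allele pairs that cannot be matched (A/T, C/G flips) are an error.
#'
#' @param panel a `genotype_panel`.
#' @param weights named numeric vector, names = variant ids, values = per
#'   effect-allele weights; or a `summary_stats` object (uses beta).
#' @param stats optional `summary_stats` carrying allele codes for
#'   harmonization; when `NULL` the panel's A1 is assumed to be the effect
#'   allele.
#' @return named numeric vector of raw (unstandardized) scores per
#'   individual.
#' @export
prs_score <- function(panel, weights, stats = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (inherits(weights, "summary_stats")) {
    stats <- weights
    weights <- stats::setNames(weights$beta, weights$id)
  }
  ids <- names(weights)
  miss <- setdiff(ids, panel$variants$id)
  if (length(miss))
    stop("weights reference variants absent from the panel: ",
         paste(utils::head(miss, 10), collapse = ", "))
  idx <- match(ids, panel$variants$id)
  g <- panel$dosage[, idx, drop = FALSE]
  if (!is.null(stats)) {
    srow <- match(ids, stats$id)
    if (anyNA(srow)) stop("allele harmonization requires stats rows for all weights")
    pa1 <- panel$variants$a1[idx]; pa2 <- panel$variants$a2[idx]
    sa1 <- stats$a1[srow]; sa2 <- stats$a2[srow]
    same <- pa1 == sa1 & pa2 == sa2
    flipped <- pa1 == sa2 & pa2 == sa1
    bad <- !(same | flipped)
    if (any(bad))
      stop("allele mismatch (possible strand ambiguity) for: ",
           paste(utils::head(ids[bad], 10), collapse = ", "))
    if (any(flipped)) g[, flipped] <- 2 - g[, flipped]
  }
  if (anyNA(g)) {
    cm <- colMeans(g, na.rm = TRUE)   # 2 * allele frequency of effect allele
    nas <- which(is.na(g), arr.ind = TRUE)
    g[nas] <- cm[nas[, 2]]
  }
  drop(g %*% unname(weights))
}

#' P-value-threshold PRS series
#'
#' Builds one PRS model per p-value threshold over a clumped, region-filtered
#' summary-statistics table: clumping (and APOE-region exclusion unless
#' `exclude_apoe = FALSE`) is applied once, then each threshold keeps the
#' clumped variants with GWAS p <= threshold. Variant sets are therefore
#' nested from the loosest to the strictest model. Scores are z-scored over
#' the cohort (raw scores retained).
#'
#' @param stats a `summary_stats` object.
#' @param panel a `genotype_panel`.
#' @param thresholds strictly decreasing p-value cutoffs; the default is the
#'   PRS1-7 ladder 0.05, 5e-3, 5e-4, 5e-5, 5e-6, 5e-7, 5e-8.
#' @param exclude_apoe drop variants in the APOE region before clumping
#'   (default TRUE). Models built with `FALSE` are flagged `apoe_included`
#'   and association scans then omit the APOE allele-count covariates.
#' @param region region to exclude (default [apoe_region()]).
#' @param r2_max,window_kb clumping parameters.
#' @return list of `prs_model` objects (one per threshold), each with label,
#'   threshold, variant ids, weights, raw and standardized scores, and an
#'   `apoe_included` flag. A threshold retaining no variants yields an empty
#'   model with all-zero scores and a warning.
#' @export
threshold_series <- function(stats, panel,
                             thresholds = c(0.05, 5e-3, 5e-4, 5e-5, 5e-6,
                                            5e-7, 5e-8),
                             exclude_apoe = TRUE, region = apoe_region(),
                             r2_max = 0.1, window_kb = 1000) {
  stopifnot(inherits(stats, "summary_stats"))
  if (any(diff(thresholds) >= 0))
    stop("thresholds must be strictly decreasing")
  if (exclude_apoe) stats <- exclude_region(stats, region)
  kept <- clump(stats, panel, r2_max = r2_max, window_kb = window_kb)
  clumped <- stats[match(kept, stats$id), , drop = FALSE]
  lapply(seq_along(thresholds), function(i) {
    thr <- thresholds[i]
    sub <- clumped[clumped$p <= thr, , drop = FALSE]
    label <- paste0("PRS", i)
    if (nrow(sub) == 0L) {
      warning("threshold ", thr, " (", label, ") retains no variants")
      raw <- stats::setNames(rep(0, nrow(panel$dosage)), rownames(panel$dosage))
      std <- raw
    } else {
      w <- stats::setNames(sub$beta, sub$id)
      raw <- prs_score(panel, w, stats = sub)
      std <- if (stats::sd(raw) > 0) standardize(raw) else raw * 0
    }
    structure(list(label = label, threshold = thr, variants = sub$id,
                   weights = stats::setNames(sub$beta, sub$id),
                   raw = raw, score = std,
                   apoe_included = !exclude_apoe),
              class = "prs_model")
  })
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model %s: p <= %g, %d variants, %d individuals%s\n",
              x$label, x$threshold, length(x$variants), length(x$score),
              if (x$apoe_included) " (APOE region included)" else ""))
  invisible(x)
}

#' Build a standalone PRS model from an explicit variant subset
#'
#' Used by the decomposition stage: score a given id/weight set on a panel
#' and z-score over the cohort.
#'
#' @param panel a `genotype_panel`.
#' @param weights named numeric weight vector (ids must be panel variants).
#' @param label model label.
#' @return a `prs_model`.
#' @export
prs_from_weights <- function(panel, weights, label = "PRS") {
  raw <- prs_score(panel, weights)
  std <- if (stats::sd(raw) > 0) standardize(raw) else raw * 0
  structure(list(label = label, threshold = NA_real_,
                 variants = names(weights), weights = weights,
                 raw = raw, score = std, apoe_included = FALSE),
            class = "prs_model")
}
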