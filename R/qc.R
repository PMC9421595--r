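#' Variant QC thresholds
#'
#' Defaults follow the usual chip-QC regime for common-variant analyses:
#' MAF >= 5\%, call rate > 99\%, exact HWE p > 5e-08.
#'
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param call_rate_min call-rate bound (exclusive: retained variants have
#'   call rate strictly greater).
#' @param hwe_p_min HWE exact-test p bound (exclusive).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.05, call_rate_min = 0.99,
                          hwe_p_min = 5e-08) {
  vals <- c(maf_min, call_rate_min, hwe_p_min)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("QC thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min), class = "qc_thresholds")
}

#' Variant-level quality control
#'
#' Retains variants with call rate > `call_rate_min`, MAF >= `maf_min`
#' (computed on non-missing dosages) and exact HWE p > `hwe_p_min`. Each
#' removed variant is reported with the first failing criterion, evaluated in
#' the order call rate, MAF, HWE.
#'
#' @param panel a `genotype_panel`.
#' @param thresholds a `qc_thresholds` object.
#' @return list with `panel` (filtered `genotype_panel`) and `report`
#'   (data.frame: id, call_rate, maf, hwe_p, retained, reason).
#' @export
qc_filter <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ncol(panel$dosage) == 0L) stop("panel has no variants")
  cr <- panel_call_rate(panel)
  maf <- panel_maf(panel)
  hwe <- apply(panel$dosage, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)  # fully missing: fails call rate anyway
    # HWE on hard genotypes; dosages are 0/1/2 by construction
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  })
  reason <- rep(NA_character_, ncol(panel$dosage))
  reason[is.na(reason) & !(cr > thresholds$call_rate_min)] <- "call_rate"
  reason[is.na(reason) & (is.na(maf) | !(maf >= thresholds$maf_min))] <- "maf"
  reason[is.na(reason) & !is.na(hwe) & !(hwe > thresholds$hwe_p_min)] <- "hwe"
  keep <- is.na(reason)
  report <- data.frame(id = panel$variants$id, call_rate = unname(cr),
                       maf = unname(maf), hwe_p = unname(hwe),
                       retained = keep, reason = reason,
                       stringsAsFactors = FALSE)
  filtered <- genotype_panel(panel$dosage[, keep, drop = FALSE],
                             panel$variants[keep, , drop = FALSE],
                             rownames(panel$dosage))
  list(panel = filtered, report = report)
}
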