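#' Pairwise LD as squared dosage correlation
#'
#' Composite LD on unphased dosages: the squared Pearson correlation of the
#' two dosage columns, computed over individuals with both calls present
#' (pairwise complete). This is the quantity LD clumping prunes on.
#'
#' @param panel a `genotype_panel`.
#' @param variant_i,variant_j variant ids.
#' @return r-squared in [0, 1]; symmetric in its arguments.
#' @export
ld_r2 <- function(panel, variant_i, variant_j) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- match(c(variant_i, variant_j), panel$variants$id)
  if (anyNA(idx))
    stop("unknown variant id: ",
         paste(c(variant_i, variant_j)[is.na(idx)], collapse = ", "))
  ld_r2_cols(panel$dosage[, idx[1]], panel$dosage[, idx[2]])
}

# Core on two dosage vectors; written as explicit moment sums so tests can
# cross-check against stats::cor as an independent route.
ld_r2_cols <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2)
    stop("need at least 2 individuals with non-missing dosages for both variants")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  vx <- sum(x * x) - sx * sx / n
  vy <- sum(y * y) - sy * sy / n
  if (vx <= 0 || vy <= 0)
    stop("monomorphic variant: zero dosage variance")
  cov <- sum(x * y) - sx * sy / n
  min(1, cov * cov / (vx * vy))
}

# Full m x m r2 matrix for clumping; mean-imputation-free, pairwise complete.
ld_matrix <- function(dosage) {
  if (anyNA(dosage)) {
    r <- stats::cor(dosage, use = "pairwise.complete.obs")
  } else {
    r <- stats::cor(dosage)
  }
  r[!is.finite(r)] <- 0
  pmin(r * r, 1)
}
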