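#' Genotype principal components
#'
#' PC scores are the left singular vectors, scaled by the singular values, of
#' the column-standardized dosage matrix; missing dosages are mean-imputed
#' per variant before standardization. Monomorphic columns (zero variance)
#' carry no information and are dropped from the decomposition. Sign is fixed
#' by making each component's largest-magnitude variant loading positive, so
#' results are deterministic.
#'
#' @param panel a `genotype_panel`.
#' @param k number of components (default 10); must not exceed the matrix
#'   rank.
#' @return numeric matrix (individuals x k), columns `PC1..PCk`, with
#'   attribute `var_explained` (fraction of total variance per component).
#' @export
compute_pcs <- function(panel, k = 10) {
  stopifnot(inherits(panel, "genotype_panel"))
  x <- panel$dosage
  if (k < 1 || k > min(dim(x)))
    stop("k must lie in [1, min(individuals, variants)]")
  # mean-impute, then z-score columns; drop zero-variance columns
  cm <- colMeans(x, na.rm = TRUE)
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- cm[nas[, 2]]
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  x <- scale(x[, keep, drop = FALSE], center = TRUE, scale = sds[keep])
  sv <- svd(x, nu = k, nv = k)
  if (k > sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1]))
    stop("k exceeds the rank of the standardized dosage matrix")
  signs <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  scores <- sweep(sv$u, 2, sv$d[seq_len(k)] * signs, `*`)
  dimnames(scores) <- list(rownames(panel$dosage), paste0("PC", seq_len(k)))
  attr(scores, "var_explained") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  scores
}
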