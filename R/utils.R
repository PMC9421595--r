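# Internal helpers shared across modules.

#' Derive a stage-specific seed from a root seed
#'
#' Deterministically maps a root seed and a stage label to a 31-bit seed so
#' pipeline stages can be re-run in isolation without sharing an RNG stream.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @return a single integer in [0, 2^31).
#' @keywords internal
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# z-score a vector; error on zero variance unless allow_constant.
standardize <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    stop("cannot standardize a constant vector")
  }
  (x - mean(x)) / s
}

# Per-SD genotype standardization used inside the phenotype models:
# z(G) = (G - 2*maf) / sqrt(2*maf*(1-maf)), with maf computed from the
# non-missing dosages of the column.
scale_dosage <- function(g) {
  maf <- mean(g, na.rm = TRUE) / 2
  maf <- min(maf, 1 - maf)
  denom <- sqrt(2 * maf * (1 - maf))
  if (denom == 0) return(rep(0, length(g)))
  out <- (g - 2 * maf) / denom
  out[is.na(out)] <- 0
  out
}

# MD5 of an arbitrary R object via serialization to a temp file.
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
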