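# Independent oracles used to freeze expected values.

# Exact HWE p by direct enumeration of all heterozygote counts compatible
# with the observed allele counts, probabilities from the multinomial /
# allele-permanence formula written out directly.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    exp(h * log(2) + lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) -
          lgamma(bb + 1) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Independent greedy clumping oracle: naive O(m^2) loop over the p-sorted
# table, recomputing r2 from raw dosages with stats::cor each time.
clump_oracle <- function(stats, panel, r2_max = 0.1, window_kb = 1000) {
  ord <- order(stats$p, stats$pos, stats$id)
  removed <- character(0)
  kept <- character(0)
  for (i in ord) {
    if (stats$id[i] %in% removed) next
    kept <- c(kept, stats$id[i])
    gi <- panel$dosage[, match(stats$id[i], panel$variants$id)]
    for (j in seq_len(nrow(stats))) {
      if (j == i || stats$id[j] %in% c(removed, kept)) next
      if (stats$chrom[j] != stats$chrom[i]) next
      if (abs(stats$pos[j] - stats$pos[i]) > window_kb * 1000) next
      gj <- panel$dosage[, match(stats$id[j], panel$variants$id)]
      r <- suppressWarnings(stats::cor(gi, gj, use = "pairwise.complete.obs"))
      if (is.finite(r) && r^2 >= r2_max) removed <- c(removed, stats$id[j])
    }
  }
  stats$id[stats$id %in% kept]
}

# Closed-form OLS via the normal equations.
ols_oracle <- function(X, y) {
  xtx <- solve(t(X) %*% X)
  beta <- xtx %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  se <- sqrt(diag(xtx) * sum(res^2) / df)
  t <- beta / se
  list(beta = drop(beta), se = se, p = 2 * pt(-abs(drop(t)), df))
}
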