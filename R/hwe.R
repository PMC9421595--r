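#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the number of
#' heterozygotes follows a (generalised) hypergeometric distribution under
#' HWE. The two-sided p-value is the total probability of all heterozygote
#' counts whose probability does not exceed that of the observed count (ties
#' included), the convention used by standard genotype-QC toolchains.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts (homozygous A1,
#'   heterozygous, homozygous A2).
#' @return exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # equilibrium: p near 1
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  if (sum(counts) < 1)
    stop("at least one genotype must be observed")
  n <- sum(counts)
  nA <- 2 * n_AA + n_Aa        # allele-1 count
  nB <- 2 * n_aa + n_Aa
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  if (length(hets) == 1L) return(1)  # monomorphic or single configuration
  logp <- hets * log(2) +
    lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  # tolerance guards float ties in the "no more probable than observed" sum
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}
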