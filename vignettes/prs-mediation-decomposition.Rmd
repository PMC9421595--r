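---
title: "Polygenic scores, amyloid mediation, and the decomposition of a PRS into amyloid-independent and amyloid-dependent variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores, amyloid mediation, and PRS decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

In Alzheimer's disease, amyloid-beta (A&beta;) pathology and tau pathology are
coupled but not interchangeable: part of the genetic risk that raises CSF tau
levels appears to act *through* amyloid accumulation, and part appears to act
on tau metabolism *independently of* amyloid. `prsmed` implements a complete
analysis chain for dissecting this: clumping-and-thresholding polygenic risk
scores (PRS) built from external GWAS summary statistics, covariate-adjusted
association scans of those scores against CSF biomarkers, bootstrap mediation
of the PRS&rarr;tau effect through binary amyloid status, and a leave-one-out
heuristic that splits the PRS's variants into an amyloid-independent subset
and an exclusive amyloid-dependent subset.

Individual-level cohorts of this kind are access-restricted, so the package
ships a synthetic-cohort generator with a *planted* causal architecture.
Every downstream stage can therefore be tested against known ground truth:
the generator decides which variants drive the mediator and which drive the
outcome directly, and the tests check that the pipeline recovers exactly that
split.

# The models

## PRS construction

Given per-variant GWAS effects $\hat\beta_i$ (log-odds, effect allele $A1$)
and a genotype dosage matrix $G \in \{0,1,2\}^{n \times m}$, the raw score is
the weighted allele count

$$ s_j = \sum_{i \in S(p_T)} \hat\beta_i \, G_{ij}, $$

where $S(p_T)$ is the set of LD-clumped variants with GWAS $p \le p_T$.
Clumping is greedy PLINK-style pruning: take the remaining variant with the
smallest $p$ as an index and discard every variant within 1,000 kb on the
same chromosome with $r^2 \ge 0.1$ against it ($r^2$ = squared Pearson
correlation of dosages, pairwise-complete). The threshold ladder
$p_T \in \{0.05, 5\times10^{-3}, \dots, 5\times10^{-8}\}$ yields the nested
PRS1&ndash;PRS7 family. The *APOE* region (chr19:44,400,000&ndash;46,500,000,
GRCh37, inclusive bounds) is excluded by default because its exceptional
effect size and extended LD would dominate the score; models built with the
region included drop the APOE $\varepsilon2/\varepsilon4$ count covariates
instead. Scores entering regressions are z-scored over the cohort so
coefficients are per SD of PRS; missing dosages contribute their variant's
mean dosage $2\,\mathrm{maf}$.

## Association scans

Continuous CSF biomarkers are rank-based inverse-normal transformed (Blom
offset: rank $r$ of $n$ maps to $\Phi^{-1}((r - 3/8)/(n + 1/4))$, average
ranks for ties) and fitted by OLS on the PRS plus covariates (age, sex,
education, MMSE, APOE $\varepsilon4$ and $\varepsilon2$ counts, genotype
PC1&ndash;10). The A&beta;42/40 ratio is bimodal and is used only as a
dichotomous amyloid status: by default a ratio strictly *below* the 0.091
cutoff is pathologic, which is the standard direction for CSF A&beta;42/40;
the opposite comparison is available behind a flag because published cutpoint
descriptions are not always consistent about the inequality's direction.
Dichotomous outcomes use maximum-likelihood logistic regression with Wald
tests; perfect separation is an error rather than a silently divergent fit.
Bonferroni control is applied within each biomarker family, $m$ = number of
PRS models scanned.

## Bootstrap mediation

For exposure $X$ (standardized PRS), binary mediator $M$ (amyloid status) and
outcome $Y$ (INT tau), with covariates $\mathbf{Z}$ throughout:

* $c$: coefficient of $X$ in $Y \sim X + \mathbf{Z}$ (total effect);
* $c'$ and $b$: coefficients of $X$ and $M$ in $Y \sim X + M + \mathbf{Z}$;
* $a$: coefficient of $X$ in the linear-probability model
  $M \sim X + \mathbf{Z}$ (standardized-coefficient presentation across all
  paths; a logistic $a$-path is a diagnostic, not the estimator).

The indirect effect is the difference $c - c'$ and the proportion mediated
$(c - c')/c$. We use the difference-of-coefficients form rather than the
product $a \times b$ because with a binary mediator the "% mediation" summary
is defined directly from $c$ and $c'$. Inference is a nonparametric bootstrap
over individuals (paired rows, default 1,000 resamples): percentile CI for
$c - c'$ and the two-sided fraction-based p-value
$2\min(\widehat{\Pr}(c-c' \le 0), \widehat{\Pr}(c-c' \ge 0))$. The proportion
mediated is withheld (reported `NA`) when $|c| < 10\,\mathrm{SE}(c)$ — the
guard multiplier is configurable — because a ratio over a noisy denominator
is uninterpretable.

## The decomposition heuristic

Given a full PRS of $n$ variants:

1. **Leave-one-out screen.** For each variant $i$, score the PRS from the
   remaining $n-1$ variants and record the p-value of its association with
   amyloid status. Removal of a variant that carries amyloid signal *weakens*
   the association (larger p); removal of a variant irrelevant to amyloid
   leaves it unchanged or slightly *strengthens* it. The strengthened /
   weakened partition is reported but deliberately not used as a hard filter
   — the ranking below already orders the same information.
2. **Ranking.** Sort variants by the leave-one-out p (ascending by default:
   the most amyloid-independent variants first; ties break by variant id so
   the ranking is deterministic). Descending order, exposed as an option,
   targets the amyloid-dependent end first.
3. **Nested profile.** For $k = 1 \dots n$ build the top-$k$ PRS
   (re-standardized per $k$), fit its tau association unadjusted and
   amyloid-adjusted, and run a screening bootstrap mediation (200 resamples
   by default; the n-row profile is the expensive step, and 200 resamples
   give 0.005 granularity on the screening p, ample for an $\alpha = 0.05$
   gate; the final subsets are re-validated at 1,000).
4. **Independence screen.** Candidate amyloid-independent PRSs are the $k$
   with no significant mediation (bootstrap p $\ge \alpha$) that still
   predict tau significantly both with and without amyloid adjustment. The
   *optimal* independent subset minimizes $|\beta_{adj} - \beta_{unadj}|$
   (ties to larger $k$).
5. **Exclusive dependent subset.** The complement of the union of *all*
   candidate sets — variants that belong to no amyloid-independent PRS. Its
   subset-PRS is validated against the mediator and against tau with and
   without adjustment: the expected signature is a strong unadjusted effect
   that collapses on adjustment. Finally both subset-PRSs enter one joint
   model to confirm they carry independent signal.

# The synthetic generator

Genotypes are biallelic dosages drawn haplotype-wise: within an LD block,
each haplotype's latent Gaussian follows an AR(1) with parameter `ld_rho`,
and the allele indicator thresholds the latent at the MAF quantile; two
independent haplotypes per individual guarantee Hardy-Weinberg marginals,
and blocks are independent. Note the realized dosage correlation is the
*phi* coefficient of two thresholded Gaussians and is therefore attenuated
below `ld_rho`, increasingly so at extreme or mismatched MAFs — the pairwise
$r^2$ that clumping consumes is tunable, which is all the pipeline needs.
Blocks are laid out cyclically over chromosomes 1&ndash;22 at 50 kb spacing.
Allele pairs are drawn from non-complementary bases only, so simulated data
never trip the strand-ambiguity error.

Summary statistics mimic a large external case-control GWAS: each variant's
estimate is its true standardized effect plus noise with
$\mathrm{SE} = 1/\sqrt{2\,N\,\mathrm{maf}(1-\mathrm{maf})}$ (default
$N = 50{,}000$), p from the two-sided normal. Phenotypes follow a liability
threshold: dependent-set variants (per-SD effects on standardized dosages
$z(G) = (G - 2\,\mathrm{maf})/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})}$) drive
amyloid liability, dichotomized at the empirical $1-\text{prevalence}$
quantile (default prevalence 0.30); P-tau181 receives `b_med` (default 0.8
SD) times the mediator plus direct effects from the disjoint independent
set; T-tau adds noise to the same latent; NfL, A&beta;1-38 and A&beta;1-40
carry no variant effects and serve as negative controls. A&beta;1-42 is
constructed so that dichotomizing A&beta;42/40 at the configured cutoff
reproduces the mediator exactly — the biomarker dialect round-trips.
Covariate distributions (age U(60,85), sex Bernoulli(0.5), education
U(6,20), MMSE 24&ndash;30, APOE counts from HWE at allele frequencies
0.15/0.08) are deliberately generic placeholders, not estimates of any real
cohort; effects default to 0.1 SD confounding on both mediator and outcome.

What the generator does *not* emulate: realistic human LD maps and allele
frequency spectra, ancestry structure (the PCs it produces capture noise,
not stratification), imputation uncertainty, assay measurement error
structure, and selection into the cohort. Passing recovery tests therefore
demonstrate that the *procedure* is correct and well-calibrated, not that
any particular real-data effect size will replicate.

## Default study conditions

The planted two-path design used by the recovery tests and the acceptance
script: 5,000 individuals, 100 unlinked variants — 10 mediator-path variants
at $w_{dep} = 0.25$ SD, 20 direct-path variants at $w_{ind} = 0.20$ SD, 70
null — prevalence 0.30, $b_{med} = 0.8$, unit noise SDs. The
all-through-the-mediator design strengthens to $w_{dep} = 0.4$,
$b_{med} = 1.2$, $\sigma_y = 0.5$ so the proportion mediated approaches 1
with a total effect comfortably above the reporting guard. Calibration runs
use 500 individuals and 1,000 (scan) / 100 (coverage) replicates. These
sizes were chosen once as representative desk-scale conditions; they keep
the full suite in a few minutes on one CPU.

# Numerical choices and degenerate inputs

* **HWE exact test**: conditional on allele counts, heterozygote-count
  enumeration with the "no more probable than observed" two-sided rule (ties
  included, with a $1+10^{-12}$ relative tolerance against floating-point
  ties); monomorphic tables have a single attainable configuration and give
  p = 1.
* **QC order**: call rate, then MAF, then HWE — each removed variant reports
  the *first* failing criterion. Filtering is idempotent.
* **PCA**: SVD of the column-standardized, mean-imputed dosage matrix;
  zero-variance columns are dropped; signs fixed by the largest-magnitude
  loading, so results are reproducible to the bit.
* **Clumping ties**: equal p breaks by smaller position, then id.
* **Empty threshold models** are emitted with zero scores and a warning, not
  an error, so the PRS1&ndash;7 ladder always has seven entries.
* **Degenerate mediation inputs**: a single-class mediator is an error; a
  near-zero total effect only withholds the proportion, never errors.
* **Determinism**: every stochastic routine takes an explicit seed; the
  pipeline derives per-stage seeds from one root seed so stages can be rerun
  in isolation, and rerunning a config reproduces byte-identical output
  checksums.

# Known limitations

* **Difference-method suppression.** With a composite exposure containing
  both mediator-path and direct-path variants, conditioning on the scalar
  PRS induces a negative correlation between the two genetic components, so
  the difference estimator $c - c'$ can be systematically nonzero even when
  the mediator has no causal effect on the outcome ($b_{med} = 0$). This is
  a property of difference-method mediation with composite exposures, not a
  bug; the null-calibration checks therefore use designs where the artifact
  cannot arise (fully null, or a-path only). Interpret small indirect
  effects from heterogeneous PRSs with care.
* The independence screen inherits the usual multiplicity caveat: the
  optimal subset is selected by the same data that validate it. The planted
  simulations show the selection is accurate under strong effects; near the
  detection boundary the subsets will be noisy.
* The linear-probability $a$-path is a presentation convention; it is not a
  calibrated probability model for rare mediators.
* Person-level QC (sex checks, heterozygosity), imputation, strand flipping
  against a reference, and PRS methods beyond clumping + thresholding are
  out of scope.

# Interface note

The pipeline is driven by `run_pipeline()` and a single YAML config (see
`?read_run_config` for the schema); `inst/cli/prsmed.R` is a thin
command-line wrapper over it with `simulate`, `decompose` and `run-all`
subcommands. The per-stage operations (`qc_filter()`, `clump()`,
`prs_score()`, `assoc_scan()`, `mediate()`, `decompose_prs()`) are exported
R functions — that is the intended programmatic interface, mirroring how
modelling packages expose fitting functions rather than shell verbs.

# A worked example

```{r, eval = FALSE}
library(prsmed)

ids <- sprintf("rs%05d", 1:100)
cfg <- causal_config(dependent_set = ids[1:10], independent_set = ids[11:30])
sc  <- simulate_cohort(5000, 100, cfg, seed = 11)
co  <- add_pcs(sc$cohort, sc$panel, 10)

kept  <- clump(sc$stats, sc$panel)
w     <- setNames(sc$stats$beta, sc$stats$id)[kept]
model <- prs_from_weights(sc$panel, w, "PRS-full")

med <- mediate(model, co$ab_status, inverse_normal_transform(co$ptau181),
               co[, c("age", "sex", "education", "mmse", "apoe4_count",
                      "apoe2_count", paste0("PC", 1:10))],
               n_boot = 1000, seed = 5)
print(med)

dec <- decompose_prs(model, sc$panel, co, seed = 5)
print(dec)
```
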