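# prsmed

Dissecting how polygenic risk for Alzheimer's disease reaches tau pathology:
through amyloid, or around it.

`prsmed` is an R package for analysts working with genotype panels, GWAS
summary statistics and CSF biomarker panels. It implements the full chain
from variant QC to a variant-level causal decomposition:

* **Genotype handling** — dosage/VCF/PLINK-style readers, variant QC (call
  rate, MAF, exact Hardy-Weinberg test), pairwise LD, genotype principal
  components.
* **PRS construction** — greedy LD clumping (r² < 0.1 over 1,000 kb),
  *APOE*-region exclusion (chr19:44.4–46.5 Mb, GRCh37), allele-harmonized
  weighted scoring, and the nested p-value threshold ladder PRS1–PRS7
  (p ≤ 0.05 down to 5e-8).
* **Association scans** — rank-based inverse-normal transformation (Blom),
  covariate-adjusted linear and logistic regressions, amyloid-status
  dichotomization of the Aβ42/40 ratio at 0.091, Bonferroni control,
  stratified analyses (clinical group, APOE-ε4 status).
* **Bootstrap mediation** — difference-of-coefficients mediation of the
  PRS→P-tau181 effect through binary amyloid status: total effect `c`,
  direct effect `c'`, indirect effect `c − c'`, proportion mediated
  `(c − c')/c`, with percentile CIs from 1,000 paired-row resamples.
* **PRS decomposition** — a leave-one-out screen of every variant against
  amyloid status, nested top-k re-scoring with per-model mediation tests,
  selection of the optimal amyloid-**independent** variant subset (tau
  effect unchanged by amyloid adjustment, no significant mediation) and of
  the exclusive amyloid-**dependent** complement (tau effect collapses on
  adjustment).
* **Synthetic cohorts** — a generator with a planted causal architecture
  (block-LD genotypes in HWE, simulated case-control summary statistics, a
  liability-threshold amyloid mediator, mediated tau outcomes, null control
  biomarkers), so every stage is testable against known ground truth.

The central quantity: with exposure X (standardized PRS), mediator M
(binary amyloid status) and outcome Y (INT-transformed CSF P-tau181), all
covariate-adjusted,

    c   from  Y ~ X + Z            (total effect)
    c', b from Y ~ X + M + Z       (direct effect, mediator path)
    a   from  M ~ X + Z            (linear-probability exposure path)

    indirect = c − c'      proportion mediated = (c − c')/c

## Worked example

```r
library(prsmed)

ids <- sprintf("rs%05d", 1:100)
cfg <- causal_config(dependent_set = ids[1:10],    # act on tau via amyloid
                     independent_set = ids[11:30]) # act on tau directly
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
```

```
Bootstrap mediation (difference of coefficients), n = 5000 , bootstraps = 1000
    beta    se p
a  0.143 0.006 0
b  0.234 0.027 0
c  0.550 0.012 0
c' 0.517 0.013 0
indirect (c - c') = 0.033, 95% percentile CI [0.026, 0.042], bootstrap p = 0
proportion mediated = 6.1%
```

One SD of PRS raises P-tau181 by 0.55 SD in total (`c`); 0.033 SD of that is
routed through amyloid status (`c − c'`, CI excluding zero), about 6% —
small here because most planted variants act on tau directly. Decomposing
the same score:

```r
dec <- decompose_prs(model, sc$panel, co, seed = 5)
print(dec)
```

```
PRS decomposition of PRS-full ( 100 variants )
  leave-one-out:  55 strengthened / 45 weakened the mediator association on removal
  independent candidates: 81 nested models; optimal k = 19
  optimal independent subset: 19 variants; exclusive dependent subset: 10 variants
  dependent-subset PRS on outcome: beta 0.120 (p 4.6e-17) -> 0.002 (p 0.89) after mediator adjustment
```

The heuristic recovers the planted architecture: the 19-variant optimal
independent subset is drawn from the 20 planted direct-path variants (none
of the 10 amyloid-path variants leak in), the 10-variant exclusive dependent
subset is exactly the planted amyloid path, and its tau association
collapses from β = 0.12 to 0.002 once amyloid status enters the model —
while the independent subset's coefficient is unchanged by adjustment.

The whole chain can also be driven from one YAML config via
`run_pipeline()` (stage outputs as TSV/JSON plus a checksummed manifest) or
the thin CLI at `inst/cli/prsmed.R`.

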