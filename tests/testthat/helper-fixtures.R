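# Small in-code fixtures.

make_panel <- function(dosage, chrom = NULL, pos = NULL, a1 = NULL,
                       a2 = NULL) {
  m <- ncol(dosage)
  genotype_panel(dosage,
                 data.frame(id = paste0("v", seq_len(m)),
                            chrom = chrom %||% rep("1", m),
                            pos = pos %||% (seq_len(m) * 1000),
                            a1 = a1 %||% rep("A", m),
                            a2 = a2 %||% rep("G", m),
                            stringsAsFactors = FALSE))
}

make_stats <- function(panel, p, beta = NULL) {
  v <- panel$variants
  summary_stats(data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                           a1 = v$a1, a2 = v$a2,
                           beta = beta %||% rep(0.1, nrow(v)),
                           se = rep(0.02, nrow(v)), p = p,
                           stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A fully null causal configuration (no planted effects anywhere).
null_config <- function(...) {
  causal_config(w_dep = 0, w_ind = 0, b_med = 0,
                age_effect_med = 0, sex_effect_med = 0,
                age_effect_out = 0, sex_effect_out = 0, ...)
}

standardize <- function(x) as.vector(scale(x))

basic_covariates <- function(cohort) {
  cohort[, c("age", "sex", "education", "mmse", "apoe4_count", "apoe2_count")]
}
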