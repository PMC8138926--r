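#!/usr/bin/env Rscript
# Cross-tabulations and association tests on the cohort's marker calls:
# H3K27me3 and ATRX against diagnosis group, and the 2x2 association of
# H3K27me3 loss with 1p/19q codeletion among IDH-mutant gliomas (both
# Fisher exact and uncorrected chi-squared are reported side by side).

library(oligotriage)

dir.create("results", showWarnings = FALSE)
cohort <- build_cohort_fixture()

tab_h3 <- crosstab(cohort, "diagnosis_group", "h3k27me3")
tab_atrx <- crosstab(cohort, "diagnosis_group", "atrx")
cat("H3K27me3 by diagnosis group:\n"); print(tab_h3)
cat("\nATRX by diagnosis group:\n"); print(tab_atrx)

idh_mut <- cohort[cohort$diagnosis_group %in%
                    c("OLIGO_CODEL", "ASTRO_IDH_MUT"), ]
m <- crosstab(idh_mut, "diagnosis_group", "h3k27me3")[
  c("OLIGO_CODEL", "ASTRO_IDH_MUT"), c("NL", "NR")]
tests <- list(
  table = as.list(as.data.frame(as.table(m))),
  fisher_p = fisher_exact_2x2(m),
  chi_squared = chi_squared(m)
)
cat("\nOligo vs IDH-mut astro, NL vs NR:\n"); print(m)
cat(sprintf("Fisher exact p = %.3g; chi-squared = %.2f (df %d, p = %.3g)\n",
            tests$fisher_p, tests$chi_squared$statistic,
            tests$chi_squared$df, tests$chi_squared$p))

jsonlite::write_json(tests, "results/association_tests.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
write.table(as.data.frame.matrix(tab_h3), "results/crosstab_h3k27me3.csv",
            sep = ",", col.names = NA, quote = FALSE)
write.table(as.data.frame.matrix(tab_atrx), "results/crosstab_atrx.csv",
            sep = ",", col.names = NA, quote = FALSE)
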