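#!/usr/bin/env Rscript
# Sequencing-assay arithmetic: in-silico PCR of the published IDH1/IDH2
# primer pairs on synthetic templates built to the published 129/293 bp
# amplicon designs, and codon-level naming of every IDH mutation observed
# in the cohort.

library(oligotriage)

dir.create("results", showWarnings = FALSE)
primers <- idh_primer_pairs()
templates <- synthetic_idh_templates()

amplicons <- lapply(names(primers), function(gene) {
  amp <- in_silico_pcr(templates[[gene]], primers[[gene]])
  cat(sprintf("%s: amplicon %d bp (template %d nt, synthetic)\n",
              gene, amp$length, nchar(templates[[gene]])))
  list(gene = gene, length = amp$length, start = amp$start, end = amp$end)
})

# codon changes behind the cohort's mutation labels
codons <- list(
  list("IDH1", 132, "CGT", "CAT"),  # R132H
  list("IDH1", 132, "CGT", "CTT"),  # R132L
  list("IDH1", 132, "CGT", "AGT"),  # R132S
  list("IDH2", 172, "AGG", "AAG"),  # R172K
  list("IDH2", 172, "AGG", "AGT"),  # R172S
  list("IDH2", 172, "AGG", "TGG")   # R172W
)
calls <- lapply(codons, function(x) do.call(name_codon_mutation, x))
cat("\nMutation labels:",
    paste(vapply(calls, `[[`, character(1), "label"), collapse = ", "), "\n")

jsonlite::write_json(
  list(amplicons = amplicons,
       mutations = lapply(calls, unclass)),
  "results/idh_assays.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
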