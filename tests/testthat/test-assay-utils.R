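test_that("reverse complement is an involution and validates its alphabet", {
  expect_equal(dna_revcomp("ACGT"), "ACGT")
  expect_equal(dna_revcomp("AAAC"), "GTTT")
  withr::local_seed(5)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(1:60, 1), replace = TRUE),
               collapse = "")
    expect_equal(dna_revcomp(dna_revcomp(s)), s)
  }
  expect_error(dna_revcomp("ACGU"), "non-ACGT")
})

test_that("amplicon length is |forward| + insert + |reverse| on constructed templates", {
  p <- idh_primer_pairs()$IDH1   # 20 nt forward, 22 nt reverse
  tmpl <- paste0(p$forward, strrep("A", 87), dna_revcomp(p$reverse))
  amp <- in_silico_pcr(tmpl, p)
  expect_equal(amp$length, 129)
  expect_equal(amp$start, 0)
  expect_equal(amp$end, nchar(tmpl))
  expect_equal(amp$sequence, tmpl)

  withr::local_seed(11)
  for (i in 1:10) {
    ins <- sample(0:300, 1)
    t2 <- make_synthetic_template(p, ins, seed = i)
    expect_equal(in_silico_pcr(t2, p)$length,
                 nchar(p$forward) + ins + nchar(p$reverse))
  }
})

test_that("primer binding failures raise distinct errors", {
  p <- primer_pair("CGGTCTTCAGAGAAGCCATT", "GCAAAATCACATTATTGCCAAC")
  no_rev <- paste0(p$forward, strrep("A", 50))
  expect_error(in_silico_pcr(no_rev, p), "reverse primer not found")
  no_fwd <- paste0(strrep("A", 50), dna_revcomp(p$reverse))
  expect_error(in_silico_pcr(no_fwd, p), "forward primer not found")
  multi_fwd <- paste0(p$forward, "AAAA", p$forward, "AAAA",
                      dna_revcomp(p$reverse))
  expect_error(in_silico_pcr(multi_fwd, p), "multiple sites")
  upstream <- paste0(dna_revcomp(p$reverse), strrep("A", 30), p$forward)
  expect_error(in_silico_pcr(upstream, p), "upstream")
  expect_error(primer_pair("ACGT", "ACGTACGTACGTACGT"), "15 nt")
})

test_that("synthetic IDH templates yield the published 129 / 293 bp amplicon sizes", {
  templates <- synthetic_idh_templates()
  primers <- idh_primer_pairs()
  expect_equal(in_silico_pcr(templates$IDH1, primers$IDH1)$length, 129)
  expect_equal(in_silico_pcr(templates$IDH2, primers$IDH2)$length, 293)
  # deterministic for a given seed
  expect_identical(templates, synthetic_idh_templates())
})

test_that("codon mutations are named by standard-genetic-code translation", {
  expect_equal(name_codon_mutation("IDH1", 132, "CGT", "CAT")$label, "R132H")
  expect_equal(name_codon_mutation("IDH2", 172, "AGG", "AAG")$label, "R172K")
  expect_equal(name_codon_mutation("IDH2", 172, "AGG", "TGG")$label, "R172W")
  expect_equal(name_codon_mutation("IDH1", 132, "CGT", "CGT")$label, "wild-type")
  # synonymous change is wild-type at the protein level
  expect_equal(name_codon_mutation("IDH1", 132, "CGT", "CGC")$label, "wild-type")
  # nonsense mutation labels the stop as *
  expect_equal(name_codon_mutation("X", 10, "TGG", "TGA")$label, "W10*")
  expect_error(name_codon_mutation("X", 1, "TAA", "ATG"), "stop codon")
  expect_error(name_codon_mutation("X", 1, "CG", "CAT"), "3-mers")
  expect_error(name_codon_mutation("X", 1, "CGN", "CAT"), "non-ACGT")
})

test_that("mutation naming round-trips a hand-written codon table", {
  # independent mini translation table (standard genetic code)
  known <- c(ATG = "M", TGG = "W", TTT = "F", AAA = "K", GGC = "G",
             CAT = "H", CGT = "R", AGG = "R", GAT = "D", TCA = "S")
  for (codon in names(known)) {
    call <- name_codon_mutation("G", 1, "ATG", codon)
    expect_equal(call$obs_aa, unname(known[codon]))
    if (known[codon] == "M") expect_equal(call$label, "wild-type")
    else expect_equal(call$label, paste0("M1", known[codon]))
  }
})

test_that("FASTA templates read back as plain DNA strings", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">tmpl synthetic", "ACGTACGTAC", "GTACGT"), path)
  expect_equal(read_template_fasta(path), "ACGTACGTACGTACGT")
})
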