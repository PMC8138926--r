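# Sequencing-assay arithmetic: in-silico PCR (exact primer placement and
# amplicon length) and codon-level mutation naming for the IDH1 codon-132
# / IDH2 codon-172 Sanger assays.

check_dna <- function(s, what = "sequence") {
  s <- toupper(as.character(s))
  if (length(s) != 1 || nchar(s) == 0) stop(what, " must be one DNA string")
  if (grepl("[^ACGT]", s)) stop(what, " contains non-ACGT characters")
  s
}

#' Reverse-complement a DNA string
#'
#' @param s DNA string over `{A, C, G, T}`.
#' @return The reverse complement, as a character scalar.
#' @export
dna_revcomp <- function(s) {
  s <- check_dna(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' A validated primer pair
#'
#' Both primers are written 5' to 3' on their own strand; minimum length
#' 15.
#'
#' @param forward,reverse DNA strings.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- check_dna(forward, "forward primer")
  reverse <- check_dna(reverse, "reverse primer")
  if (nchar(forward) < 15 || nchar(reverse) < 15)
    stop("primers must be at least 15 nt")
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

#' Published primer pairs for the IDH1/IDH2 Sanger assays
#'
#' The primer pairs used to amplify a 129 bp fragment spanning IDH1 codon
#' 132 and a 293 bp fragment spanning IDH2 codon 172.
#'
#' @return Named list of two [primer_pair()] objects (`IDH1`, `IDH2`).
#' @export
idh_primer_pairs <- function() {
  list(
    IDH1 = primer_pair("CGGTCTTCAGAGAAGCCATT", "GCAAAATCACATTATTGCCAAC"),
    IDH2 = primer_pair("GCTGCAGTGGGACCACTATT", "TGTGGCCTTGTACTGCAGAG")
  )
}

match_count <- function(pattern, subject) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject)
  list(n = length(m),
       start = if (length(m)) Biostrings::start(m) else integer(0),
       end = if (length(m)) Biostrings::end(m) else integer(0))
}

#' In-silico PCR: exact primer placement and amplicon extraction
#'
#' Binds primers by exact match only: the forward primer must occur
#' exactly once on the plus strand and the reverse-complement of the
#' reverse primer exactly once, downstream of the forward site. The
#' amplicon spans the first base of the forward binding site through the
#' last base of the reverse binding site, so its length includes both
#' primers (the standard amplicon convention).
#'
#' @param template DNA string.
#' @param primers a [primer_pair()].
#' @return Object of class `amplicon`: list with `start`, `end` (0-based
#'   half-open template coordinates), `length` (bases) and `sequence`.
#' @examples
#' p <- primer_pair("CGGTCTTCAGAGAAGCCATT", "GCAAAATCACATTATTGCCAAC")
#' tmpl <- paste0(p$forward, strrep("A", 87), dna_revcomp(p$reverse))
#' in_silico_pcr(tmpl, p)$length  # 129
#' @export
in_silico_pcr <- function(template, primers) {
  template <- check_dna(template, "template")
  if (!inherits(primers, "primer_pair")) stop("primers must be a primer_pair")
  subject <- Biostrings::DNAString(template)
  fwd <- match_count(primers$forward, subject)
  if (fwd$n == 0) stop("forward primer not found on the template")
  if (fwd$n > 1) stop("forward primer binds the template at multiple sites")
  rev_rc <- match_count(dna_revcomp(primers$reverse), subject)
  if (rev_rc$n == 0) stop("reverse primer not found on the template")
  if (rev_rc$n > 1) stop("reverse primer binds the template at multiple sites")
  if (rev_rc$start < fwd$start || rev_rc$end < fwd$end)
    stop("reverse primer site lies upstream of the forward site")
  start0 <- fwd$start - 1L           # 0-based half-open
  end0 <- rev_rc$end
  structure(list(
    start = start0,
    end = end0,
    length = end0 - start0,
    sequence = substr(template, fwd$start, rev_rc$end)
  ), class = "amplicon")
}

#' Random templates matching the published IDH amplicon sizes
#'
#' Builds one synthetic template per assay as forward primer + seeded
#' random insert + reverse-complement of the reverse primer, with insert
#' sizes chosen so the amplicons are 129 bp (IDH1) and 293 bp (IDH2) —
#' the published fragment sizes. These are synthetic stand-ins for the
#' human genomic reference (which is not bundled), exercising the
#' constructed-template length contract of [in_silico_pcr()]; they are
#' not genomic sequence.
#'
#' @param seed integer seed for the random inserts.
#' @return Named list of two DNA strings (`IDH1`, `IDH2`).
#' @export
synthetic_idh_templates <- function(seed = 20210521L) {
  primers <- idh_primer_pairs()
  sizes <- c(IDH1 = 129L, IDH2 = 293L)
  out <- list()
  for (gene in names(primers)) {
    p <- primers[[gene]]
    insert_len <- sizes[[gene]] - nchar(p$forward) - nchar(p$reverse)
    out[[gene]] <- make_synthetic_template(p, insert_len,
                                           seed = derive_seed(seed, match(gene, names(primers))))
  }
  out
}

#' Construct a synthetic PCR template
#'
#' Template = forward primer + random insert + revcomp(reverse primer);
#' inserts are redrawn (up to 100 times) until each primer has exactly
#' one binding site.
#'
#' @param primers a [primer_pair()].
#' @param insert_length bases between the two primer sites (>= 0).
#' @param seed integer seed.
#' @return DNA string.
#' @export
make_synthetic_template <- function(primers, insert_length, seed = 1L) {
  if (!inherits(primers, "primer_pair")) stop("primers must be a primer_pair")
  insert_length <- as.integer(insert_length)
  if (insert_length < 0) stop("insert_length must be >= 0")
  withr::with_seed(as.integer(seed), {
    for (try in 1:100) {
      insert <- paste(sample(c("A", "C", "G", "T"), insert_length,
                             replace = TRUE), collapse = "")
      tmpl <- paste0(primers$forward, insert, dna_revcomp(primers$reverse))
      subject <- Biostrings::DNAString(tmpl)
      if (match_count(primers$forward, subject)$n == 1 &&
          match_count(dna_revcomp(primers$reverse), subject)$n == 1)
        return(tmpl)
    }
  })
  stop("could not build a template with unique primer sites")
}

#' Read the first sequence of a FASTA file as a DNA string
#'
#' @param path FASTA file.
#' @return Character scalar.
#' @export
read_template_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path)
  as.character(set[[1]])
}

#' Name a codon-level mutation (e.g. R132H)
#'
#' Translates the reference and observed codons with the standard genetic
#' code and builds the conventional label `refAA + codon_number + obsAA`
#' (`"*"` for a stop), or `"wild-type"` when the two codons encode the
#' same amino acid.
#'
#' @param gene gene symbol (carried through).
#' @param codon_number codon position in the protein.
#' @param ref_codon,obs_codon 3-mers over `{A, C, G, T}`; the reference
#'   codon must encode a standard amino acid.
#' @return Object of class `mutation_call`: list with `gene`,
#'   `codon_number`, `ref_codon`, `obs_codon`, `ref_aa`, `obs_aa`,
#'   `label`.
#' @examples
#' name_codon_mutation("IDH1", 132, "CGT", "CAT")$label  # "R132H"
#' @export
name_codon_mutation <- function(gene, codon_number, ref_codon, obs_codon) {
  ref_codon <- check_dna(ref_codon, "ref_codon")
  obs_codon <- check_dna(obs_codon, "obs_codon")
  if (nchar(ref_codon) != 3 || nchar(obs_codon) != 3)
    stop("codons must be 3-mers")
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[[ref_codon]])
  obs_aa <- unname(code[[obs_codon]])
  if (ref_aa == "*") stop("reference codon is a stop codon")
  label <- if (ref_aa == obs_aa) "wild-type"
           else paste0(ref_aa, as.integer(codon_number), obs_aa)
  structure(list(gene = gene, codon_number = as.integer(codon_number),
                 ref_codon = ref_codon, obs_codon = obs_codon,
                 ref_aa = ref_aa, obs_aa = obs_aa, label = label),
            class = "mutation_call")
}
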