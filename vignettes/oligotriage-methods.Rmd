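---
title: "Methods: IHC-based glioma triage, from pixels to a decision tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IHC-based glioma triage, from pixels to a decision tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotriage)
```

This vignette is the package's own account of its science: the scoring
models and their assumptions, the parameters that matter, what the
simulators emulate (and what they do not), the numerical choices, and the
reconstruction decisions behind the bundled cohort. Nothing stated here as
an empirical result goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The diagnostic problem

Among adult diffuse gliomas, the IDH-mutant 1p/19q-codeleted
oligodendroglioma is defined molecularly, but three routine immunostains
are strongly informative: nuclear loss (NL) of H3K27me3 is frequent in
IDH1-R132H-mutant codeleted tumors, ATRX loss marks astrocytic lineage
(codeletion and ATRX mutation are mutually exclusive), and the IDH1-R132H
antibody detects the canonical hotspot mutation. The pipeline quantifies
the H3K27me3 stain, binarizes it cohort-wide, checks its association with
codeletion, and folds all three stains into a recursive-partitioning
classifier that flags which cases still need confirmatory 1p/19q testing.

## 2. Intensity scoring and its orientation

Each case is scored on three randomly chosen 20× fields. A field's gray
histogram is split by **Otsu's method** — the threshold $t$ maximizing the
between-class variance $\omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2$
of the classes $\{gray \le t\}$ and $\{gray > t\}$, ties broken toward the
smallest $t$, and a single-bin histogram an explicit error. The field
score is the mean gray of the extracted (foreground) pixels; the case
score is the mean over fields.

The source material never states whether a higher score means more or
less stain. On the brightfield proxy used here, stain is dark, so the
foreground mean *rises* as stain is lost; the two published anchor scores
(a low-score retention outlier at 65, a borderline loss case at 152
adjacent to the retention cluster) are consistent only with this
orientation. The package therefore labels the *higher*-scoring of the two
clusters NL. This is an interpretation, recorded as such.

The cohort-wide NR/NL cut is a k = 2 cut of a 1-D agglomerative
dendrogram (Euclidean distance). The linkage was not published; average
linkage is the default, with complete and Ward linkage exposed as options
for sensitivity checks. No fixed numeric score cut-off was ever published,
so the clustering cut *is* the decision rule — a borderline loss case
adjacent to the retention cluster can legitimately be assigned NR, exactly
as in the published dendrogram.

## 3. Fraction scoring: the 25%/75% rule

The second route counts cells. Nuclei are segmented as connected
components of the thresholded foreground (components under
`min_nucleus_area` = 20 px discarded), each nucleus is classified by the
fraction of its pixels at or below a stain cutoff:

* stained fraction $= 0$ → `NEGATIVE`;
* $0 <$ fraction $\le$ `dot_area_fraction_max` (0.10) → `DOTLIKE_NEGATIVE`;
* otherwise → `STAINED` (diffuse staining).

"Dot-like" staining — a single punctate focus, attributed to the
inactivated X chromosome — counts as loss, as does complete loss. A case
is **positive** when the pooled stained fraction exceeds 25% and
**negative** when the loss fraction exceeds 75%. The two published rules
are complementary only for strict inequalities; the undefined exactly-25%
boundary is resolved as negative (the conservative choice for a rule whose
positive call suppresses further testing). The p53 variant replaces 25%
with 50%. No pixel-level definition of "dot-like" or "diffuse" was
published; the 0.10 area bound operationalizes it and the simulator draws
its dots at 1/16 of the nucleus area, safely inside the bound.

On simulated cases at the default conditions the two routes agree on every
case, mirroring the published observation that manual fraction scoring and
automated quantification were identical in the positive/negative sense;
the test suite asserts this agreement on 100 simulated cases.

## 4. The field-image simulator

The simulator renders what the scoring chain needs and nothing more:
non-overlapping nucleus discs on a near-white background in 8-bit
grayscale. Study conditions (fixed once, used by all tests):

| parameter | default | why |
|---|---|---|
| field size | 128 px square | small 20×-field proxy; keeps a full cohort run fast |
| tumor nuclei / field | 40 | ~25% tissue area, a realistic low-power density |
| internal controls / field | 5 | endothelium/lymphocytes, always stained |
| mean grays (stained / unstained / background) | 120 / 160 / 240 | stain dark; unstained nuclei darker than background |
| noise | Gaussian, sd 8, truncated at ±3 sd | hematoxylin texture; truncation makes per-class pixel bounds exact |
| nucleus radius | 4–7 px | 20× nucleus scale |
| NL / NR stained fraction | 0.05 / 0.85 | well inside the 75%-loss and 25%-positive regions |
| dot-like fraction of unstained nuclei | 0.10 | dot-like cases are a minority of loss nuclei |

The gray levels were chosen analytically so that Otsu's two-class cut
falls between the nuclei and the background for *any* stained fraction
(the stained/unstained contrast, 40 gray levels, is smaller than the
nuclei/background contrast), which is what makes one threshold serve both
the intensity route (foreground = all nuclei) and segmentation. Placement
is rejection sampling with ≥ 2 px clearance; a stuck configuration is
discarded and redrawn a bounded number of times, keeping the draw a pure
function of the seed.

What the simulator does **not** emulate: RGB DAB/hematoxylin color physics
(no color deconvolution), touching or overlapping nuclei, tissue texture,
JPEG re-encoding, or scanner formats. Passing tests therefore demonstrate
that the *chain* is correct under its stated reading of the scoring rules
— not that segmentation or thresholding would survive real whole-slide
images, where tumor-versus-control cell identity is also a manual call.

## 5. FISH calling

Per nucleus, one red (target) + two green (control) signals is the
deleted pattern and two red + two green the disomic pattern. Patterns with
any other signal count (truncation artifacts, polysomy) are excluded from
the denominator — the published criterion is silent on them, and excluding
them is the interpretation least sensitive to artifact rates. An arm is
deleted when the deleted fraction among informative nuclei is **at least
50%** (inclusive, "50% of nuclei or more"); codeletion requires both arms.
The boundary is asserted exactly: 50 deleted of 100 is a deletion call, 49
is not.

## 6. Contingency statistics

Cross-tabulations are exact integer counts. Which of the two named tests
was applied to which table was not published, so both are computed and
reported side by side: the two-sided Fisher exact test under the
"probability ≤ observed" small-sample convention (relative tolerance 1e-7;
the test suite verifies it against full hypergeometric enumeration for all
totals ≤ 40), and the Pearson chi-squared statistic without Yates
continuity correction (a zero expected cell is an error, not a NaN). No
multiple-testing correction is applied, since none was reported.

## 7. The partition model

The classifier is a greedy binary tree over the three two-level stains,
response = codeleted oligodendroglioma vs anything else. The original
software's split criterion and stopping rule are not printed; the package
uses the likelihood-ratio statistic
$G^2 = 2\sum_{\text{children, classes}} O \ln(O/E)$ (expected counts from
the parent's class proportions), minimum child size 5, each predictor at
most once per path, no pruning. This pair was chosen because the published
tree uses each predictor exactly once at depth ≤ 3, which this
criterion reproduces on the fixture: the greedy split order is H3K27me3 →
ATRX → IDH1-R132H. Ties are broken by the fixed predictor order of the
figure legend (H3K27me3, ATRX, IDH1-R132H).

Leaf probabilities are smoothed toward the root prior with a single
pseudo-observation, $(n_c + \pi_c)/(N + 1)$. The published probability
scores (0.9835, 0.9823) came from an unpublished smoothing formula, so
numeric agreement is *reported but never asserted*; the corresponding
leaves here score above 0.9.

`forced_root` deserves a note. The published alternate tree starts at
IDH1-R132H, then ATRX, then H3K27me3. With the reconstructed cohort, the
greedy criterion prefers H3K27me3 over ATRX beneath the R132H-positive
root (G² 44.6 vs 33.3), so forcing the root alone cannot reproduce that
tree. `forced_root` therefore accepts a vector forcing the split variable
*by depth*; with the full spine forced, the R132H-positive / ATRX-retained
node holds 50 cases of which 39 are oligodendrogliomas — the published
stratum that still requires 1p/19q testing. A node where the forced
variable cannot split validly becomes a leaf.

## 8. The cohort fixture: reconstruction, not data

Only marginal counts were published. The fixture fixes the joint
distribution deterministically so that every published count is exact:

* Oligodendrogliomas (45; all codeleted): 40 IDH1-R132H, 1 IDH1-R132L,
  2 IDH2-R172K, 1 R172S, 1 R172W. NL = 36, all within R132H; the five
  non-canonical cases are all NR. ATRX retained = 43.
* The "50 of 69 R132H-positive cases retained ATRX, 39 of them
  oligodendrogliomas" statement forces the R132H oligodendrogliomas to
  split 39 retained / 1 lost and the retained R132H astrocytomas to
  number 11; the single R132S astrocytoma is assigned ATRX-lost.
* Of the two ATRX-lost oligodendrogliomas, the R132H case is NL and the
  R132L case NR (forced by "36 NL, all R132H" + "non-canonical all NR").
* IDH-mutant astrocytomas (30): 4 NL (within R132H), 26 NR; 11 retained.
* IDH-wildtype: 1/16 astrocytomas and 5/54 glioblastomas NL.
* The ATRX status of the NL non-oligodendroglioma cases is not published.
  It is the one degree of freedom that decides whether ATRX or IDH1-R132H
  is the better second split under the NL root, and the published tree
  answers it: assigning the 4 NL IDH-mutant astrocytomas and the 5 NL
  glioblastomas ATRX-lost (the NL IDH-wildtype astrocytoma retained) makes
  ATRX the greedy second split, as published. This assignment is a
  reconstruction constrained by the printed tree structure, not a reported
  fact.
* Ages are drawn uniformly within each group's published range under a
  fixed internal seed (the published group means are not targets — the raw
  ages are unpublished); sex counts match the published table; per-case
  p53 calls were not published and are stored `NA`; 1p/19q status is `NA`
  for glioblastomas, where it was not assessed.

## 9. Sequencing-assay arithmetic

In-silico PCR uses exact primer matching only (the wet assay's mismatch
tolerance is out of scope): the forward primer must bind the plus strand
exactly once and the reverse-complement of the reverse primer exactly once
downstream; the amplicon spans both primer sites, with 0-based half-open
coordinates and lengths that include both primers. The published 129 bp
(IDH1) and 293 bp (IDH2) fragment lengths refer to the human genome, which
is not bundled; the package instead builds *synthetic* templates (forward
primer + seeded random insert + reverse-complemented reverse primer) to
those published designs, and the length contract
$|F| + \text{insert} + |R|$ is what the default tests assert. Mutation
naming translates reference and observed codons with the standard genetic
code (`R132H`, `R172K`, ..., `*` for stop, synonymous changes =
"wild-type").

## 10. Numerical choices and degenerate inputs

* Otsu ties → smallest threshold; single-bin histogram, empty foreground,
  empty nucleus region, zero informative FISH nuclei, identical cohort
  scores, zero expected cells, non-binary predictors, and an exhausted
  disc placement are all explicit errors.
* All randomness flows through seeds; per-field and per-case seeds are
  derived from the run seed with a fixed integer recurrence kept inside
  the 32-bit range, so every pipeline output is byte-reproducible.
* Problem sizes used by the shipped runs: 128-px fields, three fields per
  case, 145-case cohort (≈ 13 s end to end), 100-case recovery experiment
  in the acceptance tests, 1000-histogram Otsu oracle sweep, Fisher
  enumeration up to total 40.

## 11. Known limitations

The simulator's separability makes the 100% label-recovery result a check
of the chain's correctness, not a claim about real slides; stain
deconvolution, nucleus clumping and the manual exclusion of control cells
on real tissue are outside scope. The fixture's joint marker distribution
is a constrained reconstruction (Section 8); analyses that depend on the
published marginals are exact, while analyses sensitive to the
within-group joints (notably deeper tree nodes) reflect the reconstruction
choices documented above. The FISH module scores counts, not images, and
implements no polysomy or ratio-based criteria.

```{r headline, eval = FALSE}
# the numbers this vignette refers to, recomputed:
source("scripts/acceptance.R")  # or: Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
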