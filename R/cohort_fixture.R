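# 145-case cohort fixture reconstructed from published summary counts.
#
# Only marginal counts were published (group sizes, IDH subtype counts,
# per-group H3K27me3/ATRX tallies, and the 50/69 -> 39 ATRX-retained
# IDH1-R132H stratum). The joint marker distribution inside groups is a
# reconstruction chosen so that every published count — and the published
# tree structure — is reproduced exactly; see the methods vignette.

DIAGNOSIS_GROUPS <- c("OLIGO_CODEL", "ASTRO_IDH_MUT", "ASTRO_IDH_WT", "GBM_IDH_WT")
IDH_LEVELS <- c("IDH1_R132H", "IDH1_R132L", "IDH1_R132S",
                "IDH2_R172K", "IDH2_R172S", "IDH2_R172W", "WT")
ATRX_LEVELS <- c("RETAINED", "LOST")
H3_LEVELS <- c("NL", "NR")
P53_LEVELS <- c("POS", "NEG")
SEX_LEVELS <- c("M", "F")

# Published age ranges per diagnosis group (years).
AGE_RANGES <- list(
  OLIGO_CODEL   = c(23L, 72L),
  ASTRO_IDH_MUT = c(25L, 86L),
  ASTRO_IDH_WT  = c(31L, 84L),
  GBM_IDH_WT    = c(28L, 86L)
)

# Published male counts per group (of 45/30/16/54).
SEX_MALE <- c(OLIGO_CODEL = 23L, ASTRO_IDH_MUT = 18L,
              ASTRO_IDH_WT = 8L, GBM_IDH_WT = 29L)

COHORT_FIXTURE_SEED <- 20210521L

#' Build the 145-case glioma cohort fixture
#'
#' Deterministically reconstructs the study cohort from published summary
#' counts: 45 IDH-mutant 1p/19q-codeleted oligodendrogliomas, 30 IDH-mutant
#' astrocytomas, 16 IDH-wildtype astrocytomas and 54 IDH-wildtype
#' glioblastomas, with per-case IDH subtype, ATRX and H3K27me3 calls laid
#' out so that every published cross-tabulation is matched exactly
#' (e.g. 36/45 oligodendrogliomas H3K27me3 nuclear loss, 43/45 ATRX
#' retained, 11/30 IDH-mutant astrocytomas ATRX retained, and 50
#' IDH1-R132H-positive/ATRX-retained cases of which 39 are
#' oligodendrogliomas).
#'
#' Ages are sampled uniformly within each group's published range under a
#' fixed internal seed, so repeated calls are bit-identical. Per-case p53
#' calls were not published and are stored as `NA`.
#'
#' @return A `data.frame` with one row per case and columns `case_id`,
#'   `diagnosis_group`, `idh`, `atrx`, `h3k27me3`, `p53`, `codeleted`
#'   (logical; `NA` for glioblastoma, where 1p/19q status was not reported),
#'   `sex` and `age`.
#' @examples
#' cohort <- build_cohort_fixture()
#' table(cohort$diagnosis_group)
#' @export
build_cohort_fixture <- function() {
  rows <- list()
  blk <- function(n, group, idh, atrx, h3) {
    data.frame(
      diagnosis_group = rep(group, n), idh = rep(idh, n),
      atrx = rep(atrx, n), h3k27me3 = rep(h3, n),
      stringsAsFactors = FALSE
    )
  }

  oligo <- rbind(
    blk(35L, "OLIGO_CODEL", "IDH1_R132H", "RETAINED", "NL"),
    blk(4L,  "OLIGO_CODEL", "IDH1_R132H", "RETAINED", "NR"),
    blk(1L,  "OLIGO_CODEL", "IDH1_R132H", "LOST",     "NL"),
    blk(1L,  "OLIGO_CODEL", "IDH1_R132L", "LOST",     "NR"),
    blk(2L,  "OLIGO_CODEL", "IDH2_R172K", "RETAINED", "NR"),
    blk(1L,  "OLIGO_CODEL", "IDH2_R172S", "RETAINED", "NR"),
    blk(1L,  "OLIGO_CODEL", "IDH2_R172W", "RETAINED", "NR")
  )
  astro_mut <- rbind(
    blk(11L, "ASTRO_IDH_MUT", "IDH1_R132H", "RETAINED", "NR"),
    blk(4L,  "ASTRO_IDH_MUT", "IDH1_R132H", "LOST",     "NL"),
    blk(14L, "ASTRO_IDH_MUT", "IDH1_R132H", "LOST",     "NR"),
    blk(1L,  "ASTRO_IDH_MUT", "IDH1_R132S", "LOST",     "NR")
  )
  astro_wt <- rbind(
    blk(1L,  "ASTRO_IDH_WT", "WT", "RETAINED", "NL"),
    blk(15L, "ASTRO_IDH_WT", "WT", "RETAINED", "NR")
  )
  gbm <- rbind(
    blk(5L,  "GBM_IDH_WT", "WT", "LOST",     "NL"),
    blk(49L, "GBM_IDH_WT", "WT", "RETAINED", "NR")
  )
  cohort <- rbind(oligo, astro_mut, astro_wt, gbm)

  cohort$diagnosis_group <- factor(cohort$diagnosis_group, levels = DIAGNOSIS_GROUPS)
  cohort$idh <- factor(cohort$idh, levels = IDH_LEVELS)
  cohort$atrx <- factor(cohort$atrx, levels = ATRX_LEVELS)
  cohort$h3k27me3 <- factor(cohort$h3k27me3, levels = H3_LEVELS)
  cohort$p53 <- factor(rep(NA_character_, nrow(cohort)), levels = P53_LEVELS)
  cohort$codeleted <- ifelse(
    cohort$diagnosis_group == "OLIGO_CODEL", TRUE,
    ifelse(cohort$diagnosis_group == "GBM_IDH_WT", NA, FALSE)
  )

  sex <- unlist(lapply(DIAGNOSIS_GROUPS, function(g) {
    n <- sum(cohort$diagnosis_group == g)
    rep(SEX_LEVELS, times = c(SEX_MALE[[g]], n - SEX_MALE[[g]]))
  }), use.names = FALSE)
  cohort$sex <- factor(sex, levels = SEX_LEVELS)

  cohort$age <- withr::with_seed(COHORT_FIXTURE_SEED, {
    unlist(lapply(DIAGNOSIS_GROUPS, function(g) {
      n <- sum(cohort$diagnosis_group == g)
      r <- AGE_RANGES[[g]]
      sample(seq(r[1], r[2]), n, replace = TRUE)
    }), use.names = FALSE)
  })

  cohort <- cohort[, c("diagnosis_group", "idh", "atrx", "h3k27me3",
                       "p53", "codeleted", "sex", "age")]
  cohort <- cbind(case_id = sprintf("case_%03d", seq_len(nrow(cohort))),
                  cohort, stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  cohort
}

#' Validate a cohort table
#'
#' Checks the structural invariants every cohort table must satisfy:
#' required columns, consistent codeletion status (codeleted is `TRUE` iff
#' the case is a 1p/19q-codeleted oligodendroglioma and `FALSE` for both
#' astrocytoma groups), IDH wildtype iff IDH-wildtype diagnosis group, and
#' ages within each group's published range.
#'
#' @param cohort a cohort `data.frame` as returned by
#'   [build_cohort_fixture()] or [read_cohort_csv()].
#' @return `cohort`, invisibly; stops on the first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  need <- c("case_id", "diagnosis_group", "idh", "atrx", "h3k27me3",
            "p53", "codeleted", "sex", "age")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(cohort) == 0) stop("cohort has no records")

  oligo <- cohort$diagnosis_group == "OLIGO_CODEL"
  if (!all(cohort$codeleted[oligo] %in% TRUE))
    stop("all oligodendrogliomas must be 1p/19q codeleted")
  astro <- cohort$diagnosis_group %in% c("ASTRO_IDH_MUT", "ASTRO_IDH_WT")
  if (!all(cohort$codeleted[astro] %in% FALSE))
    stop("astrocytoma groups must be 1p/19q intact")
  if (any(cohort$codeleted[!oligo] %in% TRUE))
    stop("codeleted = TRUE outside the oligodendroglioma group")

  wt_group <- cohort$diagnosis_group %in% c("ASTRO_IDH_WT", "GBM_IDH_WT")
  if (!all((cohort$idh == "WT") == wt_group))
    stop("idh must be WT exactly in the IDH-wildtype diagnosis groups")

  for (g in intersect(levels(factor(cohort$diagnosis_group)), names(AGE_RANGES))) {
    a <- cohort$age[cohort$diagnosis_group == g]
    r <- AGE_RANGES[[g]]
    if (length(a) && (any(a < r[1]) || any(a > r[2])))
      stop("ages outside the published range for group ", g)
  }
  invisible(cohort)
}

#' Write / read a cohort table as CSV
#'
#' Plain comma-separated UTF-8 with a header row; booleans are written as
#' `true`/`false` and `NA` as an empty field, so files round-trip through
#' [read_cohort_csv()] with equality.
#'
#' @param cohort cohort `data.frame`.
#' @param path file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the cohort `data.frame` with factor levels
#'   restored.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  out$codeleted <- ifelse(is.na(out$codeleted), "",
                          ifelse(out$codeleted, "true", "false"))
  for (col in names(out)) {
    if (is.factor(out[[col]])) {
      v <- as.character(out[[col]])
      v[is.na(v)] <- ""
      out[[col]] <- v
    }
  }
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = "character")
  cohort <- data.frame(
    case_id = raw$case_id,
    diagnosis_group = factor(raw$diagnosis_group, levels = DIAGNOSIS_GROUPS),
    idh = factor(raw$idh, levels = IDH_LEVELS),
    atrx = factor(raw$atrx, levels = ATRX_LEVELS),
    h3k27me3 = factor(raw$h3k27me3, levels = H3_LEVELS),
    p53 = factor(raw$p53, levels = P53_LEVELS),
    codeleted = ifelse(is.na(raw$codeleted), NA, raw$codeleted == "true"),
    sex = factor(raw$sex, levels = SEX_LEVELS),
    age = as.integer(raw$age),
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort)
  cohort
}

#' Binary marker frame for the partition model
#'
#' Recodes a cohort into the three binary immunostain predictors used by
#' the recursive-partitioning classifier — H3K27me3 (`NL`/`NR`), ATRX
#' (`RETAINED`/`LOST`) and IDH1-R132H immunopositivity (`POS` iff the
#' mutation-specific antibody would stain, i.e. `idh == "IDH1_R132H"`) —
#' plus the response `oligo` (`OLIGO` = IDH-mutant 1p/19q-codeleted
#' oligodendroglioma, `OTHER` otherwise).
#'
#' @param cohort cohort `data.frame`.
#' @return `data.frame` with columns `case_id`, `h3k27me3`, `atrx`,
#'   `idh1_r132h`, `oligo` (all two-level factors except `case_id`).
#' @export
cohort_marker_frame <- function(cohort) {
  validate_cohort(cohort)
  data.frame(
    case_id = cohort$case_id,
    h3k27me3 = factor(as.character(cohort$h3k27me3), levels = H3_LEVELS),
    atrx = factor(as.character(cohort$atrx), levels = ATRX_LEVELS),
    idh1_r132h = factor(ifelse(cohort$idh == "IDH1_R132H", "POS", "NEG"),
                        levels = c("POS", "NEG")),
    oligo = factor(ifelse(cohort$diagnosis_group == "OLIGO_CODEL",
                          "OLIGO", "OTHER"),
                   levels = c("OLIGO", "OTHER")),
    stringsAsFactors = FALSE
  )
}
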