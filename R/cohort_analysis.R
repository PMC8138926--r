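# Cohort-level statistics: cross-tabulations, association tests, and the
# hierarchical clustering that splits intensity scores into NL/NR.

#' Cross-tabulate two case variables
#'
#' @param cohort cohort `data.frame`.
#' @param row_var,col_var column names of `cohort`.
#' @return A base `table` (rows = `row_var` levels, columns = `col_var`
#'   levels, deterministic level order); cases with `NA` in either
#'   variable are dropped.
#' @examples
#' crosstab(build_cohort_fixture(), "diagnosis_group", "h3k27me3")
#' @export
crosstab <- function(cohort, row_var, col_var) {
  if (nrow(cohort) == 0) stop("empty cohort")
  for (v in c(row_var, col_var))
    if (!v %in% names(cohort)) stop("unknown variable: ", v)
  tab <- table(cohort[[row_var]], cohort[[col_var]], useNA = "no")
  names(dimnames(tab)) <- c(row_var, col_var)
  tab
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value under the small-sample convention: the sum, over all
#' tables with the observed margins, of hypergeometric probabilities not
#' exceeding that of the observed table (within relative tolerance 1e-7).
#' Computed via [stats::fisher.test()], which implements exactly this
#' definition.
#'
#' @param table 2x2 matrix of non-negative counts with all margins > 0.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be >= 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be > 0")
  stats::fisher.test(table)$p.value
}

#' Pearson chi-squared test without continuity correction
#'
#' @param table RxC matrix of non-negative counts (R, C >= 2), total > 0;
#'   a zero expected cell is an explicit error.
#' @return List with `statistic` (Pearson sum of (O-E)^2/E), `df`
#'   ((R-1)(C-1)) and `p`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("chi-squared needs at least a 2x2 table")
  if (any(table < 0)) stop("counts must be >= 0")
  if (sum(table) == 0) stop("empty table")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("zero expected cell")
  fit <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(fit$statistic),
       df = unname(fit$parameter),
       p = fit$p.value)
}

#' Hierarchically cluster 1-D case scores
#'
#' Agglomerative clustering on the Euclidean distance between scores
#' (average linkage by default; complete and Ward linkage are exposed for
#' sensitivity checks), cut into `k` clusters. Cutting at `k = 2` yields
#' the NR/NL partition used by [binarize_cohort_scores()].
#'
#' @param scores numeric vector with at least `k` distinct values.
#' @param k number of clusters.
#' @param linkage `"average"`, `"complete"` or `"ward.D2"`.
#' @return List with `hclust` (the [stats::hclust()] dendrogram; merge
#'   heights are non-decreasing for these linkages) and `labels` (integer
#'   cluster labels in input order).
#' @export
hcluster_scores <- function(scores, k = 2L,
                            linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  if (length(scores) < k) stop("fewer scores than clusters")
  if (length(unique(scores)) < k)
    stop("need at least k distinct scores")
  h <- stats::hclust(stats::dist(scores), method = linkage)
  list(hclust = h, labels = unname(stats::cutree(h, k = k)))
}

#' Per-group marker frequency report
#'
#' For each diagnosis group and marker, the number and proportion of
#' cases in each marker state (cases with `NA` for that marker are
#' excluded from the denominator). This is the table behind statements
#' like "H3K27me3 nuclear loss in 36/45 (80%) of oligodendrogliomas".
#'
#' @param cohort cohort `data.frame`.
#' @param markers marker columns to tabulate.
#' @return Long `data.frame` with columns `diagnosis_group`, `marker`,
#'   `state`, `n`, `total`, `proportion`.
#' @export
marker_frequency_report <- function(cohort,
                                    markers = c("h3k27me3", "atrx")) {
  if (nrow(cohort) == 0) stop("empty cohort")
  rows <- list()
  for (g in levels(factor(cohort$diagnosis_group))) {
    sub <- cohort[cohort$diagnosis_group == g, , drop = FALSE]
    for (m in markers) {
      if (!m %in% names(cohort)) stop("unknown marker: ", m)
      v <- sub[[m]]
      total <- sum(!is.na(v))
      for (s in levels(factor(v))) {
        rows[[length(rows) + 1L]] <- data.frame(
          diagnosis_group = g, marker = m, state = s,
          n = sum(v == s, na.rm = TRUE), total = total,
          proportion = if (total > 0) sum(v == s, na.rm = TRUE) / total else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Look up one marker proportion from a frequency report
#'
#' @param report result of [marker_frequency_report()].
#' @param group,marker,state the row to extract.
#' @return List with `n`, `total`, `proportion`.
#' @export
marker_proportion <- function(report, group, marker, state) {
  row <- report[report$diagnosis_group == group & report$marker == marker &
                  report$state == state, , drop = FALSE]
  if (nrow(row) != 1) stop("no unique report row for ", group, "/", marker,
                           "/", state)
  list(n = row$n, total = row$total, proportion = row$proportion)
}
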