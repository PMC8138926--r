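# FISH 1p/19q deletion calling from per-nucleus probe signal counts.
#
# Dual-color probes: target red (1p36 or 19q13), control green (1q25 or
# 19p13). A nucleus with one red and two green signals carries the deleted
# pattern; two red / two green is disomic. All other patterns (truncation
# artifacts, polysomy) are uninformative and excluded from the
# denominator. An arm is deleted when at least 50% of informative nuclei
# show the deleted pattern; 1p/19q codeletion requires both arms deleted.

#' Classify one nucleus's probe signal pattern
#'
#' @param n_red,n_green non-negative signal counts for the target (red)
#'   and control (green) probes; vectorized.
#' @return Character vector: `"DELETED"` for (1 red, 2 green), `"INTACT"`
#'   for (2 red, 2 green), `"UNINFORMATIVE"` otherwise.
#' @examples
#' classify_nucleus_signals(1, 2)  # DELETED
#' @export
classify_nucleus_signals <- function(n_red, n_green) {
  if (any(n_red < 0) || any(n_green < 0)) stop("signal counts must be >= 0")
  ifelse(n_red == 1 & n_green == 2, "DELETED",
         ifelse(n_red == 2 & n_green == 2, "INTACT", "UNINFORMATIVE"))
}

#' Call arm-level deletion from a nucleus table
#'
#' Applies the established criterion: the arm is deleted when 50% or more
#' of informative nuclei display the one-red/two-green pattern. The
#' deleted fraction is `DELETED / (DELETED + INTACT)`; uninformative
#' patterns do not enter the denominator.
#'
#' @param table `data.frame` with columns `probe_set` (a single probe
#'   set), `n_red`, `n_green`, one row per scored nucleus.
#' @return Object of class `fish_deletion_call`: list with `probe_set`,
#'   `n_scored` (informative nuclei), `n_deleted_pattern`,
#'   `fraction_deleted`, `deleted`.
#' @export
call_deletion <- function(table) {
  need <- c("probe_set", "n_red", "n_green")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("FISH table is missing columns: ", paste(missing, collapse = ", "))
  ps <- unique(table$probe_set)
  if (length(ps) != 1)
    stop("table must contain a single probe set, found: ",
         paste(ps, collapse = ", "))
  cls <- classify_nucleus_signals(table$n_red, table$n_green)
  n_del <- sum(cls == "DELETED")
  n_int <- sum(cls == "INTACT")
  if (n_del + n_int == 0) stop("zero informative nuclei")
  frac <- n_del / (n_del + n_int)
  structure(list(
    probe_set = ps,
    n_scored = n_del + n_int,
    n_deleted_pattern = n_del,
    fraction_deleted = frac,
    deleted = frac >= 0.5
  ), class = "fish_deletion_call")
}

#' Combine 1p and 19q calls into a codeletion call
#'
#' 1p/19q codeletion — the molecular hallmark of oligodendroglioma — is
#' called when both arms are deleted.
#'
#' @param call_1p,call_19q [call_deletion()] results for the
#'   `P1_1p36_1q25` and `P19_19q13_19p13` probe sets (in either argument
#'   order, but the two must come from distinct probe sets).
#' @return Logical scalar.
#' @export
call_codeletion <- function(call_1p, call_19q) {
  if (!inherits(call_1p, "fish_deletion_call") ||
      !inherits(call_19q, "fish_deletion_call"))
    stop("both arguments must be fish_deletion_call objects")
  sets <- c(call_1p$probe_set, call_19q$probe_set)
  if (anyDuplicated(sets))
    stop("both calls come from probe set ", sets[1],
         "; need one call per arm")
  if (!setequal(sets, PROBE_SETS))
    stop("calls must cover the 1p and 19q probe sets, got: ",
         paste(sets, collapse = ", "))
  isTRUE(call_1p$deleted) && isTRUE(call_19q$deleted)
}
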