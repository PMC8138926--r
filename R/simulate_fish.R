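# Seeded simulator for per-nucleus FISH signal-count tables.

PROBE_SETS <- c("P1_1p36_1q25", "P19_19q13_19p13")

#' Simulate a per-nucleus FISH signal-count table
#'
#' Emulates scoring ~100 well-defined nuclei under a dual-color probe set
#' (target red / control green): `round(deleted_fraction * n_nuclei)`
#' nuclei carry the deleted pattern (1 red, 2 green) and the rest the
#' disomic pattern (2 red, 2 green); row order is shuffled by the seed.
#'
#' @param deleted_fraction proportion of nuclei with the deleted pattern,
#'   in `[0, 1]`.
#' @param n_nuclei number of nuclei scored (>= 1).
#' @param seed integer seed for the row shuffle.
#' @param probe_set one of `"P1_1p36_1q25"` (1p target) or
#'   `"P19_19q13_19p13"` (19q target).
#' @return `data.frame` with columns `nucleus_id`, `probe_set`, `n_red`,
#'   `n_green`.
#' @examples
#' tab <- simulate_fish_table(0.73, 100, seed = 1)
#' sum(tab$n_red == 1 & tab$n_green == 2)  # 73 by construction
#' @export
simulate_fish_table <- function(deleted_fraction, n_nuclei, seed = 1L,
                                probe_set = PROBE_SETS[1]) {
  if (deleted_fraction < 0 || deleted_fraction > 1)
    stop("deleted_fraction must lie in [0, 1]")
  n_nuclei <- as.integer(n_nuclei)
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  probe_set <- match.arg(probe_set, PROBE_SETS)
  n_del <- as.integer(round(deleted_fraction * n_nuclei))
  withr::with_seed(as.integer(seed), {
    n_red <- sample(rep(c(1L, 2L), times = c(n_del, n_nuclei - n_del)))
  })
  data.frame(
    nucleus_id = sprintf("fish_%03d", seq_len(n_nuclei)),
    probe_set = probe_set,
    n_red = n_red,
    n_green = 2L,
    stringsAsFactors = FALSE
  )
}

#' Write / read a FISH nucleus table as CSV
#'
#' @param table FISH `data.frame` with columns `nucleus_id`, `probe_set`,
#'   `n_red`, `n_green`.
#' @param path file path.
#' @return `write_fish_csv()` returns `path` invisibly; `read_fish_csv()`
#'   the `data.frame`.
#' @export
write_fish_csv <- function(table, path) {
  write.table(table, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fish_csv
#' @export
read_fish_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("nucleus_id", "probe_set", "n_red", "n_green")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("FISH table is missing columns: ", paste(missing, collapse = ", "))
  tab
}
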