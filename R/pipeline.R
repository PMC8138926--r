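# One seeded run of the whole chain: cohort -> simulated fields ->
# intensity + fraction scoring -> NL/NR clustering -> FISH calls ->
# contingency statistics -> partition trees -> summary.

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

score_one_case <- function(case_label, base_params, config, case_seed) {
  fields <- simulate_case_fields(case_label, n_fields = config$n_fields,
                                 base_params = base_params, seed = case_seed)
  field_scores <- vapply(fields, function(f)
    score_field(f$image)$mean_foreground_gray, numeric(1))

  stain_cutoff <- (base_params$mean_stained_gray +
                     base_params$mean_unstained_gray) / 2
  calls <- unlist(lapply(fields, function(f) {
    regions <- segment_nuclei(f$image, min_nucleus_area = config$min_nucleus_area)
    matched <- match_nuclei(regions, f$truth)
    keep <- !is.na(matched$truth_class) &
      matched$truth_class != "CONTROL_POSITIVE"
    vapply(which(keep), function(i)
      classify_nucleus(regions[[i]], f$image, stain_cutoff, config),
      character(1))
  }), use.names = FALSE)
  fraction_call <- fraction_score_case(calls, config)

  list(field_scores = field_scores,
       case_score = mean(field_scores),
       fraction_call = fraction_call)
}

#' Run the full triage pipeline on a cohort
#'
#' Simulates the three fields of every case from its true H3K27me3 label,
#' scores them by both routes (Otsu mean-intensity and nucleus-fraction),
#' binarizes the cohort intensity scores into NR/NL by 2-cluster
#' hierarchical clustering, simulates and calls per-case 1p/19q FISH,
#' cross-tabulates the recovered labels, runs the association tests, fits
#' the default and forced-spine partition trees, and writes every table
#' plus a machine-readable JSON summary under `out_dir`. Every stochastic
#' step derives its seed deterministically from `seed`, so two runs with
#' the same configuration are byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed run seed.
#' @param cohort cohort `data.frame` (default the bundled 145-case
#'   fixture).
#' @param base_params [sim_image_params()] defaults for every field.
#' @param config a [scoring_config()].
#' @param linkage clustering linkage for the NR/NL cut.
#' @param write_images also write every field PNG and ground-truth CSV
#'   under `out_dir/images/` (off by default).
#' @param fish_deleted_fraction,fish_intact_fraction deleted-pattern
#'   nucleus fractions used to simulate FISH tables for codeleted and
#'   intact cases.
#' @return The summary list, invisibly.
#' @export
run_full_pipeline <- function(out_dir, seed = 1L,
                              cohort = build_cohort_fixture(),
                              base_params = sim_image_params(),
                              config = scoring_config(),
                              linkage = "average",
                              write_images = FALSE,
                              fish_deleted_fraction = 0.75,
                              fish_intact_fraction = 0.10) {
  validate_cohort(cohort)
  if (!inherits(config, "scoring_config")) stop("config must be a scoring_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  stage_log("cohort", nrow(cohort), " cases; writing fixture CSV")
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))

  stage_log("simulate+score", "scoring ", config$n_fields,
            " fields per case (seed ", seed, ")")
  scored <- lapply(seq_len(nrow(cohort)), function(i) {
    res <- score_one_case(as.character(cohort$h3k27me3[i]), base_params,
                          config, derive_seed(seed, i))
    if (write_images) {
      img_dir <- file.path(out_dir, "images", cohort$case_id[i])
      dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
      fields <- simulate_case_fields(as.character(cohort$h3k27me3[i]),
                                     n_fields = config$n_fields,
                                     base_params = base_params,
                                     seed = derive_seed(seed, i))
      for (k in seq_along(fields)) {
        write_field_png(fields[[k]]$image,
                        file.path(img_dir, sprintf("field_%d.png", k)))
        write_truth_csv(fields[[k]]$truth,
                        file.path(img_dir, sprintf("field_%d_truth.csv", k)))
      }
    }
    res
  })
  case_scores <- vapply(scored, `[[`, numeric(1), "case_score")
  names(case_scores) <- cohort$case_id
  labels <- binarize_cohort_scores(case_scores, linkage = linkage)
  fraction_labels <- ifelse(
    vapply(scored, `[[`, character(1), "fraction_call") == "POSITIVE",
    "NR", "NL")

  field_mat <- do.call(rbind, lapply(scored, `[[`, "field_scores"))
  scores_df <- data.frame(case_id = cohort$case_id, field_mat,
                          case_score = case_scores,
                          label = as.character(labels),
                          stringsAsFactors = FALSE)
  names(scores_df)[2:(1 + config$n_fields)] <-
    paste0("field_", seq_len(config$n_fields))
  write.table(scores_df, file.path(out_dir, "scores.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)

  label_recovery <- mean(as.character(labels) == as.character(cohort$h3k27me3))
  route_agreement <- mean(fraction_labels == as.character(labels))
  stage_log("cluster", sprintf("label recovery %.1f%%, route agreement %.1f%%",
                               100 * label_recovery, 100 * route_agreement))

  stage_log("fish", "calling 1p/19q on cases with known status")
  fish_known <- !is.na(cohort$codeleted)
  fish_calls <- vapply(which(fish_known), function(i) {
    f <- if (cohort$codeleted[i]) fish_deleted_fraction else fish_intact_fraction
    t1 <- simulate_fish_table(f, 100L, seed = derive_seed(seed, 10000 + i),
                              probe_set = PROBE_SETS[1])
    t19 <- simulate_fish_table(f, 100L, seed = derive_seed(seed, 20000 + i),
                               probe_set = PROBE_SETS[2])
    call_codeletion(call_deletion(t1), call_deletion(t19))
  }, logical(1))
  fish_recovery <- mean(fish_calls == cohort$codeleted[fish_known])

  stage_log("stats", "cross-tabs and association tests on recovered labels")
  recovered <- cohort
  recovered$h3k27me3 <- factor(as.character(labels), levels = H3_LEVELS)
  report_recovered <- marker_frequency_report(recovered)
  write.table(report_recovered, file.path(out_dir, "marker_frequencies.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)

  idh_mut <- recovered[recovered$diagnosis_group %in%
                         c("OLIGO_CODEL", "ASTRO_IDH_MUT"), ]
  tab <- crosstab(idh_mut, "diagnosis_group", "h3k27me3")
  tab22 <- tab[c("OLIGO_CODEL", "ASTRO_IDH_MUT"), c("NL", "NR")]
  tests <- list(
    fisher_p = fisher_exact_2x2(tab22),
    chi_squared = chi_squared(tab22)
  )

  stage_log("tree", "fitting default and forced-spine partition trees")
  markers <- cohort_marker_frame(cohort)
  tree_default <- fit_tree(markers, c("h3k27me3", "atrx", "idh1_r132h"),
                           "oligo")
  tree_forced <- fit_tree(markers, c("h3k27me3", "atrx", "idh1_r132h"),
                          "oligo",
                          forced_root = c("idh1_r132h", "atrx", "h3k27me3"))
  tree_to_json(tree_default, file.path(out_dir, "tree_default.json"))
  tree_to_json(tree_forced, file.path(out_dir, "tree_forced.json"))
  # the R132H-positive / ATRX-retained stratum; read off the forced tree
  # when it grew that node, otherwise (tiny cohorts) by the path query
  stratum <- tryCatch(tree_node(tree_forced, c("POS", "RETAINED")),
                      error = function(e) NULL)
  if (is.null(stratum)) {
    sel <- markers$idh1_r132h == "POS" & markers$atrx == "RETAINED"
    stratum <- list(n = sum(sel),
                    counts = c(OLIGO = sum(sel & markers$oligo == "OLIGO")))
  }

  oligo_nl <- marker_proportion(report_recovered, "OLIGO_CODEL",
                                "h3k27me3", "NL")
  summary <- list(
    seed = seed,
    n_cases = nrow(cohort),
    label_recovery = label_recovery,
    route_agreement = route_agreement,
    fish_recovery = fish_recovery,
    recovered_oligo_h3k27me3_nl = oligo_nl,
    fisher_p_oligo_vs_astro_mut = tests$fisher_p,
    chi_squared = tests$chi_squared,
    default_tree_split_sequence = tree_split_sequence(tree_default),
    forced_stratum = list(n = stratum$n,
                          oligo = unname(stratum$counts["OLIGO"]))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("done", "summary written to ", file.path(out_dir, "summary.json"))
  invisible(summary)
}
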