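# IHC quantification: the two scoring routes applied to each case.
#
# Route 1 (automated): Otsu background/foreground separation on the gray
# histogram, mean gray of the extracted (foreground) pixels per field,
# case score = mean over three fields, and NL/NR binarization of the
# cohort's case scores by 2-cluster hierarchical clustering. On the
# brightfield proxy stain is dark, so a HIGHER case score means LESS
# stain, i.e. nuclear loss.
#
# Route 2 (cell fraction): segment nuclei, classify each as stained /
# dot-like / negative, and apply the 25%/75% rule, counting dot-like
# nuclei as loss.

#' Scoring configuration
#'
#' Thresholds of the fraction-based scoring rules and of nucleus
#' classification. Defaults: a case is positive when more than 25% of
#' tumor nuclei show diffuse staining and negative when more than 75% show
#' loss (the two published rules are complementary for strict
#' inequalities; an exactly-25% stained fraction is called negative); the
#' p53 variant uses a 50% positivity threshold. A nucleus whose stained
#' area is positive but at most `dot_area_fraction_max` of its area is
#' "dot-like" and counted as loss.
#'
#' @param positive_fraction_threshold stained-cell fraction above which a
#'   case is positive (default 0.25).
#' @param negative_loss_threshold loss fraction above which a case is
#'   negative (default 0.75).
#' @param p53_fraction_threshold positivity threshold for the p53 variant
#'   (default 0.50).
#' @param dot_area_fraction_max maximal stained-area fraction of a
#'   dot-like nucleus (default 0.10).
#' @param min_nucleus_area minimal connected-component area kept by
#'   [segment_nuclei()], pixels (default 20).
#' @param n_fields fields scored per case (default 3).
#' @param nucleus_stain_margin gray levels subtracted from the stain
#'   cutoff when classifying nucleus pixels (default 0).
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(positive_fraction_threshold = 0.25,
                           negative_loss_threshold = 0.75,
                           p53_fraction_threshold = 0.50,
                           dot_area_fraction_max = 0.10,
                           min_nucleus_area = 20L,
                           n_fields = 3L,
                           nucleus_stain_margin = 0) {
  if (positive_fraction_threshold <= 0 || positive_fraction_threshold >= 1)
    stop("positive_fraction_threshold must lie in (0, 1)")
  if (negative_loss_threshold <= 0 || negative_loss_threshold >= 1)
    stop("negative_loss_threshold must lie in (0, 1)")
  if (n_fields < 1) stop("n_fields must be >= 1")
  structure(list(
    positive_fraction_threshold = positive_fraction_threshold,
    negative_loss_threshold = negative_loss_threshold,
    p53_fraction_threshold = p53_fraction_threshold,
    dot_area_fraction_max = dot_area_fraction_max,
    min_nucleus_area = as.integer(min_nucleus_area),
    n_fields = as.integer(n_fields),
    nucleus_stain_margin = nucleus_stain_margin
  ), class = "scoring_config")
}

#' Otsu's global threshold from a 256-bin gray histogram
#'
#' Returns the threshold `t` in `[0, 255]` maximizing the between-class
#' variance `w0(t) w1(t) (mu0(t) - mu1(t))^2` of the two classes
#' `gray <= t` and `gray > t`; ties are broken by the smallest `t`. A
#' degenerate histogram (fewer than two occupied bins) is an explicit
#' error, never a silent threshold.
#'
#' @param gray_histogram numeric vector of 256 non-negative counts for
#'   gray levels 0..255.
#' @return Integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(gray_histogram) {
  if (length(gray_histogram) != 256)
    stop("gray_histogram must have 256 bins (gray 0..255)")
  if (any(gray_histogram < 0)) stop("histogram counts must be >= 0")
  total <- sum(gray_histogram)
  if (total <= 0) stop("histogram is empty")
  if (sum(gray_histogram > 0) < 2)
    stop("degenerate histogram: a single occupied gray level has no Otsu threshold")
  p <- gray_histogram / total
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_total <- mu[256]
  w1 <- 1 - w0
  sigma_b <- (mu_total * w0 - mu)^2 / (w0 * w1)
  sigma_b[!(w0 > 0 & w1 > 0)] <- -Inf
  as.integer(which.max(sigma_b) - 1L)  # which.max takes the smallest tie
}

image_histogram <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  v <- as.integer(image)
  if (any(is.na(v)) || any(v < 0) || any(v > 255))
    stop("image must contain integer gray values in [0, 255]")
  tabulate(v + 1L, nbins = 256L)
}

#' Score one field: mean intensity of the extracted pixels
#'
#' Separates foreground from background with Otsu's global threshold on
#' the field's gray histogram and records the average intensity of the
#' extracted (foreground, `gray <= t`) pixels — tissue and nuclei are
#' darker than the near-white background, so the foreground is the nucleus
#' population.
#'
#' @param image integer gray matrix (0-255).
#' @return Object of class `ihc_field_score`: a list with
#'   `mean_foreground_gray`, `n_foreground_pixels`, `otsu_threshold`.
#' @export
score_field <- function(image) {
  h <- image_histogram(image)
  t <- otsu_threshold(h)
  fg <- image <= t
  n_fg <- sum(fg)
  if (n_fg == 0) stop("empty foreground")
  structure(list(
    mean_foreground_gray = mean(image[fg]),
    n_foreground_pixels = n_fg,
    otsu_threshold = t
  ), class = "ihc_field_score")
}

#' Score one case: mean of the per-field scores
#'
#' The case score is the arithmetic mean of the field scores of the
#' (default three) randomly chosen areas. The NL/NR label is left `UNSET`
#' here; it is assigned cohort-wide by [binarize_cohort_scores()].
#'
#' @param fields either a list of field images (each scored with
#'   [score_field()]) or a numeric vector of precomputed per-field scores.
#' @return Object of class `ihc_case_score`: list with `field_scores`,
#'   `case_score`, `label` (`"UNSET"`).
#' @examples
#' score_case(c(100, 110, 120))$case_score  # 110
#' @export
score_case <- function(fields) {
  if (is.numeric(fields)) {
    field_scores <- as.numeric(fields)
  } else if (is.list(fields)) {
    if (length(fields) == 0) stop("need at least one field")
    field_scores <- vapply(fields, function(f) {
      img <- if (is.list(f) && !is.null(f$image)) f$image else f
      score_field(img)$mean_foreground_gray
    }, numeric(1))
  } else stop("fields must be a list of images or a numeric vector of scores")
  if (length(field_scores) < 1) stop("need at least one field")
  structure(list(
    field_scores = field_scores,
    case_score = mean(field_scores),
    label = "UNSET"
  ), class = "ihc_case_score")
}

#' Segment nuclei as connected foreground components
#'
#' Thresholds the field (by default at its Otsu threshold — unstained
#' nuclei are darker than the background, so with the package's standard
#' imaging conditions the Otsu foreground contains every nucleus), labels
#' 4-connected components and discards components smaller than
#' `min_nucleus_area`.
#'
#' @param image integer gray matrix.
#' @param min_nucleus_area minimal region area in pixels.
#' @param threshold optional gray threshold overriding Otsu.
#' @return List of regions; each region is a list with `pixels` (integer
#'   indices into the image), `area`, and `center` (0-based `c(row, col)`
#'   centroid). Zero regions is an error.
#' @export
segment_nuclei <- function(image, min_nucleus_area = 20L, threshold = NULL) {
  if (is.null(threshold)) threshold <- otsu_threshold(image_histogram(image))
  mask <- image <= threshold
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  regions <- list()
  if (n > 0) {
    idx_by_label <- split(seq_along(labels), as.vector(labels))
    idx_by_label[["0"]] <- NULL
    for (px in idx_by_label) {
      if (length(px) < min_nucleus_area) next
      rows <- (px - 1L) %% nrow(image)        # 0-based
      cols <- (px - 1L) %/% nrow(image)
      regions[[length(regions) + 1L]] <- list(
        pixels = px,
        area = length(px),
        center = c(row = mean(rows), col = mean(cols))
      )
    }
  }
  if (length(regions) == 0) stop("no nucleus regions found")
  regions
}

#' Match segmented regions to simulator ground truth
#'
#' Assigns each region the ground-truth nucleus whose center is nearest to
#' the region centroid (at most `max_dist` pixels away; farther regions
#' get `NA`). Used to audit segmentation and to exclude internal-control
#' cells from fraction scoring.
#'
#' @param regions result of [segment_nuclei()].
#' @param truth ground-truth `data.frame` from [simulate_field()].
#' @param max_dist maximal centroid-to-truth distance in pixels.
#' @return `data.frame` with one row per region: `region`, `nucleus_id`,
#'   `truth_class`, `dist`.
#' @export
match_nuclei <- function(regions, truth, max_dist = 2) {
  res <- lapply(seq_along(regions), function(i) {
    ctr <- regions[[i]]$center
    d <- sqrt((truth$row - ctr["row"])^2 + (truth$col - ctr["col"])^2)
    j <- which.min(d)
    if (d[j] <= max_dist)
      data.frame(region = i, nucleus_id = truth$nucleus_id[j],
                 truth_class = as.character(truth$truth_class[j]),
                 dist = d[j], stringsAsFactors = FALSE)
    else
      data.frame(region = i, nucleus_id = NA_character_,
                 truth_class = NA_character_, dist = d[j],
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify one nucleus as stained, dot-like or negative
#'
#' Computes the fraction of the region's pixels at or below the stain
#' cutoff. The call is `STAINED` when that fraction exceeds
#' `dot_area_fraction_max` (diffuse staining), `DOTLIKE_NEGATIVE` when it
#' is positive but confined to at most a dot's area, and `NEGATIVE` when
#' it is zero. Complete loss and dot-like staining are both counted as
#' nuclear loss downstream.
#'
#' @param region a region from [segment_nuclei()], or an integer vector of
#'   pixel indices.
#' @param image integer gray matrix the region indexes into.
#' @param stain_cutoff gray level at or below which a pixel counts as
#'   stained; on simulated fields the midpoint of the stained and
#'   unstained class means, on arbitrary images the field's Otsu threshold
#'   re-applied within the nucleus mask.
#' @param config a [scoring_config()].
#' @return Character scalar: `"STAINED"`, `"DOTLIKE_NEGATIVE"` or
#'   `"NEGATIVE"`.
#' @export
classify_nucleus <- function(region, image, stain_cutoff,
                             config = scoring_config()) {
  px <- if (is.list(region)) region$pixels else region
  if (length(px) == 0) stop("empty nucleus region")
  gray <- image[px]
  cutoff <- stain_cutoff - config$nucleus_stain_margin
  stained_area_fraction <- mean(gray <= cutoff)
  if (stained_area_fraction == 0) return("NEGATIVE")
  if (stained_area_fraction <= config$dot_area_fraction_max)
    return("DOTLIKE_NEGATIVE")
  "STAINED"
}

#' Fraction-based case scoring (25%/75% rule)
#'
#' Pools per-nucleus calls over all fields of a case and applies the
#' published rule: positive when more than 25% of tumor nuclei show
#' diffuse staining, negative when more than 75% show loss (complete or
#' dot-like); an exactly-25% stained fraction is negative. The p53 variant
#' (`marker = "p53"`) uses the 50% positivity threshold instead.
#' Internal-control cells must be excluded by the caller (the simulator
#' marks them; on real slides this is a manual step).
#'
#' @param calls character vector (or list of per-field vectors) of
#'   nucleus calls from [classify_nucleus()].
#' @param config a [scoring_config()].
#' @param marker `"default"` (25% rule) or `"p53"` (50% rule).
#' @return `"POSITIVE"` or `"NEGATIVE"`.
#' @examples
#' fraction_score_case(rep(c("STAINED", "NEGATIVE"), c(30, 70)))  # POSITIVE
#' @export
fraction_score_case <- function(calls, config = scoring_config(),
                                marker = c("default", "p53")) {
  marker <- match.arg(marker)
  calls <- unlist(calls, use.names = FALSE)
  if (length(calls) == 0) stop("no tumor nuclei to score")
  bad <- setdiff(unique(calls), c("STAINED", "DOTLIKE_NEGATIVE", "NEGATIVE"))
  if (length(bad)) stop("unknown nucleus calls: ", paste(bad, collapse = ", "))
  stained_fraction <- mean(calls == "STAINED")
  thr <- if (marker == "p53") config$p53_fraction_threshold
         else config$positive_fraction_threshold
  if (stained_fraction > thr) "POSITIVE" else "NEGATIVE"
}

#' Binarize cohort intensity scores into NR / NL
#'
#' Cuts the cohort's case scores into two groups by 1-D agglomerative
#' hierarchical clustering ([hcluster_scores()], average linkage by
#' default) and labels the cluster with the higher mean score `NL`
#' (nuclear loss): on the brightfield proxy less stain means brighter
#' foreground, hence a higher mean intensity score.
#'
#' @param case_scores numeric vector of case scores (optionally named);
#'   needs at least two distinct values.
#' @param linkage linkage passed to [hcluster_scores()].
#' @return Factor with levels `NR`, `NL`, one per case, preserving names.
#' @examples
#' binarize_cohort_scores(c(88, 92, 95, 180, 185))
#' @export
binarize_cohort_scores <- function(case_scores, linkage = "average") {
  if (length(case_scores) < 2) stop("need at least two cases")
  if (length(unique(case_scores)) < 2)
    stop("all case scores identical; no NR/NL cut exists")
  cl <- hcluster_scores(case_scores, k = 2, linkage = linkage)
  means <- tapply(case_scores, cl$labels, mean)
  nl_cluster <- as.integer(names(means)[which.max(means)])
  out <- factor(ifelse(cl$labels == nl_cluster, "NL", "NR"),
                levels = c("NR", "NL"))
  names(out) <- names(case_scores)
  out
}
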