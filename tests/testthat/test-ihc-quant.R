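test_that("Otsu threshold matches the brute-force all-thresholds oracle", {
  withr::local_seed(42)
  for (i in 1:300) {
    h <- numeric(256)
    occupied <- sample(0:255, sample(2:30, 1))
    h[occupied + 1] <- sample(1:50, length(occupied), replace = TRUE)
    expect_identical(otsu_threshold(h), oracle_otsu(h))
  }
})

test_that("Otsu handles flat-variance ties by the smallest threshold", {
  h <- numeric(256); h[1] <- 50; h[256] <- 50  # grays 0 and 255
  expect_identical(otsu_threshold(h), 0L)
  curve <- oracle_otsu_variance_curve(h)
  expect_true(all(abs(curve[1:255] - curve[1]) < 1e-9))  # flat on t = 0..254

  h3 <- numeric(256); h3[81] <- 30; h3[91] <- 30; h3[201] <- 40
  t <- otsu_threshold(h3)
  expect_identical(t, oracle_otsu(h3))
  expect_true(t >= 90 && t < 200)  # separates {80, 90} from {200}
})

test_that("degenerate histograms raise an explicit error", {
  h <- numeric(256); h[11] <- 100
  expect_error(otsu_threshold(h), "degenerate")
  expect_error(otsu_threshold(numeric(256)), "empty")
  expect_error(otsu_threshold(numeric(10)), "256")
  # an all-background (constant) image propagates the degenerate error
  expect_error(score_field(matrix(240L, 32, 32)), "degenerate")
})

test_that("field score extracts the dark foreground", {
  img <- disc_image(size = 61, radius = 10, gray = 90, background = 240)
  s <- score_field(img)
  expect_s3_class(s, "ihc_field_score")
  expect_lt(abs(s$mean_foreground_gray - 90), 1e-9)
  expect_equal(s$n_foreground_pixels, sum(img == 90))
  expect_true(s$otsu_threshold >= 90 && s$otsu_threshold < 240)
})

test_that("an NL field scores higher than an NR field (less stain, brighter foreground)", {
  nr <- simulate_field(sim_image_params(stained_fraction = 0.85, seed = 31))
  nl <- simulate_field(sim_image_params(stained_fraction = 0.05, seed = 31))
  expect_gt(score_field(nl$image)$mean_foreground_gray,
            score_field(nr$image)$mean_foreground_gray)
})

test_that("case score is the field mean, order-invariant, label unset", {
  cs <- score_case(c(100, 110, 120))
  expect_equal(cs$case_score, 110)
  expect_equal(cs$label, "UNSET")
  expect_equal(score_case(152)$case_score, 152)
  expect_equal(score_case(c(120, 100, 110))$case_score, cs$case_score)
  expect_error(score_case(list()), "at least one")

  p <- sim_image_params(seed = 17)
  fields <- simulate_case_fields("NR", 3, base_params = p, seed = 17)
  cs_sim <- score_case(lapply(fields, `[[`, "image"))
  expect_lt(abs(cs_sim$case_score - p$mean_stained_gray), 3 * p$noise_sd)
})

test_that("segmentation recovers every simulated nucleus with centroid accuracy", {
  f <- simulate_field(sim_image_params(seed = 23))
  regions <- segment_nuclei(f$image)
  expect_length(regions, nrow(f$truth))
  matched <- match_nuclei(regions, f$truth, max_dist = 2)
  expect_false(any(is.na(matched$truth_class)))
  expect_true(all(matched$dist <= 2))
  expect_equal(anyDuplicated(matched$nucleus_id), 0L)
})

test_that("segmentation filters sub-minimum regions and rejects empty masks", {
  img <- disc_image(size = 61, radius = 8, gray = 120, background = 240)
  img[3, 3] <- 120L; img[3, 4] <- 120L  # 2-px salt speck, below min area
  regions <- segment_nuclei(img, min_nucleus_area = 20, threshold = 180)
  expect_length(regions, 1)
  expect_gt(regions[[1]]$area, 20)
  expect_error(segment_nuclei(matrix(c(240L, 239L), 16, 16),
                              min_nucleus_area = 20, threshold = 100),
               "no nucleus regions")
})

test_that("nucleus classification separates stained, dot-like and negative", {
  stained <- disc_image(radius = 12, gray = 120)
  regions <- segment_nuclei(stained, threshold = 180)
  expect_equal(classify_nucleus(regions[[1]], stained, stain_cutoff = 140),
               "STAINED")

  # one dark dot covering ~5% of the nucleus area
  dotted <- disc_image(radius = 12, gray = 160, dot_radius = 2.7, dot_gray = 120)
  regions <- segment_nuclei(dotted, threshold = 180)
  expect_equal(classify_nucleus(regions[[1]], dotted, stain_cutoff = 140),
               "DOTLIKE_NEGATIVE")

  negative <- disc_image(radius = 12, gray = 160)
  regions <- segment_nuclei(negative, threshold = 180)
  expect_equal(classify_nucleus(regions[[1]], negative, stain_cutoff = 140),
               "NEGATIVE")
  expect_error(classify_nucleus(integer(0), negative, 140), "empty")
})

test_that("fraction scoring applies the 25%/75% rule with a negative tie-break", {
  calls <- function(n_stained, n_total)
    rep(c("STAINED", "NEGATIVE"), c(n_stained, n_total - n_stained))
  expect_equal(fraction_score_case(calls(30, 100)), "POSITIVE")
  expect_equal(fraction_score_case(calls(20, 100)), "NEGATIVE")
  expect_equal(fraction_score_case(calls(25, 100)), "NEGATIVE")  # boundary
  # dot-like counts as loss
  mixed <- c(rep("STAINED", 20), rep("DOTLIKE_NEGATIVE", 60), rep("NEGATIVE", 20))
  expect_equal(fraction_score_case(mixed), "NEGATIVE")
  # p53 variant: 50% threshold
  expect_equal(fraction_score_case(calls(40, 100), marker = "p53"), "NEGATIVE")
  expect_equal(fraction_score_case(calls(60, 100), marker = "p53"), "POSITIVE")
  expect_equal(fraction_score_case(calls(40, 100)), "POSITIVE")
  expect_error(fraction_score_case(character(0)), "no tumor nuclei")
  expect_error(fraction_score_case("WEIRD"), "unknown")
})

test_that("cohort score binarization finds the high-score (NL) cluster", {
  lab <- binarize_cohort_scores(c(a = 88, b = 92, c = 95, d = 180, e = 185))
  expect_equal(as.character(lab), c("NR", "NR", "NR", "NL", "NL"))
  expect_equal(names(lab), c("a", "b", "c", "d", "e"))
  lab2 <- binarize_cohort_scores(c(65, 200))
  expect_equal(as.character(lab2), c("NR", "NL"))
  expect_error(binarize_cohort_scores(rep(150, 5)), "identical")
  expect_error(binarize_cohort_scores(150), "two cases")
})

test_that("scoring_config validates its thresholds", {
  expect_error(scoring_config(positive_fraction_threshold = 0), "\\(0, 1\\)")
  expect_error(scoring_config(n_fields = 0), ">= 1")
  cfg <- scoring_config()
  expect_equal(cfg$negative_loss_threshold, 1 - cfg$positive_fraction_threshold)
})
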