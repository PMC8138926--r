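test_that("field simulation is seed-deterministic and respects class counts", {
  p <- sim_image_params(seed = 11)
  f1 <- simulate_field(p)
  f2 <- simulate_field(p)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$truth, f2$truth)

  tumor <- f1$truth[f1$truth$truth_class != "CONTROL_POSITIVE", ]
  expect_equal(sum(tumor$truth_class == "TUMOR_STAINED"),
               round(0.85 * p$n_tumor_nuclei))
  expect_equal(nrow(tumor), p$n_tumor_nuclei)
  expect_equal(sum(f1$truth$truth_class == "CONTROL_POSITIVE"),
               p$n_control_cells)

  # nuclei stay clear of the image border
  expect_true(all(f1$truth$row - f1$truth$radius >= 0))
  expect_true(all(f1$truth$row + f1$truth$radius <= p$image_size - 1))
  expect_true(all(f1$truth$col - f1$truth$radius >= 0))
  expect_true(all(f1$truth$col + f1$truth$radius <= p$image_size - 1))
})

test_that("fully stained and fully unstained boundary fields audit against ground truth", {
  p1 <- sim_image_params(stained_fraction = 1, seed = 5)
  f1 <- simulate_field(p1)
  tumor <- f1$truth$truth_class[f1$truth$truth_class != "CONTROL_POSITIVE"]
  expect_true(all(tumor == "TUMOR_STAINED"))

  # no stain at all: with noise truncated at 3 sd, no tumor pixel may fall
  # below the unstained class mean minus 3 sd
  p0 <- sim_image_params(stained_fraction = 0, dotlike_fraction = 0, seed = 5)
  f0 <- simulate_field(p0)
  tumor_rows <- f0$truth[f0$truth$truth_class != "CONTROL_POSITIVE", ]
  in_tumor <- matrix(FALSE, p0$image_size, p0$image_size)
  for (i in seq_len(nrow(tumor_rows))) {
    cr <- tumor_rows$row[i] + 1; cc <- tumor_rows$col[i] + 1
    r <- tumor_rows$radius[i]
    for (dr in -r:r) for (dc in -r:r)
      if (dr^2 + dc^2 <= r^2) in_tumor[cr + dr, cc + dc] <- TRUE
  }
  expect_true(all(f0$image[in_tumor] >=
                    p0$mean_unstained_gray - 3 * p0$noise_sd))
})

test_that("rendered per-nucleus mean gray matches its class mean", {
  p <- sim_image_params(stained_fraction = 0.5, dotlike_fraction = 0, seed = 9)
  f <- simulate_field(p)
  class_mean <- c(TUMOR_STAINED = p$mean_stained_gray,
                  TUMOR_NEGATIVE = p$mean_unstained_gray,
                  CONTROL_POSITIVE = p$mean_stained_gray)
  for (i in seq_len(nrow(f$truth))) {
    cr <- f$truth$row[i] + 1; cc <- f$truth$col[i] + 1
    r <- f$truth$radius[i]
    px <- c()
    for (dr in -r:r) for (dc in -r:r)
      if (dr^2 + dc^2 <= r^2) px <- c(px, f$image[cr + dr, cc + dc])
    expect_lt(abs(mean(px) - class_mean[[as.character(f$truth$truth_class[i])]]),
              3 * p$noise_sd)
  }
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_image_params(mean_stained_gray = 200,
                                mean_unstained_gray = 160),
               "stained < unstained")
  expect_error(sim_image_params(stained_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_image_params(n_tumor_nuclei = 0), ">= 1")
  # too many nuclei to place without overlap
  expect_error(simulate_field(sim_image_params(image_size = 48,
                                               n_tumor_nuclei = 60,
                                               seed = 1)),
               "place")
})

test_that("case fields honor the NL/NR staining regimes", {
  tumor_stained_fraction <- function(field) {
    tumor <- field$truth[field$truth$truth_class != "CONTROL_POSITIVE", ]
    mean(tumor$truth_class == "TUMOR_STAINED")
  }
  nl <- simulate_case_fields("NL", 3, seed = 21)
  expect_length(nl, 3)
  expect_true(all(vapply(nl, tumor_stained_fraction, numeric(1)) <= 0.25))
  nr <- simulate_case_fields("NR", 3, seed = 21)
  expect_true(all(vapply(nr, tumor_stained_fraction, numeric(1)) > 0.25))
  expect_length(simulate_case_fields("NR", 1, seed = 3), 1)
  expect_error(simulate_case_fields("NR", 0, seed = 3), ">= 1")
})

test_that("field images and ground truth round-trip through PNG and CSV", {
  f <- simulate_field(sim_image_params(seed = 2))
  img_path <- withr::local_tempfile(fileext = ".png")
  write_field_png(f$image, img_path)
  expect_identical(read_field_image(img_path), f$image)

  truth_path <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(f$truth, truth_path)
  expect_equal(read_truth_csv(truth_path), f$truth)
})

test_that("FISH tables carry exact deleted-pattern counts and are seed-stable", {
  deleted_count <- function(tab) sum(tab$n_red == 1 & tab$n_green == 2)
  expect_equal(deleted_count(simulate_fish_table(0.5, 100, seed = 1)), 50)
  expect_equal(deleted_count(simulate_fish_table(0, 100, seed = 1)), 0)
  expect_equal(deleted_count(simulate_fish_table(0.73, 100, seed = 1)), 73)
  expect_identical(simulate_fish_table(0.4, 80, seed = 7),
                   simulate_fish_table(0.4, 80, seed = 7))
  expect_error(simulate_fish_table(1.2, 100), "\\[0, 1\\]")
  expect_error(simulate_fish_table(0.5, 0), ">= 1")

  tab <- simulate_fish_table(0.3, 60, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fish_csv(tab, path)
  expect_equal(read_fish_csv(path), tab)
})
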