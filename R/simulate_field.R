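# Seeded simulator for single-channel brightfield IHC field images.
#
# The simulator is a proxy for DAB/hematoxylin appearance on an 8-bit gray
# scale: stained nuclei are dark, unstained nuclei are paler but still
# darker than the near-white background, and "dot-like" nuclei are
# unstained except for one small punctate focus of stain. Internal-control
# cells (endothelium / lymphocytes) are always rendered stained. Noise is
# Gaussian truncated at +/- 3 standard deviations so per-class pixel
# guarantees are exact by construction.

TRUTH_CLASSES <- c("TUMOR_STAINED", "TUMOR_DOTLIKE", "TUMOR_NEGATIVE",
                   "CONTROL_POSITIVE")

#' Simulation parameters for one stained tissue field
#'
#' Constructs and validates the parameter set of [simulate_field()].
#' Defaults define the package's standard study conditions: a 128-pixel
#' square field (a 20x-magnification proxy) holding 40 tumor nuclei and 5
#' always-stained internal-control cells, with class mean grays
#' stained 120 < unstained 160 < background 240 and truncated Gaussian
#' noise of sd 8 gray levels. With these grays and densities, Otsu's
#' two-class threshold falls between the nuclei and the background for any
#' stained fraction, so the extracted foreground is the full nucleus
#' population.
#'
#' @param image_size side of the square field, pixels.
#' @param n_tumor_nuclei number of tumor nuclei (>= 1).
#' @param n_control_cells number of internal-control cells.
#' @param stained_fraction proportion of tumor nuclei rendered diffusely
#'   stained, in `[0, 1]`.
#' @param dotlike_fraction proportion of the *unstained* tumor nuclei that
#'   carry one punctate stained dot.
#' @param mean_stained_gray,mean_unstained_gray,background_gray class mean
#'   gray levels, 0-255; must satisfy stained < unstained < background
#'   (brightfield: stain is dark).
#' @param noise_sd pixel noise standard deviation, gray levels (truncated
#'   at 3 sd).
#' @param nucleus_radius_range integer vector `c(min, max)` of nucleus
#'   radii, pixels.
#' @param seed integer seed; the rendered field is a pure function of the
#'   parameter set.
#' @return An object of class `sim_image_params`.
#' @export
sim_image_params <- function(image_size = 128L,
                             n_tumor_nuclei = 40L,
                             n_control_cells = 5L,
                             stained_fraction = 0.85,
                             dotlike_fraction = 0.10,
                             mean_stained_gray = 120,
                             mean_unstained_gray = 160,
                             background_gray = 240,
                             noise_sd = 8,
                             nucleus_radius_range = c(4L, 7L),
                             seed = 1L) {
  p <- list(image_size = as.integer(image_size),
            n_tumor_nuclei = as.integer(n_tumor_nuclei),
            n_control_cells = as.integer(n_control_cells),
            stained_fraction = stained_fraction,
            dotlike_fraction = dotlike_fraction,
            mean_stained_gray = mean_stained_gray,
            mean_unstained_gray = mean_unstained_gray,
            background_gray = background_gray,
            noise_sd = noise_sd,
            nucleus_radius_range = as.integer(nucleus_radius_range),
            seed = as.integer(seed))
  if (p$image_size < 16) stop("image_size too small")
  if (p$n_tumor_nuclei < 1) stop("n_tumor_nuclei must be >= 1")
  if (p$n_control_cells < 0) stop("n_control_cells must be >= 0")
  for (f in c("stained_fraction", "dotlike_fraction"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (!(p$mean_stained_gray < p$mean_unstained_gray &&
        p$mean_unstained_gray < p$background_gray))
    stop("class grays must satisfy stained < unstained < background")
  if (any(c(p$mean_stained_gray, p$background_gray) < 0) ||
      p$background_gray > 255)
    stop("gray levels must lie in [0, 255]")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(p$nucleus_radius_range) != 2 ||
      p$nucleus_radius_range[1] < 2 ||
      diff(p$nucleus_radius_range) < 0)
    stop("nucleus_radius_range must be c(min >= 2, max >= min)")
  structure(p, class = "sim_image_params")
}

# Non-overlapping disc placement by rejection sampling (consumes the RNG
# stream of the caller). Discs keep >= 2 px of clearance from each other
# and from the image border. A stuck configuration is discarded and
# placement restarted (bounded number of restarts), which keeps the draw
# deterministic for a given RNG state.
place_nuclei <- function(image_size, radii, max_attempts = 400L,
                         max_restarts = 25L) {
  n <- length(radii)
  for (restart in seq_len(max_restarts)) {
    rows <- integer(n); cols <- integer(n)
    placed_all <- TRUE
    for (i in seq_len(n)) {
      r <- radii[i]
      lo <- r + 2L
      hi <- image_size - r - 1L
      if (hi <= lo) stop("nucleus radius too large for image size")
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        cr <- sample(lo:hi, 1L)
        cc <- sample(lo:hi, 1L)
        if (i == 1L) { ok <- TRUE } else {
          j <- seq_len(i - 1L)
          d2 <- (rows[j] - cr)^2 + (cols[j] - cc)^2
          ok <- all(d2 >= (radii[j] + r + 2L)^2)
        }
        if (ok) { rows[i] <- cr; cols[i] <- cc; break }
      }
      if (!ok) { placed_all <- FALSE; break }
    }
    if (placed_all) return(cbind(row = rows, col = cols))
  }
  stop("could not place ", n, " non-overlapping nuclei after ",
       max_restarts, " restarts; reduce density")
}

fill_disc <- function(img, cr, cc, r, value) {
  rr <- max(1L, cr - r):min(nrow(img), cr + r)
  cc_ <- max(1L, cc - r):min(ncol(img), cc + r)
  sub <- outer((rr - cr)^2, (cc_ - cc)^2, `+`) <= r^2
  img[rr, cc_][sub] <- value
  img
}

#' Simulate one stained tissue field with per-nucleus ground truth
#'
#' Renders an 8-bit single-channel field: non-overlapping nucleus discs at
#' their class mean gray on a near-white background, with
#' `round(stained_fraction * n_tumor_nuclei)` tumor nuclei diffusely
#' stained, a seeded subset of the unstained nuclei carrying one interior
#' stained dot (area 1/16 of the nucleus, below the 10% dot-area bound used
#' by nucleus classification), and internal-control cells always stained.
#' Truncated Gaussian noise (+/- 3 sd) is added and the image clipped to
#' `[0, 255]` and rounded. The same parameter set always yields a
#' bit-identical image.
#'
#' @param params a [sim_image_params()] object.
#' @return A list with elements `image` (integer matrix, gray 0-255,
#'   row-major) and `truth`, a `data.frame` with columns `nucleus_id`,
#'   `row`, `col` (0-based center coordinates), `radius` and `truth_class`
#'   (one of `TUMOR_STAINED`, `TUMOR_DOTLIKE`, `TUMOR_NEGATIVE`,
#'   `CONTROL_POSITIVE`).
#' @examples
#' f <- simulate_field(sim_image_params(stained_fraction = 1, seed = 7))
#' table(f$truth$truth_class)
#' @export
simulate_field <- function(params) {
  if (!inherits(params, "sim_image_params"))
    params <- do.call(sim_image_params, params)
  withr::with_seed(params$seed, {
    n_tumor <- params$n_tumor_nuclei
    n_total <- n_tumor + params$n_control_cells
    rr <- params$nucleus_radius_range
    radii <- sample(seq(rr[1], rr[2]), n_total, replace = TRUE)
    centers <- place_nuclei(params$image_size, radii)

    n_stained <- as.integer(round(params$stained_fraction * n_tumor))
    n_unstained <- n_tumor - n_stained
    n_dot <- as.integer(round(params$dotlike_fraction * n_unstained))
    tumor_classes <- sample(rep(c("TUMOR_STAINED", "TUMOR_DOTLIKE",
                                  "TUMOR_NEGATIVE"),
                                times = c(n_stained, n_dot,
                                          n_unstained - n_dot)))
    classes <- c(tumor_classes, rep("CONTROL_POSITIVE", params$n_control_cells))

    img <- matrix(params$background_gray, params$image_size, params$image_size)
    for (i in seq_len(n_total)) {
      g <- if (classes[i] %in% c("TUMOR_STAINED", "CONTROL_POSITIVE"))
        params$mean_stained_gray else params$mean_unstained_gray
      img <- fill_disc(img, centers[i, "row"], centers[i, "col"], radii[i], g)
      if (classes[i] == "TUMOR_DOTLIKE") {
        dot_r <- max(1L, as.integer(round(radii[i] / 4)))
        img <- fill_disc(img, centers[i, "row"], centers[i, "col"], dot_r,
                         params$mean_stained_gray)
      }
    }
    if (params$noise_sd > 0) {
      eps <- rnorm(length(img), sd = params$noise_sd)
      lim <- 3 * params$noise_sd
      img <- img + pmin(pmax(eps, -lim), lim)
    }
    img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))),
                  nrow = params$image_size)

    truth <- data.frame(
      nucleus_id = sprintf("nuc_%03d", seq_len(n_total)),
      row = centers[, "row"] - 1L,
      col = centers[, "col"] - 1L,
      radius = radii,
      truth_class = factor(classes, levels = TRUTH_CLASSES),
      stringsAsFactors = FALSE
    )
    list(image = img, truth = truth)
  })
}

# Seeds for per-field / per-case streams, derived deterministically from a
# parent seed; kept inside the 32-bit signed integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 7919) %% 2147483647)
}

#' Simulate the three fields scored for one case
#'
#' Draws `n_fields` fields for a case whose expected H3K27me3 read-out is
#' `NL` (nuclear loss) or `NR` (nuclear retention). NL cases are drawn with
#' a stained fraction well below the 25% positivity rule and NR cases well
#' above it (defaults 0.05 and 0.85); per-field seeds are derived
#' deterministically from the case seed.
#'
#' @param case_label `"NL"` or `"NR"`.
#' @param n_fields number of fields per case (default 3, the number of
#'   randomly chosen 20x areas scored per section).
#' @param base_params a [sim_image_params()] object supplying everything
#'   except the stained fraction and seed.
#' @param seed case-level integer seed.
#' @param nl_stained_fraction,nr_stained_fraction stained fractions used
#'   for NL and NR cases.
#' @return A list of `n_fields` results of [simulate_field()].
#' @export
simulate_case_fields <- function(case_label = c("NR", "NL"),
                                 n_fields = 3L,
                                 base_params = sim_image_params(),
                                 seed = 1L,
                                 nl_stained_fraction = 0.05,
                                 nr_stained_fraction = 0.85) {
  case_label <- match.arg(case_label)
  n_fields <- as.integer(n_fields)
  if (n_fields < 1) stop("n_fields must be >= 1")
  sf <- if (case_label == "NL") nl_stained_fraction else nr_stained_fraction
  lapply(seq_len(n_fields), function(i) {
    p <- unclass(base_params)
    p$stained_fraction <- sf
    p$seed <- derive_seed(seed, i)
    simulate_field(do.call(sim_image_params, p))
  })
}

#' Write / read an 8-bit grayscale field image
#'
#' Fields are stored as single-channel 8-bit grayscale PNG;
#' [read_field_image()] also accepts TIFF (via the tiff package, if
#' installed). Pixel values round-trip exactly.
#'
#' @param image integer matrix, gray 0-255.
#' @param path file path (`.png`, or `.tif`/`.tiff` on read).
#' @return `write_field_png()` returns `path` invisibly;
#'   `read_field_image()` returns the integer gray matrix.
#' @export
write_field_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname write_field_png
#' @export
read_field_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  matrix(as.integer(round(arr * 255)), nrow = nrow(arr))
}

#' Write / read per-nucleus ground truth as CSV
#'
#' @param truth ground-truth `data.frame` from [simulate_field()].
#' @param path file path.
#' @return `write_truth_csv()` returns `path` invisibly;
#'   `read_truth_csv()` the `data.frame`.
#' @export
write_truth_csv <- function(truth, path) {
  write.table(truth, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  truth <- read.csv(path, stringsAsFactors = FALSE)
  truth$truth_class <- factor(truth$truth_class, levels = TRUTH_CLASSES)
  truth
}
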