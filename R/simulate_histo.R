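# Synthetic micrograph rendering. Two region models:
#   snc      -- a bright background carrying a known number of dark,
#               non-overlapping nuclear disks (counting ground truth);
#   striatum -- a fiber-staining absorbance field whose mean optical
#               density scales linearly with `fiber_density`.
# Gray values are on the 8-bit 0..255 scale; images are plain matrices
# with ground truth stored in attributes (and a JSON sidecar on disk).

#' Parameters of the synthetic micrograph generator
#'
#' @param region `"snc"` or `"striatum"`.
#' @param n_nuclei number of nuclear disks (snc).
#' @param fiber_density staining density in `[0, 1]` (striatum); the mean
#'   absorbance of the fiber field scales linearly with it.
#' @param nucleus_radius_px disk radius, pixels.
#' @param image_size image side length, pixels (square frame).
#' @param background_level background gray value (bright field).
#' @param noise_sd SD of additive Gaussian pixel noise, gray values.
#' @param seed integer seed.
#' @return object of class `histo_image_params`.
#' @export
histo_image_params <- function(region = c("snc", "striatum"),
                               n_nuclei = 100, fiber_density = 1,
                               nucleus_radius_px = 4, image_size = 512,
                               background_level = 220, noise_sd = 3,
                               seed = 1) {
  region <- match.arg(region)
  if (fiber_density < 0 || fiber_density > 1)
    stop_bad_arg("fiber_density must lie in [0, 1]")
  if (n_nuclei < 0 || nucleus_radius_px < 1 || image_size < 16)
    stop_bad_arg("invalid geometry parameters")
  structure(list(region = region, n_nuclei = as.integer(n_nuclei),
                 fiber_density = fiber_density,
                 nucleus_radius_px = nucleus_radius_px,
                 image_size = as.integer(image_size),
                 background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "histo_image_params")
}

# rejection-sample nucleus centres with a hard minimum separation;
# min_sep > 2*radius keeps disks disjoint so the count is unambiguous
place_centres <- function(n, size, radius, min_sep, max_tries) {
  cx <- numeric(n); cy <- numeric(n)
  placed <- 0L
  tries <- 0L
  lo <- radius + 2
  hi <- size - radius - 1
  if (hi <= lo) stop_bad_arg("nuclei do not fit in the frame")
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop_bad_arg(sprintf(
        "could not place %d nuclei with separation %.1f px in a %d px frame (placed %d)",
        n, min_sep, size, placed))
    x <- stats::runif(1, lo, hi)
    y <- stats::runif(1, lo, hi)
    if (placed == 0L ||
        min((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2) >=
          min_sep^2) {
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y
    }
  }
  cbind(cx, cy)
}

#' Synthesize a histology micrograph with known ground truth
#'
#' For `region = "snc"`, exactly `n_nuclei` dark disks are placed on a
#' bright background with centre separation at least `2*radius + 3`
#' pixels (disjoint components, so the true count is unambiguous). For
#' `region = "striatum"`, a clumpy fiber absorbance field `a(x, y)` is
#' rendered and pixel intensity follows the transmission law
#' `I = background * 10^(-a)` with `a` proportional to `fiber_density`,
#' so optical density is additive under stacking and its mean recovers
#' the density linearly. Gaussian pixel noise is added last.
#'
#' @param params a [histo_image_params()].
#' @return a numeric matrix (gray 0..255) of class `histo_image` with
#'   attributes `region` and `ground_truth`.
#' @export
synthesize_histo_image <- function(params) {
  stopifnot(inherits(params, "histo_image_params"))
  set.seed(params$seed)
  size <- params$image_size
  img <- matrix(params$background_level, size, size)
  truth <- list(region = params$region)
  if (params$region == "snc") {
    r <- params$nucleus_radius_px
    if (params$n_nuclei > 0) {
      cen <- place_centres(params$n_nuclei, size, r,
                           min_sep = 2 * r + 3,
                           max_tries = 400L * params$n_nuclei + 1000L)
      for (i in seq_len(nrow(cen))) {
        xr <- floor(max(1, cen[i, 1] - r)):ceiling(min(size, cen[i, 1] + r))
        yr <- floor(max(1, cen[i, 2] - r)):ceiling(min(size, cen[i, 2] + r))
        dx <- outer(xr - cen[i, 1], yr - cen[i, 2],
                    function(a, b) a^2 + b^2)
        disk <- dx <= r^2
        sub <- img[xr, yr]
        sub[disk] <- 60  # dark DAB-stained nucleus
        img[xr, yr] <- sub
      }
      truth$centres <- cen
    }
    truth$n_nuclei <- params$n_nuclei
  } else {
    # clumpy binary fiber mask from blurred white noise, thresholded to
    # ~60% coverage; absorbance on fibers is proportional to density
    field <- matrix(stats::runif(size * size), size, size)
    field <- as.matrix(EBImage::gblur(EBImage::Image(field),
                                      sigma = max(2, size / 128)))
    mask <- field < stats::quantile(field, 0.6)
    absorb <- matrix(0, size, size)
    absorb[mask] <- params$fiber_density * 0.30
    img <- params$background_level * 10^(-absorb)
    truth$fiber_density <- params$fiber_density
    truth$mean_absorbance <- mean(absorb)
  }
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, params$noise_sd),
                        size, size)
  img <- pmin(pmax(img, 0), 255)
  structure(img, class = c("histo_image", "matrix", "array"),
            region = params$region, ground_truth = truth)
}

#' @export
print.histo_image <- function(x, ...) {
  gt <- attr(x, "ground_truth")
  cat(sprintf("histo_image: %dx%d px, region %s%s\n",
              nrow(x), ncol(x), attr(x, "region"),
              if (!is.null(gt$n_nuclei))
                sprintf(", %d nuclei (ground truth)", gt$n_nuclei)
              else sprintf(", fiber density %.3g", gt$fiber_density)))
  invisible(x)
}

#' Write a synthetic micrograph as 8-bit PNG plus a JSON sidecar
#'
#' @param img a `histo_image`.
#' @param path PNG path; the sidecar is written at `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_histo_image <- function(img, path) {
  png::writePNG(t(img) / 255, path)
  gt <- attr(img, "ground_truth")
  gt$centres <- NULL  # keep the sidecar small; count/density is the truth
  jsonlite::write_json(gt, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a micrograph PNG (and its ground-truth sidecar when present)
#'
#' @param path PNG path.
#' @return a `histo_image` matrix on the 0..255 scale.
#' @export
read_histo_image <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  img <- t(m) * 255
  sidecar <- paste0(path, ".json")
  gt <- NULL
  if (file.exists(sidecar))
    gt <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(img, class = c("histo_image", "matrix", "array"),
            region = gt$region %||% NA_character_, ground_truth = gt)
}
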