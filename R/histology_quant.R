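# Quantification of TH-positive staining on grayscale micrographs:
# densitometry of striatal fibers and nuclei counting in the SNc.

#' Object-counting parameters
#'
#' @param intensity_threshold `"otsu"` (automatic, default) or a numeric
#'   gray value; pixels darker than the threshold are foreground.
#' @param min_object_area,max_object_area component area filter, px^2.
#' @param min_contrast minimum separation (gray values) between the
#'   bright and dark class means for the automatic threshold to be
#'   considered meaningful; below it the image is treated as unstained
#'   and the count is 0.
#' @return object of class `counting_params`.
#' @export
counting_params <- function(intensity_threshold = "otsu",
                            min_object_area = 8,
                            max_object_area = 1e5,
                            min_contrast = 20) {
  if (min_object_area <= 0 || max_object_area < min_object_area)
    stop_bad_arg("need 0 < min_object_area <= max_object_area")
  structure(list(intensity_threshold = intensity_threshold,
                 min_object_area = min_object_area,
                 max_object_area = max_object_area,
                 min_contrast = min_contrast),
            class = "counting_params")
}

#' Mean optical density of a stained region
#'
#' Per-pixel optical density is `log10(I_bg / I)`, where the background
#' intensity `I_bg` is estimated as the mean of the brightest decile of
#' the region (or supplied explicitly). The value returned is the mean
#' OD over the region of interest. Pixels at or below
#' `I_bg * 10^-od_ceiling` (saturated black) are clipped at the OD
#' ceiling; the number clipped is reported in the `n_clipped` attribute.
#'
#' @param image grayscale matrix (0..255).
#' @param roi optional logical mask of the same dimension; default whole
#'   frame.
#' @param background optional background intensity `I_bg`; default
#'   estimated from the ROI's brightest decile.
#' @param od_ceiling OD clipping ceiling (default 3).
#' @return mean OD (dimensionless), with attributes `background` and
#'   `n_clipped`.
#' @export
striatal_optical_density <- function(image, roi = NULL, background = NULL,
                                     od_ceiling = 3) {
  m <- unclass(image)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(m), ncol(m))
  if (!identical(dim(roi), dim(m)))
    stop_bad_arg("roi must match the image dimensions")
  v <- m[roi]
  if (!length(v)) stop_bad_arg("empty region of interest")
  bg <- background %||%
    mean(v[v >= stats::quantile(v, 0.9, names = FALSE)])
  if (bg <= 0) stop_bad_arg("background intensity must be > 0")
  floor_i <- bg * 10^(-od_ceiling)
  n_clipped <- sum(v <= floor_i)
  od <- log10(bg / pmax(v, floor_i))
  out <- mean(od)
  attr(out, "background") <- bg
  attr(out, "n_clipped") <- n_clipped
  out
}

# Otsu threshold on the 0..255 scale
otsu_threshold <- function(m) {
  EBImage::otsu(EBImage::Image(m / 255), range = c(0, 1)) * 255
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass
label_components_8 <- function(mask) {
  lbl <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lbl <- matrix(as.integer(lbl), nrow(mask), ncol(mask))
  nmax <- max(lbl)
  if (nmax < 2) return(lbl)
  nr <- nrow(lbl); nc <- ncol(lbl)
  a1 <- lbl[-nr, -nc]; b1 <- lbl[-1, -1]    # down-right diagonal
  a2 <- lbl[-nr, -1];  b2 <- lbl[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs)) {
    parent <- seq_len(nmax)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nmax), find, integer(1))
    lbl[lbl > 0] <- root[lbl[lbl > 0]]
  }
  lbl
}

#' Count TH-stained nuclei in an SNc micrograph
#'
#' Dark objects are segmented by thresholding (Otsu by default), labeled
#' as 8-connected components, filtered by area, and counted. Because the
#' automatic threshold and the contrast guard depend only on intensity
#' differences, the count is invariant to uniform brightness shifts that
#' preserve the threshold ordering.
#'
#' @param image grayscale matrix (0..255).
#' @param params a [counting_params()].
#' @return integer count, with attribute `threshold`.
#' @export
count_th_nuclei <- function(image, params = counting_params()) {
  m <- unclass(image)
  if (stats::sd(m) == 0) {
    out <- 0L
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  if (identical(params$intensity_threshold, "otsu")) {
    thr <- otsu_threshold(m)
    dark <- m < thr
    if (!any(dark) || all(dark)) {
      out <- 0L; attr(out, "threshold") <- thr; return(out)
    }
    contrast <- mean(m[!dark]) - mean(m[dark])
    if (contrast < params$min_contrast) {
      out <- 0L
      attr(out, "threshold") <- thr
      return(out)
    }
  } else {
    thr <- params$intensity_threshold
    dark <- m < thr
  }
  if (!any(dark)) {
    out <- 0L; attr(out, "threshold") <- thr; return(out)
  }
  lbl <- label_components_8(dark)
  areas <- tabulate(lbl[lbl > 0])
  cnt <- sum(areas >= params$min_object_area &
               areas <= params$max_object_area)
  out <- as.integer(cnt)
  attr(out, "threshold") <- thr
  out
}

#' Percent reduction of a group relative to control
#'
#' `100 * (1 - mean(group) / mean(control))`; the median-based value is
#' attached as attribute `median_based` as a sensitivity companion.
#'
#' @param group_values,control_values nonempty numeric vectors.
#' @return percent reduction (positive = loss relative to control).
#' @export
percent_reduction <- function(group_values, control_values) {
  if (!length(group_values) || !length(control_values))
    stop_bad_arg("both value sets must be nonempty")
  mc <- mean(control_values)
  if (mc == 0) stop_bad_arg("control mean is zero; reduction undefined")
  out <- 100 * (1 - mean(group_values) / mc)
  medc <- stats::median(control_values)
  attr(out, "median_based") <-
    if (medc != 0) 100 * (1 - stats::median(group_values) / medc)
    else NA_real_
  out
}
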