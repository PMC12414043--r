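# CIELAB Delta E colour segmentation of intraoperative images: thin-walled
# (red, translucent) aneurysm wall is segmented as all pixels within a fixed
# Delta E distance of the mean Lab value of a user-selected reference region.

#' Construct an 8-bit RGB image object
#'
#' @param x h x w x 3 array of 8-bit channel values (0..255), or values in
#'   [0, 1] which are rescaled.
#' @param roi optional logical h x w matrix marking the region of interest;
#'   defaults to the full frame.
#' @return object of class `rgb_image` (integer array with `roi` attribute).
#' @export
rgb_image <- function(x, roi = NULL) {
  if (length(dim(x)) != 3L || dim(x)[3] != 3L) stop("expected an h x w x 3 array")
  if (max(x) <= 1 && min(x) >= 0 && !is.integer(x)) x <- round(x * 255)
  if (min(x) < 0 || max(x) > 255) stop("channel values must lie in [0, 255]")
  img <- array(as.integer(round(x)), dim = dim(x))
  if (is.null(roi)) roi <- matrix(TRUE, dim(x)[1], dim(x)[2])
  if (!identical(dim(roi), dim(x)[1:2])) stop("ROI dimensions do not match image")
  structure(img, roi = roi, class = "rgb_image")
}

#' Read / write 8-bit PNG images
#' @param path file path.
#' @return [read_image_png()] returns an `rgb_image`.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  rgb_image(a[, , 1:3, drop = FALSE])
}

#' @rdname read_image_png
#' @param image an `rgb_image` (or logical mask, written as 0/255).
#' @export
write_image_png <- function(image, path) {
  if (is.logical(image)) {
    png::writePNG(matrix(as.numeric(image), nrow(image), ncol(image)), path)
  } else {
    png::writePNG(unclass(image) / 255, path)
  }
  invisible(path)
}

#' Rasterise a region-of-interest polygon to a pixel mask
#'
#' Even-odd (ray casting) point-in-polygon test on pixel centres. The
#' polygon must be simple: self-intersecting boundaries are rejected.
#' @keywords internal
polygon_mask <- function(poly, h, w) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L) stop("ROI polygon needs >= 3 (x, y) vertices")
  if (min(poly[, 1]) < 0.5 || max(poly[, 1]) > w + 0.5 ||
      min(poly[, 2]) < 0.5 || max(poly[, 2]) > h + 0.5)
    stop("ROI polygon lies outside the image bounds")
  if (polygon_self_intersects(poly)) stop("ROI polygon is self-intersecting")
  px <- rep(seq_len(w), each = h)
  py <- rep(seq_len(h), times = w)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- logical(h * w)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, h, w)
}

#' @keywords internal
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1L), ])
  ccw <- function(a, b, c)
    (c[, 2] - a[, 2]) * (b[, 1] - a[, 1]) > (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  for (i in seq_len(n - 2L)) {
    js <- setdiff(seq(i + 2L, n), c(i, if (i == 1L) n else integer()))
    if (length(js) == 0L) next
    a <- matrix(seg[i, 1:2], length(js), 2, byrow = TRUE)
    b <- matrix(seg[i, 3:4], length(js), 2, byrow = TRUE)
    cpt <- seg[js, 1:2, drop = FALSE]
    dpt <- seg[js, 3:4, drop = FALSE]
    hit <- (ccw(a, cpt, dpt) != ccw(b, cpt, dpt)) &
           (ccw(a, b, cpt) != ccw(a, b, dpt))
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Pre-process an intraoperative image
#'
#' Applies the manual-masking and contrast-enhancement step: pixels outside
#' the region-of-interest polygon are excluded from all downstream
#' statistics, and an optional linear percentile stretch is applied inside
#' the ROI only. With `contrast = NULL` and a full-frame ROI the image is
#' returned unchanged (idempotent identity).
#'
#' @param image an `rgb_image` (or raw array).
#' @param roi_polygon optional n x 2 matrix of (x, y) polygon vertices in
#'   pixel coordinates; must be simple (non-self-intersecting).
#' @param contrast optional list `list(p_lo, p_hi, out_range)`: channel
#'   values between the `p_lo` and `p_hi` quantiles (defaults 0.01 / 0.99,
#'   computed inside the ROI) are mapped linearly onto `out_range`
#'   (default `c(0, 255)`) and clipped.
#' @return an `rgb_image` with the ROI recorded in its `roi` attribute.
#' @export
preprocess <- function(image, roi_polygon = NULL, contrast = NULL) {
  image <- if (inherits(image, "rgb_image")) image else rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  roi <- if (is.null(roi_polygon)) attr(image, "roi") else polygon_mask(roi_polygon, h, w)
  out <- unclass(image)
  if (!is.null(contrast)) {
    p_lo <- if (is.null(contrast$p_lo)) 0.01 else contrast$p_lo
    p_hi <- if (is.null(contrast$p_hi)) 0.99 else contrast$p_hi
    rng <- if (is.null(contrast$out_range)) c(0, 255) else contrast$out_range
    for (ch in 1:3) {
      plane <- out[, , ch]
      q <- stats::quantile(plane[roi], c(p_lo, p_hi), names = FALSE, type = 7)
      if (q[2] > q[1]) {
        stretched <- (plane[roi] - q[1]) / (q[2] - q[1]) * (rng[2] - rng[1]) + rng[1]
        plane[roi] <- pmin(pmax(stretched, rng[1]), rng[2])
        out[, , ch] <- plane
      }
    }
  }
  rgb_image(out, roi = roi)
}

#' Convert an 8-bit sRGB image to CIELAB
#'
#' Standard sRGB to CIELAB conversion under the D65 illuminant
#' (via [grDevices::convertColor()]).
#'
#' @param image an `rgb_image`.
#' @return object of class `lab_image`: h x w x 3 array with L* in
#'   `[0, 100]`, carrying the source ROI.
#' @export
rgb_to_lab <- function(image) {
  image <- if (inherits(image, "rgb_image")) image else rgb_image(image)
  d <- dim(image)
  flat <- matrix(as.vector(unclass(image)), ncol = 3) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  structure(array(as.vector(lab), dim = d), roi = attr(image, "roi"),
            class = "lab_image")
}

#' Mean CIELAB value of a reference region
#'
#' @param lab_image a `lab_image`.
#' @param region_pixels logical h x w matrix or linear pixel indices of the
#'   (non-empty) reference region.
#' @return named numeric Lab triple `(L, a, b)`.
#' @export
reference_from_region <- function(lab_image, region_pixels) {
  if (is.logical(region_pixels)) region_pixels <- which(region_pixels)
  if (length(region_pixels) == 0L) stop("reference region is empty")
  npix <- prod(dim(lab_image)[1:2])
  if (any(region_pixels < 1L | region_pixels > npix))
    stop("reference region indices out of bounds")
  roi <- attr(lab_image, "roi")
  if (!is.null(roi) && !all(roi[region_pixels]))
    stop("reference region must lie inside the ROI")
  m <- matrix(unclass(lab_image), ncol = 3)[region_pixels, , drop = FALSE]
  stats::setNames(colMeans(m), c("L", "a", "b"))
}

#' Per-pixel Delta E colour distance to a reference colour
#'
#' CIE76 is the Euclidean distance in (L*, a*, b*); CIEDE2000 is the 2000
#' revision of the colour-difference formula. Pixels outside the ROI are
#' `NA` and excluded from all downstream statistics.
#'
#' @param lab_image a `lab_image`.
#' @param reference finite Lab triple (e.g. from [reference_from_region()]).
#' @param formula `"cie76"` (default) or `"ciede2000"`.
#' @return matrix of class `delta_e_map` (h x w), with attributes
#'   `reference` and `formula`.
#' @export
compute_delta_e <- function(lab_image, reference, formula = c("cie76", "ciede2000")) {
  formula <- match.arg(formula)
  if (length(reference) != 3L || !all(is.finite(reference)))
    stop("reference must be a finite Lab triple")
  d <- dim(lab_image)
  m <- matrix(unclass(lab_image), ncol = 3)
  de <- if (formula == "cie76") {
    sqrt((m[, 1] - reference[1])^2 + (m[, 2] - reference[2])^2 +
         (m[, 3] - reference[3])^2)
  } else {
    delta_e_ciede2000(m, matrix(reference, nrow(m), 3, byrow = TRUE))
  }
  de <- matrix(de, d[1], d[2])
  roi <- attr(lab_image, "roi")
  if (!is.null(roi)) de[!roi] <- NA_real_
  structure(de, reference = reference, formula = formula, class = "delta_e_map")
}

#' CIEDE2000 colour difference
#'
#' Vectorised implementation of the CIEDE2000 formula (weighting functions
#' for lightness, chroma and hue, the rotation term, and the default
#' parametric factors kL = kC = kH = 1).
#'
#' @param lab1,lab2 n x 3 matrices (or length-3 vectors) of Lab colours.
#' @return numeric vector of colour differences.
#' @export
delta_e_ciede2000 <- function(lab1, lab2) {
  if (!is.matrix(lab1)) lab1 <- matrix(lab1, ncol = 3)
  if (!is.matrix(lab2)) lab2 <- matrix(lab2, ncol = 3)
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  Cbar <- (sqrt(a1^2 + b1^2) + sqrt(a2^2 + b2^2)) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  ap1 <- (1 + G) * a1
  ap2 <- (1 + G) * a2
  Cp1 <- sqrt(ap1^2 + b1^2)
  Cp2 <- sqrt(ap2^2 + b2^2)
  hp1 <- ifelse(Cp1 == 0, 0, (atan2(b1, ap1) * 180 / pi) %% 360)
  hp2 <- ifelse(Cp2 == 0, 0, (atan2(b2, ap2) * 180 / pi) %% 360)
  dL <- L2 - L1
  dC <- Cp2 - Cp1
  dh <- hp2 - hp1
  dh <- ifelse(Cp1 * Cp2 == 0, 0,
        ifelse(abs(dh) <= 180, dh, ifelse(dh > 180, dh - 360, dh + 360)))
  dH <- 2 * sqrt(Cp1 * Cp2) * sin(dh / 2 * pi / 180)
  Lbp <- (L1 + L2) / 2
  Cbp <- (Cp1 + Cp2) / 2
  hsum <- hp1 + hp2
  hbp <- ifelse(Cp1 * Cp2 == 0, hsum,
         ifelse(abs(hp1 - hp2) <= 180, hsum / 2,
         ifelse(hsum < 360, hsum / 2 + 180, hsum / 2 - 180)))
  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) + 0.24 * cos(2 * hbp * pi / 180) +
        0.32 * cos((3 * hbp + 6) * pi / 180) - 0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  Rc <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  Sl <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  Sc <- 1 + 0.045 * Cbp
  Sh <- 1 + 0.015 * Cbp * Tt
  Rt <- -sin(2 * dtheta * pi / 180) * Rc
  sqrt((dL / Sl)^2 + (dC / Sc)^2 + (dH / Sh)^2 + Rt * (dC / Sc) * (dH / Sh))
}

#' Threshold a Delta E map into a segmentation mask
#'
#' Pixels (inside the ROI) whose Delta E does not exceed `threshold` are
#' selected; the comparison is inclusive. The threshold is also reported as
#' a percentage of the map's maximum colour difference, the bookkeeping used
#' to justify a fixed absolute threshold across cases.
#'
#' @param delta_e_map a `delta_e_map`.
#' @param threshold positive Delta E bound (the analysis default is 10).
#' @return logical matrix of class `segmentation_mask` with attributes
#'   `threshold`, `fraction_of_max_pct`, `reference`, `formula`.
#' @export
threshold_mask <- function(delta_e_map, threshold = 10) {
  if (threshold <= 0) stop("threshold must be positive")
  vals <- unclass(delta_e_map)
  mask <- !is.na(vals) & vals <= threshold
  mx <- max(vals, na.rm = TRUE)
  structure(mask,
            threshold = threshold,
            fraction_of_max_pct = 100 * threshold / mx,
            reference = attr(delta_e_map, "reference"),
            formula = attr(delta_e_map, "formula"),
            class = c("segmentation_mask", "matrix"))
}

#' Histogram of a Delta E map
#'
#' @param delta_e_map a `delta_e_map`.
#' @param n_bins number of equal-width bins over the observed range.
#' @return data.frame with `lower`, `upper`, `mid`, `count`; counts sum to
#'   the number of ROI pixels.
#' @export
delta_e_histogram <- function(delta_e_map, n_bins = 64L) {
  vals <- unclass(delta_e_map)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("Delta E map is empty inside the ROI")
  rng <- range(vals)
  if (rng[2] == rng[1]) rng[2] <- rng[1] + 1e-9
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- hist(vals, breaks = breaks, plot = FALSE, right = TRUE,
                 include.lowest = TRUE)$counts
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L],
             mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             count = counts)
}

#' Segment thin-walled pixels of an intraoperative image
#'
#' End-to-end Delta E workflow: pre-process, convert to CIELAB, average the
#' reference region, compute the Delta E map and threshold it.
#'
#' @param image an `rgb_image`.
#' @param reference_pixels logical matrix or linear indices of the
#'   user-selected red reference region.
#' @param threshold Delta E threshold (default 10).
#' @param formula `"cie76"` or `"ciede2000"`.
#' @param roi_polygon,contrast passed to [preprocess()].
#' @return a `segmentation_mask` (see [threshold_mask()]); the Delta E map
#'   is attached as attribute `delta_e`.
#' @export
segment_thin_regions <- function(image, reference_pixels, threshold = 10,
                                 formula = "cie76", roi_polygon = NULL,
                                 contrast = NULL) {
  pre <- preprocess(image, roi_polygon = roi_polygon, contrast = contrast)
  lab <- rgb_to_lab(pre)
  ref <- reference_from_region(lab, reference_pixels)
  de <- compute_delta_e(lab, ref, formula = formula)
  mask <- threshold_mask(de, threshold)
  attr(mask, "delta_e") <- de
  mask
}
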