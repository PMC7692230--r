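## En-face OCTA vessel quantification: quality gating, binarization,
## skeletonization, and the four vessel metrics (VAD, VLF, VDI, box-counting
## fractal dimension) plus FAZ polygon area.

#' Signal-strength quality gate
#'
#' Eyes with a signal-strength ("Q score") below 30 on the device's 0--40
#' scale are excluded from all downstream metrics. The threshold is strict:
#' 29 fails, 30 passes.
#'
#' @param angiogram An [enface_angiogram()].
#' @param threshold Minimum acceptable quality (default 30).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
quality_gate <- function(angiogram, threshold = 30) {
  stopifnot(inherits(angiogram, "enface_angiogram"))
  angiogram$quality >= threshold
}

#' Binarize an en-face angiogram into a vessel map
#'
#' Converts the grayscale angiogram into a boolean vessel mask. The default
#' method is a global Otsu histogram threshold with no pre-filtering; vessel
#' pixels are those at or above the threshold (the foreground/bright class --
#' display polarity, where vessels print dark, is a presentation matter).
#'
#' @param angiogram An [enface_angiogram()] or a numeric matrix in \[0,1\].
#' @param method `"otsu"` (global histogram threshold), `"mean"` (global mean
#'   intensity), or `"fixed"` (use `threshold` as given).
#' @param threshold Threshold for `method = "fixed"`.
#' @return A `binary_vessel_map`: list with `mask` (logical matrix) and
#'   `provenance` (method + threshold used).
#' @export
binarize <- function(angiogram, method = c("otsu", "mean", "fixed"),
                     threshold = NULL) {
  method <- match.arg(method)
  px <- if (inherits(angiogram, "enface_angiogram")) angiogram$pixels else angiogram
  rq_assert(is.matrix(px) && all(px >= 0) && all(px <= 1),
            "intensities must be a matrix in [0,1]")
  if (method != "fixed" && diff(range(px)) == 0)
    rq_stop("degenerate histogram: constant image", "rq_degenerate_error")
  th <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(px), range = c(0, 1)),
    mean = mean(px),
    fixed = {
      rq_assert(is_scalar_number(threshold), "fixed method needs a threshold")
      threshold
    })
  structure(list(mask = px >= th,
                 provenance = list(method = method, threshold = th)),
            class = "binary_vessel_map")
}

#' Skeletonize a binary vessel map
#'
#' Zhang-Suen morphological thinning until a single pixel remains for each
#' vessel segment: one-pixel-wide, 8-connected centerlines. Connected
#' components of the input remain connected; an empty mask yields an empty
#' skeleton.
#'
#' @param binary A `binary_vessel_map` (or logical matrix).
#' @return A `skeleton_map`: list with logical `mask`.
#' @export
skeletonize <- function(binary) {
  mask <- if (inherits(binary, "binary_vessel_map")) binary$mask else binary
  rq_assert(is.matrix(mask), "mask must be a matrix")
  structure(list(mask = zhang_suen_thin(mask)), class = "skeleton_map")
}

mask_of <- function(x) {
  if (inherits(x, c("binary_vessel_map", "skeleton_map"))) x$mask else x
}

#' Vessel area density (VAD)
#'
#' Vessel-pixel count of the binarized image divided by the total number of
#' image pixels.
#'
#' @param binary A `binary_vessel_map` or logical matrix.
#' @return Fraction in \[0,1\].
#' @export
vessel_area_density <- function(binary) {
  m <- mask_of(binary)
  sum(m) / length(m)
}

#' Vessel length fraction (VLF)
#'
#' Skeleton-pixel count divided by the total number of image pixels: a
#' caliber-independent proxy for vessel length. Always `<=` the VAD of the
#' mask the skeleton derives from.
#'
#' @param skeleton A `skeleton_map` or logical matrix.
#' @return Fraction in \[0,1\].
#' @export
vessel_length_fraction <- function(skeleton) {
  m <- mask_of(skeleton)
  sum(m) / length(m)
}

#' Vessel diameter index (VDI)
#'
#' Mean vessel caliber: binarized vessel-pixel count divided by skeleton-pixel
#' count, scaled to micrometers.
#'
#' @param binary A `binary_vessel_map` or logical matrix.
#' @param skeleton The `skeleton_map` derived from `binary`.
#' @param scale Micrometers per pixel.
#' @return Mean caliber in micrometers.
#' @export
vessel_diameter_index <- function(binary, skeleton, scale = 1) {
  b <- mask_of(binary); s <- mask_of(skeleton)
  rq_assert(all(dim(b) == dim(s)), "mask and skeleton shapes differ")
  if (sum(s) == 0)
    rq_stop("vessel diameter index undefined: empty skeleton",
            "rq_degenerate_error")
  sum(b) / sum(s) * scale
}

## Occupied-box counts for one box size; grid anchored at the top-left corner.
box_count <- function(mask, s) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  bi <- (idx[, 1] - 1L) %/% s
  bj <- (idx[, 2] - 1L) %/% s
  length(unique(bi * (((ncol(mask) - 1L) %/% s) + 1L) + bj))
}

#' Box-counting fractal dimension of a skeleton
#'
#' Counts occupied boxes N(s) over a geometric ladder of box sizes (powers of
#' two from 2 px to a quarter of the shorter image side) and returns the
#' ordinary-least-squares slope of log N(s) against log(1/s). A straight line
#' scores ~1, a filled plane ~2; branching vessel skeletons fall in between,
#' increasing with ramification complexity.
#'
#' @param skeleton A `skeleton_map` or logical matrix with >= 2 true pixels.
#' @param sizes Optional explicit ladder of box sizes (pixels).
#' @return List of class `fractal_fit`: `fd` (the slope), `sizes`, `counts`.
#' @export
fractal_dimension <- function(skeleton, sizes = NULL) {
  m <- mask_of(skeleton)
  rq_assert(sum(m) >= 2, "skeleton needs at least 2 pixels",
            "rq_degenerate_error")
  if (is.null(sizes)) {
    smax <- min(dim(m)) / 4
    sizes <- 2^(1:30)
    sizes <- sizes[sizes <= smax]
  }
  if (length(sizes) < 3)
    rq_stop("box ladder has fewer than 3 sizes; image too small",
            "rq_degenerate_error")
  counts <- vapply(sizes, function(s) box_count(m, s), integer(1))
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  structure(list(fd = unname(stats::coef(fit)[2]), sizes = sizes,
                 counts = counts), class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> FD = %.4f over box sizes %s\n", x$fd,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

## Proper segment intersection test used by the FAZ polygon validity check.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Foveal avascular zone area from a traced polygon
#'
#' Shoelace area of the manually traced FAZ outline, converted to mm^2 using
#' the lateral pixel scales.
#'
#' @param polygon_vertices Two-column matrix/data.frame of `(x_px, y_px)`
#'   vertices (>= 3, simple polygon).
#' @param scale_x,scale_y Micrometers per pixel.
#' @return Area in mm^2.
#' @export
faz_area <- function(polygon_vertices, scale_x, scale_y) {
  v <- as.matrix(polygon_vertices)
  rq_assert(ncol(v) == 2, "polygon vertices must have two columns")
  n <- nrow(v)
  if (n < 3) rq_stop("polygon needs at least 3 vertices", "rq_degenerate_error")
  ## reject self-intersection between any non-adjacent edge pair
  nxt <- c(2:n, 1)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        rq_stop("self-intersecting polygon", "rq_format_error")
    }
  }
  x <- v[, 1]; y <- v[, 2]
  area_px2 <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  area_px2 * scale_x * scale_y / 1e6
}

#' Compute the full vessel-metric bundle for one angiogram
#'
#' Chains the quality gate, binarization, skeletonization and the four vessel
#' metrics, optionally adding the FAZ polygon area.
#'
#' @param angiogram An [enface_angiogram()].
#' @param faz_polygon Optional two-column matrix of FAZ outline vertices (px).
#' @param method Binarization method passed to [binarize()].
#' @param quality_threshold Minimum Q score (default 30).
#' @return A `vessel_metrics` list: `vad`, `vlf`, `vdi_um`, `fd`, `faz_mm2`
#'   (or `NA`), `plexus`, `eye_id`, `quality_pass`, `provenance`.
#' @export
compute_all_metrics <- function(angiogram, faz_polygon = NULL,
                                method = "otsu", quality_threshold = 30) {
  stopifnot(inherits(angiogram, "enface_angiogram"))
  if (!quality_gate(angiogram, quality_threshold))
    rq_stop(sprintf("quality gate failed: Q=%g < %g (%s %s)",
                    angiogram$quality, quality_threshold,
                    angiogram$eye_id, angiogram$plexus), "rq_quality_error")
  bin <- binarize(angiogram, method = method)
  skel <- skeletonize(bin)
  scale <- sqrt(angiogram$scale_x * angiogram$scale_y)
  structure(list(
    vad = vessel_area_density(bin),
    vlf = vessel_length_fraction(skel),
    vdi_um = vessel_diameter_index(bin, skel, scale),
    fd = fractal_dimension(skel)$fd,
    faz_mm2 = if (is.null(faz_polygon)) NA_real_ else
      faz_area(faz_polygon, angiogram$scale_x, angiogram$scale_y),
    plexus = angiogram$plexus, eye_id = angiogram$eye_id,
    quality_pass = TRUE, provenance = bin$provenance
  ), class = "vessel_metrics")
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf("<vessel_metrics> %s %s: VAD %.4f, VLF %.4f, VDI %.2f um, FD %.3f%s\n",
              x$eye_id, x$plexus, x$vad, x$vlf, x$vdi_um, x$fd,
              if (is.na(x$faz_mm2)) "" else sprintf(", FAZ %.3f mm2", x$faz_mm2)))
  invisible(x)
}

#' @export
as.data.frame.vessel_metrics <- function(x, ...) {
  data.frame(eye_id = x$eye_id, plexus = x$plexus, vad = x$vad, vlf = x$vlf,
             vdi_um = x$vdi_um, fd = x$fd, faz_mm2 = x$faz_mm2,
             stringsAsFactors = FALSE)
}
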