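## Domain record constructors and on-disk readers/writers.
##
## Conventions used throughout the package:
##   * images are numeric matrices, rows = image rows (depth for B-scans,
##     increasing downward), columns = lateral position; intensities in [0,1];
##   * on-disk pixel coordinates (boundary tables, polygon CSVs, fovea_col in
##     sidecar JSON) are 0-based with pixel-center convention; readers convert
##     to R's 1-based indexing internally and writers convert back.

PLEXUS_LEVELS <- c("SVP", "ICP", "DCP")
GROUP_LEVELS <- c("control", "noDR", "DR")

## Eleven segmentation markers, ordered inner (vitreous side) to outer.
BOUNDARY_MARKERS <- c("ILM", "RNFL_GCL", "GCL_IPL", "IPL_INL", "INL_OPL",
                      "OPL_ONL", "ELM", "MZ_EZ", "EZ_OS", "OS_RPE", "BM")

## Seven reported layers as (upper marker, lower marker) pairs. ORL closes the
## stack from the external limiting membrane down to RPE/Bruch's membrane, so
## the seven layers partition the full ILM-to-BM thickness.
LAYER_DEF <- list(
  RNFL = c("ILM", "RNFL_GCL"),
  GCL  = c("RNFL_GCL", "GCL_IPL"),
  IPL  = c("GCL_IPL", "IPL_INL"),
  INL  = c("IPL_INL", "INL_OPL"),
  OPL  = c("INL_OPL", "OPL_ONL"),
  ONL  = c("OPL_ONL", "ELM"),
  ORL  = c("ELM", "BM")
)

#' En-face angiogram record
#'
#' Bundles a calibrated en-face OCTA intensity image for one vascular plexus
#' of one eye with the acquisition metadata the downstream metrics need.
#'
#' @param pixels Numeric matrix of intensities in \[0,1\].
#' @param scale_x,scale_y Lateral pixel pitch in micrometers per pixel.
#' @param plexus One of `"SVP"`, `"ICP"`, `"DCP"`.
#' @param eye_id Opaque eye identifier.
#' @param quality Signal-strength score on the device's 0--40 scale.
#' @return An object of class `enface_angiogram`.
#' @export
enface_angiogram <- function(pixels, scale_x, scale_y, plexus, eye_id = "eye",
                             quality = 40) {
  rq_assert(is.matrix(pixels) && length(pixels) > 0,
            "pixels must be a non-empty matrix", "rq_format_error")
  rq_assert(all(is.finite(pixels)) && min(pixels) >= 0 && max(pixels) <= 1,
            "pixel intensities must lie in [0,1]", "rq_format_error")
  rq_assert(is_scalar_number(scale_x) && scale_x > 0,
            "scale_x must be > 0", "rq_format_error")
  rq_assert(is_scalar_number(scale_y) && scale_y > 0,
            "scale_y must be > 0", "rq_format_error")
  rq_assert(is.character(plexus) && plexus %in% PLEXUS_LEVELS,
            "plexus must be one of SVP, ICP, DCP", "rq_format_error")
  rq_assert(is_scalar_number(quality) && quality >= 0 && quality <= 40,
            "quality outside [0,40]", "rq_format_error")
  structure(list(pixels = pixels, scale_x = scale_x, scale_y = scale_y,
                 plexus = plexus, eye_id = as.character(eye_id),
                 quality = quality),
            class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("<enface_angiogram> %s %s: %d x %d px, %.2f x %.2f um/px, Q=%g\n",
              x$eye_id, x$plexus, nrow(x$pixels), ncol(x$pixels),
              x$scale_x, x$scale_y, x$quality))
  invisible(x)
}

#' Structural B-scan record
#'
#' A structural OCT B-scan (rows = depth, increasing downward) together with
#' the 11 layer-segmentation boundary traces and axial/lateral calibration.
#'
#' @param pixels Numeric matrix, intensities in \[0,1\].
#' @param axial_scale,lateral_scale Micrometers per pixel along depth/lateral.
#' @param fovea_col Column index (1-based) of the foveal center.
#' @param boundaries Numeric matrix `11 x ncol(pixels)`, row names the
#'   segmentation markers in `BOUNDARY_MARKERS` order, values 1-based row
#'   coordinates; must be vertically ordered (ILM above BM at every column).
#' @param eye_id Opaque eye identifier.
#' @return An object of class `bscan_record`.
#' @export
bscan_record <- function(pixels, axial_scale, lateral_scale, fovea_col,
                         boundaries, eye_id = "eye") {
  rq_assert(is.matrix(pixels) && length(pixels) > 0,
            "pixels must be a non-empty matrix", "rq_format_error")
  rq_assert(is_scalar_number(axial_scale) && axial_scale > 0 &&
              is_scalar_number(lateral_scale) && lateral_scale > 0,
            "axial/lateral scales must be > 0", "rq_format_error")
  rq_assert(is_scalar_number(fovea_col) && fovea_col >= 1 &&
              fovea_col <= ncol(pixels),
            "fovea_col outside image width", "rq_format_error")
  rq_assert(is.matrix(boundaries) && nrow(boundaries) == 11 &&
              ncol(boundaries) == ncol(pixels),
            "boundaries must be an 11 x ncol matrix", "rq_format_error")
  if (is.null(rownames(boundaries))) rownames(boundaries) <- BOUNDARY_MARKERS
  rq_assert(setequal(rownames(boundaries), BOUNDARY_MARKERS),
            "boundary markers must be the 11 canonical markers",
            "rq_format_error")
  boundaries <- boundaries[BOUNDARY_MARKERS, , drop = FALSE]
  rq_assert(all(is.finite(boundaries)), "boundary traces must be finite",
            "rq_format_error")
  bad <- which(apply(boundaries, 2, function(b) any(diff(b) < 0)))
  if (length(bad) > 0)
    rq_stop(sprintf("boundaries cross at col %d", bad[1] - 1L),
            "rq_format_error")
  structure(list(pixels = pixels, axial_scale = axial_scale,
                 lateral_scale = lateral_scale, fovea_col = fovea_col,
                 boundaries = boundaries, eye_id = as.character(eye_id)),
            class = "bscan_record")
}

#' @export
print.bscan_record <- function(x, ...) {
  cat(sprintf("<bscan_record> %s: %d x %d px, %.2f um axial, %.2f um lateral, fovea col %d\n",
              x$eye_id, nrow(x$pixels), ncol(x$pixels),
              x$axial_scale, x$lateral_scale, x$fovea_col))
  invisible(x)
}

#' Multifocal ERG trace set
#'
#' The 103 per-hexagon first-order response traces of one eye, with ring
#' geometry. The standard eccentricity-scaled layout assigns 1, 6, 12, 18, 24
#' and 42 hexagons to rings R1--R6; the 19 hexagons of rings R1--R3 form the
#' central macular set.
#'
#' @param traces Numeric matrix, one column per hexagon (column names the
#'   hexagon ids), one row per time sample; units nV/deg^2.
#' @param sampling_rate Sampling rate in Hz.
#' @param ring_of_hexagon Named integer vector mapping each hexagon id to its
#'   ring 1--6.
#' @return An object of class `mferg_traceset`.
#' @export
mferg_traceset <- function(traces, sampling_rate, ring_of_hexagon) {
  rq_assert(is.matrix(traces), "traces must be a matrix", "rq_format_error")
  if (ncol(traces) != 103)
    rq_stop(sprintf("expected 103 hexagons, got %d", ncol(traces)),
            "rq_format_error")
  rq_assert(!is.null(colnames(traces)), "trace columns must be named by hexagon id",
            "rq_format_error")
  rq_assert(is_scalar_number(sampling_rate) && sampling_rate > 0,
            "sampling_rate must be > 0", "rq_format_error")
  ring_of_hexagon <- ring_of_hexagon[colnames(traces)]
  rq_assert(!anyNA(ring_of_hexagon),
            "every hexagon needs a ring assignment", "rq_format_error")
  rq_assert(all(ring_of_hexagon %in% 1:6), "ring indices must be in 1..6",
            "rq_format_error")
  central_ids <- names(ring_of_hexagon)[ring_of_hexagon <= 3]
  rq_assert(length(central_ids) == 19,
            sprintf("expected 19 central hexagons (rings 1-3), got %d",
                    length(central_ids)), "rq_format_error")
  structure(list(traces = traces, sampling_rate = sampling_rate,
                 ring_of_hexagon = ring_of_hexagon,
                 central_ids = central_ids),
            class = "mferg_traceset")
}

#' @export
print.mferg_traceset <- function(x, ...) {
  cat(sprintf("<mferg_traceset> 103 hexagons x %d samples @ %g Hz (%.1f ms)\n",
              nrow(x$traces), x$sampling_rate,
              1000 * nrow(x$traces) / x$sampling_rate))
  invisible(x)
}

## --- image reading ---------------------------------------------------------

read_gray_image <- function(path) {
  rq_assert(file.exists(path), sprintf("image file not found: %s", path),
            "rq_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    rq_stop(sprintf("unsupported image format '.%s' (%s)", ext, path),
            "rq_format_error"))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1)
      rq_stop(sprintf("multi-channel image not supported: %s", path),
              "rq_format_error")
    img <- img[, , 1]
  }
  img
}

read_json_sidecar <- function(path, required) {
  rq_assert(file.exists(path), sprintf("metadata file not found: %s", path),
            "rq_io_error")
  meta <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0)
    rq_stop(sprintf("metadata missing field(s): %s",
                    paste(missing, collapse = ", ")), "rq_format_error")
  meta
}

#' Read an en-face angiogram with its JSON sidecar
#'
#' Loads a single-channel 8/16-bit TIFF or PNG, rescales intensities to
#' \[0,1\] by the bit-depth maximum, and validates the sidecar metadata
#' (`scale_x`, `scale_y`, `plexus`, `quality`, `eye_id`).
#'
#' @param image_path Path to the grayscale image.
#' @param metadata_path Path to the JSON sidecar.
#' @return An [enface_angiogram()].
#' @export
read_angiogram <- function(image_path, metadata_path) {
  img <- read_gray_image(image_path)
  meta <- read_json_sidecar(metadata_path,
                            c("scale_x", "scale_y", "plexus", "quality"))
  enface_angiogram(img, scale_x = meta$scale_x, scale_y = meta$scale_y,
                   plexus = meta$plexus,
                   eye_id = if (!is.null(meta$eye_id)) meta$eye_id else "eye",
                   quality = meta$quality)
}

#' Read a structural B-scan with boundary table and JSON sidecar
#'
#' @param image_path Grayscale TIFF/PNG of the B-scan.
#' @param boundaries_path Long-format CSV with columns `marker,col,row`
#'   (0-based pixel coordinates).
#' @param metadata_path JSON sidecar with `axial_scale`, `lateral_scale`,
#'   `fovea_col` (0-based) and optionally `eye_id`.
#' @return A [bscan_record()].
#' @export
read_bscan <- function(image_path, boundaries_path, metadata_path) {
  img <- read_gray_image(image_path)
  meta <- read_json_sidecar(metadata_path,
                            c("axial_scale", "lateral_scale", "fovea_col"))
  rq_assert(file.exists(boundaries_path),
            sprintf("boundary file not found: %s", boundaries_path),
            "rq_io_error")
  tab <- utils::read.csv(boundaries_path, stringsAsFactors = FALSE)
  rq_assert(all(c("marker", "col", "row") %in% names(tab)),
            "boundary CSV needs columns marker,col,row", "rq_format_error")
  bmat <- matrix(NA_real_, 11, ncol(img), dimnames = list(BOUNDARY_MARKERS, NULL))
  for (m in BOUNDARY_MARKERS) {
    sub <- tab[tab$marker == m, ]
    rq_assert(nrow(sub) == ncol(img),
              sprintf("marker %s: expected %d columns, got %d", m, ncol(img),
                      nrow(sub)), "rq_format_error")
    bmat[m, sub$col + 1L] <- sub$row + 1
  }
  bscan_record(img, axial_scale = meta$axial_scale,
               lateral_scale = meta$lateral_scale,
               fovea_col = meta$fovea_col + 1L, boundaries = bmat,
               eye_id = if (!is.null(meta$eye_id)) meta$eye_id else "eye")
}

write_boundaries_csv <- function(boundaries, path) {
  nc <- ncol(boundaries)
  tab <- data.frame(
    marker = rep(rownames(boundaries), each = nc),
    col = rep(seq_len(nc) - 1L, times = nrow(boundaries)),
    row = as.vector(t(boundaries)) - 1
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read an mfERG trace set from CSV plus hexagon geometry
#'
#' The trace CSV holds one `time_ms` column and one column per hexagon
#' (header = hexagon id); the geometry CSV has columns `hexagon,ring` mapping
#' each hexagon to its eccentricity ring 1--6. The central hexagon set is
#' derived as all hexagons with ring <= 3 and must number 19.
#'
#' @param csv_path Trace CSV path.
#' @param geometry_path Geometry CSV path.
#' @return An [mferg_traceset()].
#' @export
read_traceset <- function(csv_path, geometry_path) {
  rq_assert(file.exists(csv_path), sprintf("trace file not found: %s", csv_path),
            "rq_io_error")
  rq_assert(file.exists(geometry_path),
            sprintf("geometry file not found: %s", geometry_path), "rq_io_error")
  tab <- utils::read.csv(csv_path, check.names = FALSE)
  rq_assert("time_ms" %in% names(tab), "trace CSV needs a time_ms column",
            "rq_format_error")
  t_ms <- tab$time_ms
  hex_cols <- setdiff(names(tab), "time_ms")
  if (length(hex_cols) != 103)
    rq_stop(sprintf("expected 103 hexagons, got %d", length(hex_cols)),
            "rq_format_error")
  dt <- diff(t_ms)
  rq_assert(all(dt > 0) && diff(range(dt)) < 1e-6 * stats::median(dt),
            "time_ms must be uniformly increasing", "rq_format_error")
  fs <- 1000 / stats::median(dt)
  geom <- utils::read.csv(geometry_path, stringsAsFactors = FALSE)
  rq_assert(all(c("hexagon", "ring") %in% names(geom)),
            "geometry CSV needs columns hexagon,ring", "rq_format_error")
  ring <- stats::setNames(as.integer(geom$ring), as.character(geom$hexagon))
  traces <- as.matrix(tab[, hex_cols, drop = FALSE])
  mferg_traceset(traces, sampling_rate = fs, ring_of_hexagon = ring)
}

write_traceset_csv <- function(ts, csv_path, geometry_path = NULL) {
  t_ms <- (seq_len(nrow(ts$traces)) - 1) / ts$sampling_rate * 1000
  tab <- data.frame(time_ms = t_ms, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(ts$traces, check.names = FALSE))
  utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(geometry_path))
    utils::write.csv(data.frame(hexagon = names(ts$ring_of_hexagon),
                                ring = as.integer(ts$ring_of_hexagon)),
                     geometry_path, row.names = FALSE)
  invisible(csv_path)
}

## --- manifest and metric tables --------------------------------------------

MANIFEST_COLS <- c("patient_id", "eye_id", "group", "angio_svp", "angio_icp",
                   "angio_dcp", "bscan", "boundaries", "traces")

#' Read and validate a cohort manifest
#'
#' @param path CSV with columns `patient_id,eye_id,group,angio_svp,angio_icp,
#'   angio_dcp,bscan,boundaries,traces`; file paths are interpreted relative
#'   to the manifest's directory unless absolute.
#' @return A data.frame of class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  rq_assert(file.exists(path), sprintf("manifest not found: %s", path),
            "rq_io_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  rq_assert(all(MANIFEST_COLS %in% names(tab)),
            sprintf("manifest needs columns: %s",
                    paste(MANIFEST_COLS, collapse = ",")), "rq_format_error")
  if (nrow(tab) == 0) rq_stop("no eyes in manifest", "rq_format_error")
  rq_assert(all(tab$group %in% GROUP_LEVELS),
            "group must be one of control, noDR, DR", "rq_format_error")
  rq_assert(!anyDuplicated(tab$eye_id),
            "an eye appears more than once in the manifest", "rq_format_error")
  base <- dirname(normalizePath(path))
  path_cols <- setdiff(MANIFEST_COLS, c("patient_id", "eye_id", "group"))
  for (pc in path_cols) {
    rel <- !grepl("^(/|[A-Za-z]:)", tab[[pc]]) & nzchar(tab[[pc]])
    tab[[pc]][rel] <- file.path(base, tab[[pc]][rel])
  }
  class(tab) <- c("cohort_manifest", "data.frame")
  tab
}

#' Write / read a metric table
#'
#' Plain CSV round-trip for per-eye metric tables; numeric columns are written
#' with enough digits that a round-trip preserves 6+ significant digits.
#'
#' @param metrics A data.frame of metrics.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a data.frame (reader).
#' @export
write_metrics <- function(metrics, path) {
  num <- vapply(metrics, is.numeric, logical(1))
  out <- metrics
  out[num] <- lapply(metrics[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
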