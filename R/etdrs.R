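## ETDRS macular grid geometry and retinal-layer thickness summarization.

ETDRS_SECTORS <- c("C1", "I-sup", "I-nas", "I-inf", "I-temp",
                   "O-sup", "O-nas", "O-inf", "O-temp")

#' ETDRS macular grid
#'
#' The standard nine-sector grid centered on the fovea: a central 1 mm
#' circle (C1) and inner (3 mm) and outer (6 mm) rings, each ring split into
#' superior/nasal/inferior/temporal quadrants at the +-45 degree diagonals.
#'
#' @param center_um Fovea position `(x, y)` in micrometers (default origin).
#' @param diameters_mm Central / inner / outer diameters (default 1, 3, 6).
#' @return Object of class `etdrs_grid`.
#' @export
etdrs_grid <- function(center_um = c(0, 0), diameters_mm = c(1, 3, 6)) {
  rq_assert(length(diameters_mm) == 3 && all(diff(diameters_mm) > 0),
            "ring diameters must be three increasing values")
  structure(list(center_um = center_um, radii_um = diameters_mm * 500),
            class = "etdrs_grid")
}

#' Sector of a point on the ETDRS grid
#'
#' Radial distance picks the ring (C1, inner, outer, or outside the 6 mm
#' disc); the angle against the +-45 degree diagonals picks the quadrant.
#' Coordinates are fovea-centered micrometers with y increasing upward
#' (superior) and, for a right eye (`laterality = "OD"`), x increasing toward
#' the nasal side; for `"OS"` nasal and temporal swap.
#'
#' @param point_um Numeric `(x, y)` in micrometers, or an n x 2 matrix.
#' @param grid An [etdrs_grid()].
#' @param laterality `"OD"` (right eye, default) or `"OS"`.
#' @return Sector id(s) among `C1, I-sup, I-nas, I-inf, I-temp, O-sup,
#'   O-nas, O-inf, O-temp`, or `"outside"`.
#' @export
sector_of <- function(point_um, grid = etdrs_grid(), laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  p <- if (is.matrix(point_um)) point_um else matrix(point_um, ncol = 2)
  x <- p[, 1] - grid$center_um[1]
  y <- p[, 2] - grid$center_um[2]
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x) * 180 / pi  # (-180, 180], 0 = +x, 90 = up/superior
  horiz <- if (laterality == "OD") c("nas", "temp") else c("temp", "nas")
  quad <- ifelse(ang > 45 & ang <= 135, "sup",
          ifelse(ang > -135 & ang <= -45, "inf",
          ifelse(ang > -45 & ang <= 45, horiz[1], horiz[2])))
  out <- ifelse(r < grid$radii_um[1], "C1",
         ifelse(r < grid$radii_um[2], paste0("I-", quad),
         ifelse(r <= grid$radii_um[3], paste0("O-", quad), "outside")))
  if (!is.matrix(point_um)) out[1] else out
}

#' Per-layer thickness on the ETDRS grid
#'
#' Computes, per column of each supplied B-scan, the seven reported layer
#' thicknesses (RNFL, GCL, IPL, INL, OPL, ONL, ORL) as the boundary-row
#' difference times the axial scale, assigns each column to its ETDRS sector
#' by its lateral offset from the fovea, and averages within sectors. A
#' single horizontal scan samples the nasal/temporal quadrants and C1; add a
#' vertical scan (orientation attribute `"vertical"`) to cover
#' superior/inferior. Per layer, the summary reports the C1 mean (`central`)
#' and the mean of the available inner+outer quadrant sector means
#' (`ring_mean`).
#'
#' @param bscans A [bscan_record()] or list of them; each record's
#'   `orientation` attribute (`"horizontal"` default, or `"vertical"`) says
#'   which grid axis the scan runs along.
#' @param grid An [etdrs_grid()].
#' @param laterality `"OD"` or `"OS"`.
#' @return Object of class `layer_thickness_map`: `sector_means` (7 layers x
#'   9 sectors matrix, micrometers, NA where unsampled), `summary`
#'   (data.frame layer, central, ring_mean), `total` (ILM-to-BM sector means).
#' @export
layer_thickness <- function(bscans, grid = etdrs_grid(),
                            laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  if (inherits(bscans, "bscan_record")) bscans <- list(bscans)
  layers <- names(LAYER_DEF)
  acc_sum <- matrix(0, length(layers) + 1, length(ETDRS_SECTORS),
                    dimnames = list(c(layers, "total"), ETDRS_SECTORS))
  acc_n <- acc_sum
  for (sc in bscans) {
    stopifnot(inherits(sc, "bscan_record"))
    orient <- attr(sc, "orientation")
    if (is.null(orient)) orient <- "horizontal"
    off_um <- (seq_len(ncol(sc$pixels)) - sc$fovea_col) * sc$lateral_scale
    pts <- if (orient == "horizontal") cbind(off_um, 0) else cbind(0, -off_um)
    ## vertical scans run superior -> inferior as the column index grows
    sect <- sector_of(pts, grid, laterality)
    b <- sc$boundaries
    th <- rbind(
      do.call(rbind, lapply(LAYER_DEF, function(ld)
        (b[ld[2], ] - b[ld[1], ]) * sc$axial_scale)),
      total = (b["BM", ] - b["ILM", ]) * sc$axial_scale)
    for (s in unique(sect)) {
      if (s == "outside") next
      sel <- sect == s
      acc_sum[, s] <- acc_sum[, s] + rowSums(th[, sel, drop = FALSE])
      acc_n[, s] <- acc_n[, s] + sum(sel)
    }
  }
  means <- acc_sum / ifelse(acc_n > 0, acc_n, NA)
  sector_means <- means[layers, , drop = FALSE]
  quad_cols <- setdiff(ETDRS_SECTORS, "C1")
  summary <- data.frame(
    layer = layers,
    central = unname(sector_means[, "C1"]),
    ring_mean = apply(sector_means[, quad_cols, drop = FALSE], 1,
                      function(v) mean(v, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  structure(list(sector_means = sector_means, summary = summary,
                 total = means["total", ]),
            class = "layer_thickness_map")
}

#' @export
print.layer_thickness_map <- function(x, ...) {
  cat("<layer_thickness_map> (um)\n")
  print(round(x$summary, 2))
  invisible(x)
}
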