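## Hyperreflective-foci (HRF) spot calling on structural B-scans.
##
## Candidates come from a scale-normalized Laplacian-of-Gaussian ladder
## spanning 10-40 um equivalent diameters (anisotropic pixel scales are
## handled by blurring with per-axis sigmas in pixels and forming the
## Laplacian in micrometer units). Candidates are then filtered by the
## grading criteria: maximum diameter <= 30 um, moderate reflectivity
## (within +-20% of the RNFL band mean of the same scan), and absence of
## back-shadowing (sub-focus column attenuation ratio >= 0.8), and assigned
## to the inner- or outer-retina compartment by center depth.

## mean intensity inside the RNFL band (ILM..RNFL/GCL) over the central window
rnfl_band_mean <- function(bscan, window_mm = 1.5) {
  nc <- ncol(bscan$pixels)
  cols <- which(abs((seq_len(nc) - bscan$fovea_col) * bscan$lateral_scale)
                <= window_mm * 1000 + 1e-6)
  vals <- unlist(lapply(cols, function(j) {
    r1 <- ceiling(bscan$boundaries["ILM", j])
    r2 <- floor(bscan$boundaries["RNFL_GCL", j])
    if (r2 >= r1) bscan$pixels[r1:r2, j] else NULL
  }))
  mean(vals)
}

## compartment row bounds at a given column; convention "fig1" (default):
## IR = ILM .. lower IPL border, OR = upper ONL .. RPE/BM.
## convention "text": IR = upper INL .. lower OPL border.
compartment_bounds <- function(bscan, col, ir_definition = c("fig1", "text")) {
  ir_definition <- match.arg(ir_definition)
  b <- bscan$boundaries[, col]
  ir <- if (ir_definition == "fig1") c(b["ILM"], b["IPL_INL"])
        else c(b["IPL_INL"], b["OPL_ONL"])
  list(IR = unname(ir), OR = unname(c(b["OPL_ONL"], b["BM"])))
}

#' Detect HRF candidate blobs on a B-scan
#'
#' Multiscale LoG blob detection restricted to the central 3 mm of the scan
#' (columns within +-1.5 mm of the fovea, both ends inclusive) and to rows
#' between ILM and RPE/BM. Each candidate carries a diameter measured as the
#' lateral half-maximum width of its profile, its mean reflectivity over that
#' footprint, and its lateral contrast against same-depth flanks.
#'
#' @param bscan A [bscan_record()].
#' @param d_min_um,d_max_um Diameter range the scale ladder spans.
#' @param n_scales Number of ladder scales (geometric spacing).
#' @param threshold Minimum scale-normalized response (intensity units).
#' @param window_mm Half-width of the central analysis window (mm).
#' @param ridge_frac Minimum fraction of the response carried by the lateral
#'   Laplacian component (0.5 for an isotropic blob, ~0 for a horizontal
#'   layer band); suppresses band/ridge responses.
#' @param presmooth_um Gaussian speckle pre-smoothing (micrometers) applied
#'   once before the ladder; the scale ladder and diameter estimate account
#'   for it (a blob of diameter d peaks at sigma^2 = d^2/8 + presmooth^2).
#' @return Data.frame: `row, col, diameter_um, response, reflectivity,
#'   contrast`.
#' @export
detect_hrf_candidates <- function(bscan, d_min_um = 10, d_max_um = 40,
                                  n_scales = 8, threshold = 0.08,
                                  window_mm = 1.5, ridge_frac = 0.25,
                                  presmooth_um = 6) {
  stopifnot(inherits(bscan, "bscan_record"))
  nr <- nrow(bscan$pixels); nc <- ncol(bscan$pixels)
  ax <- bscan$axial_scale; lat <- bscan$lateral_scale
  if (nc * lat < 2 * window_mm * 1000)
    rq_stop(sprintf("scan narrower than %g mm", 2 * window_mm), "rq_format_error")
  px <- if (presmooth_um > 0)
    blur_aniso(bscan$pixels, presmooth_um / ax, presmooth_um / lat)
  else bscan$pixels

  ## ladder indexed by target diameter; extra blur needed on the already
  ## pre-smoothed image is sqrt(sigma_d^2 - presmooth^2)
  diams_um <- exp(seq(log(d_min_um), log(d_max_um), length.out = n_scales))
  sigmas_um <- sqrt(diams_um^2 / 8 + presmooth_um^2)
  resp <- array(0, c(nr, nc, n_scales))
  resp_lat <- array(0, c(nr, nc, n_scales))
  for (k in seq_len(n_scales)) {
    s_um <- sigmas_um[k]
    extra <- sqrt(max(0, s_um^2 - presmooth_um^2))
    sm <- blur_aniso(px, extra / ax, extra / lat)
    lap_ax <- (shift_mat(sm, 1, 0) + shift_mat(sm, -1, 0) - 2 * sm) / ax^2
    lap_lat <- (shift_mat(sm, 0, 1) + shift_mat(sm, 0, -1) - 2 * sm) / lat^2
    resp[, , k] <- -s_um^2 * (lap_ax + lap_lat)
    resp_lat[, , k] <- -s_um^2 * lap_lat
  }

  ## local maxima over space and scale; layer bands are ridges with a near-
  ## zero lateral Laplacian and are rejected by the blobness criterion
  cand <- NULL
  for (k in seq_len(n_scales)) {
    r <- resp[, , k]
    is_max <- r > threshold & resp_lat[, , k] >= ridge_frac * r
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      is_max <- is_max & r >= shift_mat(r, dr, dc, fill = -Inf)
    }
    if (k > 1) is_max <- is_max & r >= resp[, , k - 1]
    if (k < n_scales) is_max <- is_max & r >= resp[, , k + 1]
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) > 0)
      cand <- rbind(cand, data.frame(row = idx[, 1], col = idx[, 2],
                                     scale = k, response = r[idx]))
  }
  empty <- data.frame(row = integer(0), col = integer(0),
                      diameter_um = numeric(0), response = numeric(0),
                      reflectivity = numeric(0), contrast = numeric(0))
  if (is.null(cand) || nrow(cand) == 0) return(empty)

  ## keep centers inside the analysis window (closed at both ends; half a
  ## pixel of tolerance so a center at exactly the window edge, which pixel
  ## quantization may place a fraction of a pixel outside, stays included
  ## while one a full pixel beyond is excluded) and inside the retina
  off_um <- abs((cand$col - bscan$fovea_col) * lat)
  inside <- off_um <= window_mm * 1000 + lat / 2
  ilm <- bscan$boundaries["ILM", cand$col]
  bm <- bscan$boundaries["BM", cand$col]
  cand <- cand[inside & cand$row >= ilm & cand$row <= bm, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  ## greedy non-maximum suppression in micrometer distance
  cand <- cand[order(-cand$response), , drop = FALSE]
  keep <- logical(nrow(cand))
  ky <- numeric(0); kx <- numeric(0); kd <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    d_i <- diams_um[cand$scale[i]]
    y <- cand$row[i] * ax; x <- cand$col[i] * lat
    if (length(ky) == 0 ||
        all(sqrt((ky - y)^2 + (kx - x)^2) > pmax(30, pmax(kd, d_i) * 0.9))) {
      keep[i] <- TRUE
      ky <- c(ky, y); kx <- c(kx, x); kd <- c(kd, d_i)
    }
  }
  cand <- cand[keep, , drop = FALSE]

  ## Size: lateral half-maximum width through the blob center on the
  ## pre-smoothed image. A Gaussian blur leaves the half-level crossing of a
  ## step edge at the edge, so the lateral profile width recovers the focus
  ## diameter without being corrupted by the bright layer bands above or
  ## below (which foil a scale-space estimate for foci near the RNFL band).
  ## Reflectivity is the raw-image mean over the measured footprint;
  ## contrast compares it with flanking segments at the same depth.
  raw <- bscan$pixels
  max_r_px <- ceiling(d_max_um / lat) + 2
  meas <- vapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand$row[i]; c0 <- cand$col[i]
    rh0 <- max(1, round(diams_um[cand$scale[i]] / 2 / ax * 0.7))
    rr <- max(1, r0 - rh0):min(nr, r0 + rh0)
    ccs <- max(1, c0 - max_r_px):min(nc, c0 + max_r_px)
    prof <- colMeans(px[rr, ccs, drop = FALSE])
    names(prof) <- ccs
    peak <- prof[as.character(c0)]
    far <- abs(ccs - c0) * lat >= d_max_um * 0.75
    flank_sm <- if (any(far)) mean(prof[far]) else min(prof)
    half <- (peak + flank_sm) / 2
    below <- prof < half
    li <- ccs[ccs < c0][rev(which(below[ccs < c0]))][1]  # nearest below-half left
    ri <- ccs[ccs > c0][which(below[ccs > c0])][1]
    ## sub-pixel crossings by linear interpolation
    xl <- if (is.na(li)) min(ccs) else {
      pa <- prof[as.character(li + 1L)]; pb <- prof[as.character(li)]
      li + (half - pb) / max(1e-9, pa - pb)
    }
    xr <- if (is.na(ri)) max(ccs) else {
      pa <- prof[as.character(ri - 1L)]; pb <- prof[as.character(ri)]
      ri - (half - pb) / max(1e-9, pa - pb)
    }
    d_lat <- max(lat, (xr - xl) * lat)
    ## footprint stats on the raw image
    rhf <- max(1, d_lat / 2 / ax); chf <- max(1, d_lat / 2 / lat)
    rr2 <- max(1, round(r0 - rhf)):min(nr, round(r0 + rhf))
    cc2 <- max(1, round(c0 - 3 * chf)):min(nc, round(c0 + 3 * chf))
    sub <- raw[rr2, cc2, drop = FALSE]
    d2 <- outer(((rr2 - r0) / rhf)^2, ((cc2 - c0) / chf)^2, "+")
    core <- mean(sub[d2 <= 0.8^2])
    dc <- abs(cc2 - c0) / chf
    fsel <- dc >= 1.5 & dc <= 3
    flank <- if (any(fsel)) mean(sub[abs(rr2 - r0) <= 0.8 * rhf, fsel]) else core
    c(d_lat, core, if (flank > 1e-9) core / flank else 1)
  }, numeric(3))
  cand$diameter_um <- meas[1, ]
  cand$reflectivity <- meas[2, ]
  cand$contrast <- meas[3, ]
  cand[, c("row", "col", "diameter_um", "response", "reflectivity",
           "contrast")]
}

#' Filter HRF candidates by the grading criteria
#'
#' Keeps a candidate iff (a) diameter <= `max_diameter_um`; (b) mean
#' reflectivity within `1 +- refl_tol` of the scan's RNFL band mean;
#' (c) shadow score -- mean intensity of the column strip from below the
#' focus down to RPE/BM, divided by the same strip in flanking columns -- is
#' >= `shadow_min`; and assigns the compartment (IR/OR) by center depth,
#' discarding candidates in neither.
#'
#' @param candidates Output of [detect_hrf_candidates()].
#' @param bscan The same [bscan_record()].
#' @param max_diameter_um Size criterion (default 30).
#' @param refl_tol Relative reflectivity tolerance (default 0.2).
#' @param shadow_min Minimum shadow score (default 0.8).
#' @param flank_cols Width of each flanking strip in columns (default 3).
#' @param min_contrast Minimum blob-core-to-surround intensity ratio; a
#'   focus must stand out from its background band the way a graded focus
#'   does (speckle bumps on bright layer bands do not).
#' @param ir_definition `"fig1"` (IR = ILM to lower IPL, default) or
#'   `"text"` (IR = upper INL to lower OPL).
#' @return Data.frame of class `hrf_foci`: `row, col, diameter_um,
#'   reflectivity_rel, shadow_score, compartment`.
#' @export
filter_hrf <- function(candidates, bscan, max_diameter_um = 30,
                       refl_tol = 0.2, shadow_min = 0.8, flank_cols = 3,
                       min_contrast = 1.5, ir_definition = "fig1") {
  stopifnot(inherits(bscan, "bscan_record"))
  px <- bscan$pixels
  nr <- nrow(px); nc <- ncol(px)
  ax <- bscan$axial_scale; lat <- bscan$lateral_scale
  rnfl <- rnfl_band_mean(bscan)
  out <- data.frame(row = integer(0), col = integer(0),
                    diameter_um = numeric(0), reflectivity_rel = numeric(0),
                    shadow_score = numeric(0), compartment = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    if (cd$diameter_um > max_diameter_um) next
    if (!is.null(cd$contrast) && cd$contrast < min_contrast) next
    rel <- cd$reflectivity / rnfl
    if (rel < 1 - refl_tol || rel > 1 + refl_tol) next
    ## shadow score: focus-width strip below the focus down to RPE/BM vs the
    ## same rows in flanking strips
    hw <- ceiling(cd$diameter_um / 2 / lat)
    r_lo <- min(nr, ceiling(cd$row + cd$diameter_um / 2 / ax) + 2)
    r_hi <- max(r_lo, floor(bscan$boundaries["BM", cd$col]))
    cc <- max(1, cd$col - hw):min(nc, cd$col + hw)
    left <- (cd$col - hw - flank_cols):(cd$col - hw - 1)
    right <- (cd$col + hw + 1):(cd$col + hw + flank_cols)
    fl <- c(left, right); fl <- fl[fl >= 1 & fl <= nc]
    below <- mean(px[r_lo:r_hi, cc])
    flank <- mean(px[r_lo:r_hi, fl])
    score <- if (flank > 1e-9) below / flank else 1
    if (score < shadow_min) next
    bounds <- compartment_bounds(bscan, cd$col, ir_definition)
    comp <- if (cd$row >= bounds$IR[1] && cd$row <= bounds$IR[2]) "IR"
            else if (cd$row >= bounds$OR[1] && cd$row <= bounds$OR[2]) "OR"
            else next
    out <- rbind(out, data.frame(row = cd$row, col = cd$col,
                                 diameter_um = cd$diameter_um,
                                 reflectivity_rel = rel, shadow_score = score,
                                 compartment = comp, stringsAsFactors = FALSE))
  }
  class(out) <- c("hrf_foci", "data.frame")
  out
}

#' Count retained hyperreflective foci per compartment
#'
#' Runs detection and filtering with one call and returns the inner- and
#' outer-retina counts.
#'
#' @param bscan A [bscan_record()].
#' @param ... Tunables forwarded to [detect_hrf_candidates()] and
#'   [filter_hrf()] (matched by name).
#' @return List: `n_ir`, `n_or`, `foci` (the retained [filter_hrf()] table).
#' @export
count_hrf <- function(bscan, ...) {
  dots <- list(...)
  det_args <- dots[names(dots) %in%
                     names(formals(detect_hrf_candidates))]
  fil_args <- dots[names(dots) %in% names(formals(filter_hrf))]
  cand <- do.call(detect_hrf_candidates, c(list(bscan), det_args))
  foci <- do.call(filter_hrf, c(list(cand, bscan), fil_args))
  list(n_ir = sum(foci$compartment == "IR"),
       n_or = sum(foci$compartment == "OR"), foci = foci)
}
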