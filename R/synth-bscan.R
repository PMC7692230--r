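## Synthetic structural B-scan generator: horizontal reflectivity bands from a
## layer profile, multiplicative gamma speckle, and planted hyperreflective
## foci with controlled diameter, reflectivity class and optional back-shadow.

#' Default layer profile for synthetic B-scans
#'
#' Flat boundary depths (micrometers below the image top) for the 11
#' segmentation markers, with per-band mean reflectivities. Thicknesses are
#' typical macular values; the retinal nerve fiber layer and the outer
#' ellipsoid-zone/RPE complex are the bright bands, the nuclear layers dark.
#'
#' @param ilm_depth_um Depth of the internal limiting membrane.
#' @return List with `boundaries_um` (named, 11 markers), `band_reflectivity`
#'   (named by the band's upper marker), `vitreous`, `below`.
#' @export
default_layer_profile <- function(ilm_depth_um = 150) {
  th <- c(RNFL_GCL = 20, GCL_IPL = 35, IPL_INL = 33, INL_OPL = 32,
          OPL_ONL = 28, ELM = 70, MZ_EZ = 15, EZ_OS = 12, OS_RPE = 25,
          BM = 28)
  depths <- ilm_depth_um + cumsum(c(ILM = 0, th))
  refl <- c(ILM = 0.55,      # RNFL band (below ILM): the reference band
            RNFL_GCL = 0.28, # GCL
            GCL_IPL = 0.32,  # IPL
            IPL_INL = 0.22,  # INL
            INL_OPL = 0.32,  # OPL
            OPL_ONL = 0.12,  # ONL
            ELM = 0.25,      # myoid zone
            MZ_EZ = 0.65,    # ellipsoid zone
            EZ_OS = 0.20,    # outer segments
            OS_RPE = 0.60)   # RPE complex
  list(boundaries_um = depths, band_reflectivity = refl,
       vitreous = 0.04, below = 0.06)
}

#' Specify foci to plant in a synthetic B-scan
#'
#' @param compartment `"IR"` (inner retina) or `"OR"` (outer retina).
#' @param lateral_um Lateral offset of the focus center from the fovea
#'   (micrometers; negative = left).
#' @param diameter_um Focus diameter in micrometers.
#' @param reflectivity `"moderate"` (equal to the RNFL band mean) or `"high"`
#'   (1.5x the RNFL band mean).
#' @param shadow Plant a back-shadow (columns under the focus attenuated to
#'   half intensity down to RPE/BM)?
#' @param depth_frac Position within the compartment's plantable band, 0 =
#'   top; `NA` draws it uniformly.
#' @return A data.frame, one row per focus.
#' @export
foci_spec <- function(compartment = "IR", lateral_um = 0, diameter_um = 25,
                      reflectivity = "moderate", shadow = FALSE,
                      depth_frac = NA_real_) {
  data.frame(compartment = compartment, lateral_um = lateral_um,
             diameter_um = diameter_um, reflectivity = reflectivity,
             shadow = shadow, depth_frac = depth_frac,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic structural B-scan with planted foci
#'
#' Renders horizontal reflectivity bands from a layer profile, plants the
#' requested hyperreflective foci as elliptical disks (circular in
#' micrometers), applies optional back-shadowing (0.5x attenuation of all
#' pixels below a shadowed focus down to RPE/BM), and multiplies by gamma
#' speckle. Speckle emulates the residual texture of frame-averaged scans:
#' the per-pixel multiplier is the mean of `n_frames` draws from
#' Gamma(shape, rate = shape), blended with 1 by `speckle_level`
#' (0 = noise-free).
#'
#' Moderate-reflectivity foci are drawn at the RNFL band mean, "high" at 1.5x
#' it. Inner-retina foci are planted between the RNFL/GCL boundary and the
#' lower IPL border, outer-retina foci inside the ONL, so that plants sit on
#' the darker bands where real foci are graded.
#'
#' @param size_px `c(rows, cols)` image size.
#' @param axial_scale,lateral_scale Micrometers per pixel.
#' @param layer_profile See [default_layer_profile()].
#' @param foci A [foci_spec()] data.frame (possibly 0 rows).
#' @param speckle_level Speckle blend weight in \[0,1\].
#' @param speckle_shape Gamma shape of single-frame speckle (default 4).
#' @param n_frames Frames averaged per scan (default 7).
#' @param seed Integer RNG seed.
#' @param orientation `"horizontal"` or `"vertical"` scan through the fovea.
#' @param eye_id Identifier carried into the record.
#' @return List with `bscan` (a [bscan_record()]) and `truth` (class
#'   `foci_truth`: data.frame of planted foci with center row/col in pixels).
#' @export
generate_bscan <- function(size_px = c(320, 600), axial_scale = 3.9,
                           lateral_scale = 5.86,
                           layer_profile = default_layer_profile(),
                           foci = foci_spec()[0, ], speckle_level = 1,
                           speckle_shape = 4, n_frames = 7, seed = NULL,
                           orientation = "horizontal", eye_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  nr <- size_px[1]; nc <- size_px[2]
  fovea_col <- as.integer(round(nc / 2))
  depths_um <- layer_profile$boundaries_um[BOUNDARY_MARKERS]
  depths_px <- depths_um / axial_scale + 1  # 1-based row coordinates
  rq_assert(max(depths_px) < nr, "image too shallow for the layer profile")

  ## band image: reflectivity by depth, flat across columns
  row_depth_um <- (seq_len(nr) - 1) * axial_scale
  band_refl <- layer_profile$band_reflectivity[BOUNDARY_MARKERS[-11]]
  lvl <- rep(layer_profile$vitreous, nr)
  for (i in 1:10) {
    sel <- row_depth_um >= depths_um[i] & row_depth_um < depths_um[i + 1]
    lvl[sel] <- band_refl[i]
  }
  lvl[row_depth_um >= depths_um["BM"]] <- layer_profile$below
  base <- matrix(lvl, nr, nc)

  rnfl_mean <- unname(band_refl["ILM"])

  ## plantable bands per compartment (row coordinates)
  band_for <- function(comp) {
    if (comp == "IR") c(depths_px["RNFL_GCL"], depths_px["IPL_INL"])
    else c(depths_px["OPL_ONL"], depths_px["ELM"])
  }

  n_foci <- nrow(foci)
  truth <- data.frame(row = integer(0), col = integer(0),
                      diameter_um = numeric(0), reflectivity = character(0),
                      has_shadow = logical(0), compartment = character(0),
                      stringsAsFactors = FALSE)
  if (n_foci > 0) {
    for (i in seq_len(n_foci)) {
      f <- foci[i, ]
      band <- band_for(f$compartment)
      r_half_px <- f$diameter_um / 2 / axial_scale
      c_half_px <- f$diameter_um / 2 / lateral_scale
      lo <- band[1] + r_half_px; hi <- band[2] - r_half_px
      if (lo > hi)
        rq_stop(sprintf("focus %d (%.0f um) exceeds its %s band thickness",
                        i, f$diameter_um, f$compartment), "rq_generator_error")
      frac <- if (is.na(f$depth_frac)) stats::runif(1) else f$depth_frac
      r0 <- lo + frac * (hi - lo)
      c0 <- fovea_col + f$lateral_um / lateral_scale
      rq_assert(c0 >= 1 + c_half_px && c0 <= nc - c_half_px,
                "focus center outside image", "rq_generator_error")
      level <- if (f$reflectivity == "high") min(1, 1.5 * rnfl_mean) else rnfl_mean
      rr <- which(abs(seq_len(nr) - r0) <= r_half_px + 1)
      ccs <- which(abs(seq_len(nc) - c0) <= c_half_px + 1)
      for (ri in rr) for (ci in ccs) {
        if (((ri - r0) / r_half_px)^2 + ((ci - c0) / c_half_px)^2 <= 1)
          base[ri, ci] <- level
      }
      if (isTRUE(f$shadow)) {
        sr <- seq(from = min(nr, ceiling(r0 + r_half_px + 1)),
                  to = min(nr, floor(depths_px["BM"])))
        sc <- round(c0) + seq(-ceiling(c_half_px), ceiling(c_half_px))
        sc <- sc[sc >= 1 & sc <= nc]
        base[sr, sc] <- base[sr, sc] * 0.5
      }
      truth <- rbind(truth, data.frame(
        row = round(r0), col = round(c0), diameter_um = f$diameter_um,
        reflectivity = f$reflectivity, has_shadow = isTRUE(f$shadow),
        compartment = f$compartment, stringsAsFactors = FALSE))
    }
  }

  px <- base
  if (speckle_level > 0) {
    mult <- matrix(rowMeans(matrix(stats::rgamma(nr * nc * n_frames,
                                                 shape = speckle_shape,
                                                 rate = speckle_shape),
                                   nr * nc, n_frames)), nr, nc)
    px <- base * ((1 - speckle_level) + speckle_level * mult)
  }
  px <- pmin(pmax(px, 0), 1)

  bmat <- matrix(rep(depths_px, nc), 11, nc,
                 dimnames = list(BOUNDARY_MARKERS, NULL))
  rec <- bscan_record(px, axial_scale = axial_scale,
                      lateral_scale = lateral_scale, fovea_col = fovea_col,
                      boundaries = bmat, eye_id = eye_id)
  attr(rec, "orientation") <- orientation
  class(truth) <- c("foci_truth", "data.frame")
  list(bscan = rec, truth = truth)
}
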