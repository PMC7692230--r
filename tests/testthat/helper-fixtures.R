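## Shared fixtures and independent oracles for the test suite.

## Brute-force box counter: explicit nested loops over the box grid, kept
## deliberately independent of the package's vectorized implementation.
brute_force_box_count <- function(mask, s) {
  n_occupied <- 0L
  for (bi in seq(1, nrow(mask), by = s)) {
    for (bj in seq(1, ncol(mask), by = s)) {
      rows <- bi:min(bi + s - 1, nrow(mask))
      cols <- bj:min(bj + s - 1, ncol(mask))
      hit <- FALSE
      for (r in rows) {
        for (cc in cols) {
          if (mask[r, cc]) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) n_occupied <- n_occupied + 1L
    }
  }
  n_occupied
}

## Greedy truth-to-detection matching within a micrometer radius; returns
## confusion counts plus per-match compartment agreement.
match_foci <- function(foci, truth, axial_scale = 3.9, lateral_scale = 5.86,
                       radius_um = 40) {
  used <- rep(FALSE, nrow(foci))
  tp <- 0L; fn <- 0L; comp_ok <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt(((foci$row - truth$row[i]) * axial_scale)^2 +
                ((foci$col - truth$col[i]) * lateral_scale)^2)
    j <- which(!used & d < radius_um)
    if (length(j) > 0) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
      if (foci$compartment[j[1]] == truth$compartment[i]) comp_ok <- comp_ok + 1L
    } else fn <- fn + 1L
  }
  list(tp = tp, fn = fn, fp = sum(!used), comp_ok = comp_ok, used = used)
}

## B-scan record with prescribed per-column layer thicknesses (micrometers);
## pixels are irrelevant for thickness summarization and are left flat.
bscan_from_thickness <- function(thickness_fun, n_cols = 1100,
                                 lateral_scale = 5.86, axial_scale = 3.9,
                                 orientation = "horizontal") {
  fovea <- as.integer(n_cols / 2)
  markers <- c("ILM", "RNFL_GCL", "GCL_IPL", "IPL_INL", "INL_OPL", "OPL_ONL",
               "ELM", "MZ_EZ", "EZ_OS", "OS_RPE", "BM")
  b <- matrix(0, 11, n_cols, dimnames = list(markers, NULL))
  for (j in seq_len(n_cols)) {
    x_um <- abs(j - fovea) * lateral_scale
    th <- thickness_fun(x_um)  # named vector of the 10 band thicknesses
    b[, j] <- (100 + cumsum(c(0, th))) / axial_scale + 1
  }
  rec <- bscan_record(matrix(0.5, 260, n_cols), axial_scale, lateral_scale,
                      fovea, b)
  attr(rec, "orientation") <- orientation
  rec
}

default_bands <- c(RNFL_GCL = 20, GCL_IPL = 35, IPL_INL = 33, INL_OPL = 32,
                   OPL_ONL = 28, ELM = 70, MZ_EZ = 15, EZ_OS = 12,
                   OS_RPE = 25, BM = 28)

## independent z-score oracle used against classify_abnormal
oracle_classify <- function(eye_features, db, central_ids, z_it = 2,
                            z_amp = -2) {
  flags <- logical(length(central_ids))
  for (k in seq_along(central_ids)) {
    h <- central_ids[k]
    mu_it <- db$mu[db$hexagon == h & db$feature == "p1_it"]
    sd_it <- db$sigma[db$hexagon == h & db$feature == "p1_it"]
    mu_am <- db$mu[db$hexagon == h & db$feature == "p1_amp"]
    sd_am <- db$sigma[db$hexagon == h & db$feature == "p1_amp"]
    ef <- eye_features[eye_features$hexagon == h, ]
    zi <- (ef$p1_it - mu_it) / sd_it
    za <- (ef$p1_amp - mu_am) / sd_am
    flags[k] <- (zi >= z_it) | (za <= z_amp)
  }
  flags
}
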