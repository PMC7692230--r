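## Three-group synthetic cohorts with planted, plexus-specific effects.
##
## The statistical structure mirrors the study design: two eyes per patient
## sharing a patient-level Gaussian multiplier (SD 5% by default), group
## effects applied multiplicatively to per-plexus vessel density and
## branching complexity, additively to the P1 implicit time, and as a shift
## of the Poisson mean of hyperreflective-focus counts.

#' Planted group effects for synthetic cohorts
#'
#' Defaults mirror the direction of the reported group differences: the
#' no-retinopathy group loses superficial-plexus density and complexity and
#' shows delayed central P1 implicit times; the mild-retinopathy group loses
#' intermediate-plexus complexity; both diabetic groups carry more
#' hyperreflective foci.
#'
#' @param noDR,DR Lists with elements `density` (named multiplier per plexus),
#'   `branch` (named branching-probability multiplier per plexus),
#'   `p1_it_shift` (ms, added), `hrf_shift` (added to the Poisson mean of
#'   HRF counts).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(
    noDR = list(density = c(SVP = 0.85, ICP = 1, DCP = 1),
                branch = c(SVP = 0.7, ICP = 1, DCP = 0.8),
                p1_it_shift = 2, hrf_shift = 4),
    DR = list(density = c(SVP = 1, ICP = 0.9, DCP = 1),
              branch = c(SVP = 1, ICP = 0.7, DCP = 1),
              p1_it_shift = 1, hrf_shift = 4)) {
  for (g in list(noDR, DR)) {
    rq_assert(all(g$density > 0) && all(g$branch > 0),
              "effect multipliers must be > 0")
  }
  identity_eff <- list(density = c(SVP = 1, ICP = 1, DCP = 1),
                       branch = c(SVP = 1, ICP = 1, DCP = 1),
                       p1_it_shift = 0, hrf_shift = 0)
  structure(list(control = identity_eff, noDR = noDR, DR = DR),
            class = "effect_spec")
}

#' Identity effects (null cohort)
#' @return An [effect_spec()] with all multipliers 1 and shifts 0.
#' @export
identity_effects <- function() {
  eff <- effect_spec()
  eff$noDR <- eff$control
  eff$DR <- eff$control
  eff
}

#' Baseline (control-group) generator parameters
#'
#' Plexus-wise target vessel densities and branching probabilities, HRF
#' Poisson means, and control mfERG wave parameters used by the cohort
#' generators.
#'
#' @return Named list of baseline parameters.
#' @export
cohort_baseline <- function() {
  list(density = c(SVP = 0.34, ICP = 0.30, DCP = 0.32),
       branch = c(SVP = 0.02, ICP = 0.02, DCP = 0.02),
       caliber_px = c(SVP = 3, ICP = 3, DCP = 3),
       hrf_mean = c(IR = 1.0, OR = 0.7),
       p1_it = 30, n1_it = 15, p1_amp_r1 = 80, noise_sd_frac = 0.05,
       patient_sd = 0.05, eye_sd = 0.03,
       it_patient_sd = 0.8, it_eye_sd = 1.0)
}

#' Simulate per-eye cohort metrics without rendering images
#'
#' Draws the planted ground-truth metric structure directly: per patient a
#' shared Gaussian multiplier (SD `patient_sd`) scales all of that patient's
#' metrics, each eye adds independent measurement-level noise (SD `eye_sd`,
#' multiplicative), group effects act as in [effect_spec()]. This is the
#' model the repeated-measures statistics are meant to recover, and is what
#' the calibration and power checks run on.
#'
#' @param n_per_group Patients per group (each contributes two eyes).
#' @param effects An [effect_spec()].
#' @param seed Integer RNG seed.
#' @param baseline See [cohort_baseline()].
#' @return Data.frame: patient_id, eye_id, group, vad_svp/icp/dcp, hrf_ir,
#'   hrf_or, p1_it_central.
#' @export
simulate_cohort_metrics <- function(n_per_group = 11, effects = effect_spec(),
                                    seed = NULL,
                                    baseline = cohort_baseline()) {
  if (!is.null(seed)) set.seed(seed)
  rq_assert(n_per_group >= 2, "n_per_group must be >= 2")
  rows <- list()
  pid <- 0L
  for (g in GROUP_LEVELS) {
    eff <- effects[[g]]
    for (i in seq_len(n_per_group)) {
      pid <- pid + 1L
      pmult <- stats::rnorm(1, 1, baseline$patient_sd)
      pit <- stats::rnorm(1, 0, baseline$it_patient_sd)
      for (e in 1:2) {
        emult <- stats::rnorm(3, 1, baseline$eye_sd)
        dens <- baseline$density * eff$density * pmult * emult
        hrf <- stats::rpois(2, pmax(0.01, (baseline$hrf_mean +
                 eff$hrf_shift * baseline$hrf_mean / sum(baseline$hrf_mean)) *
                 pmult))
        p1 <- baseline$p1_it + eff$p1_it_shift + pit +
          stats::rnorm(1, 0, baseline$it_eye_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%03d", pid),
          eye_id = sprintf("P%03d_E%d", pid, e), group = g,
          vad_svp = dens["SVP"], vad_icp = dens["ICP"], vad_dcp = dens["DCP"],
          hrf_ir = hrf[1], hrf_or = hrf[2], p1_it_central = p1,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a rendered synthetic cohort on disk
#'
#' For each patient (two eyes sharing a patient-level multiplier) writes
#' per-eye SVP/ICP/DCP angiograms (16-bit TIFF + JSON sidecars), a structural
#' B-scan with Poisson-drawn compliant foci (TIFF + boundary CSV + JSON), and
#' an mfERG trace-set CSV, plus a shared hexagon-geometry CSV, a cohort
#' manifest and a ground-truth table.
#'
#' @param n_per_group Patients per group, >= 2.
#' @param effects An [effect_spec()].
#' @param seed Integer RNG seed.
#' @param dir Output directory (created if needed).
#' @param image_size Angiogram side length in pixels.
#' @param bscan_size `c(rows, cols)` B-scan size.
#' @param baseline See [cohort_baseline()].
#' @return List: `manifest_path`, `truth` (data.frame, also written as
#'   `truth.csv`), invisibly.
#' @export
generate_cohort <- function(n_per_group = 2, effects = effect_spec(),
                            seed = 1, dir = tempfile("cohort"),
                            image_size = 160, bscan_size = c(300, 600),
                            baseline = cohort_baseline()) {
  rq_assert(n_per_group >= 2, "n_per_group must be >= 2")
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom_path <- file.path(dir, "hex_geometry.csv")
  geom <- mferg_hex_geometry()
  utils::write.csv(data.frame(hexagon = names(geom), ring = as.integer(geom)),
                   geom_path, row.names = FALSE)
  manifest <- NULL
  truth <- NULL
  pid <- 0L
  for (g in GROUP_LEVELS) {
    eff <- effects[[g]]
    for (i in seq_len(n_per_group)) {
      pid <- pid + 1L
      patient <- sprintf("P%03d", pid)
      pmult <- stats::rnorm(1, 1, baseline$patient_sd)
      pit <- stats::rnorm(1, 0, baseline$it_patient_sd)
      for (e in 1:2) {
        eye <- sprintf("%s_E%d", patient, e)
        ## angiograms
        angio_files <- character(3); names(angio_files) <- PLEXUS_LEVELS
        dens_t <- numeric(3); names(dens_t) <- PLEXUS_LEVELS
        dens_a <- dens_t; clen <- dens_t
        for (plex in PLEXUS_LEVELS) {
          target <- min(0.6, baseline$density[plex] * eff$density[plex] *
                          pmult * stats::rnorm(1, 1, baseline$eye_sd))
          net <- generate_vessel_network(
            size_px = image_size, n_seeds = 8,
            branch_prob = baseline$branch[plex] * eff$branch[plex],
            caliber_px = baseline$caliber_px[plex],
            target_density = target, eye_id = eye, plexus = plex)
          stem <- file.path(dir, sprintf("%s_%s", eye, tolower(plex)))
          tiff::writeTIFF(net$angiogram$pixels, paste0(stem, ".tif"),
                          bits.per.sample = 16)
          jsonlite::write_json(list(scale_x = net$angiogram$scale_x,
                                    scale_y = net$angiogram$scale_y,
                                    plexus = plex, quality = 35,
                                    eye_id = eye),
                               paste0(stem, ".json"), auto_unbox = TRUE)
          angio_files[plex] <- basename(paste0(stem, ".tif"))
          dens_t[plex] <- target; dens_a[plex] <- net$truth$density
          clen[plex] <- net$truth$centerline_length_px
        }
        ## B-scan with Poisson-drawn compliant foci
        lam <- (baseline$hrf_mean + eff$hrf_shift *
                  baseline$hrf_mean / sum(baseline$hrf_mean)) * pmult
        n_ir <- stats::rpois(1, max(0.01, lam["IR"]))
        n_or <- stats::rpois(1, max(0.01, lam["OR"]))
        fs <- plant_compliant_foci(n_ir, n_or,
                                   half_window_um = 1350,
                                   lateral_scale = 5.86)
        bs <- generate_bscan(size_px = bscan_size, foci = fs, eye_id = eye)
        bstem <- file.path(dir, paste0(eye, "_bscan"))
        tiff::writeTIFF(bs$bscan$pixels, paste0(bstem, ".tif"),
                        bits.per.sample = 16)
        write_boundaries_csv(bs$bscan$boundaries, paste0(bstem, "_bounds.csv"))
        jsonlite::write_json(list(axial_scale = bs$bscan$axial_scale,
                                  lateral_scale = bs$bscan$lateral_scale,
                                  fovea_col = bs$bscan$fovea_col - 1L,
                                  eye_id = eye),
                             paste0(bstem, ".json"), auto_unbox = TRUE)
        ## mfERG traces
        p1_shift <- eff$p1_it_shift + pit +
          stats::rnorm(1, 0, baseline$it_eye_sd)
        wt <- default_wave_truth(
          p1_amp_r1 = baseline$p1_amp_r1 * pmult,
          n1_it = baseline$n1_it, p1_it = baseline$p1_it + p1_shift,
          noise_sd = baseline$noise_sd_frac * baseline$p1_amp_r1)
        tsg <- generate_traceset(wt)
        tr_path <- file.path(dir, paste0(eye, "_traces.csv"))
        write_traceset_csv(tsg$traceset, tr_path)
        manifest <- rbind(manifest, data.frame(
          patient_id = patient, eye_id = eye, group = g,
          angio_svp = angio_files["SVP"], angio_icp = angio_files["ICP"],
          angio_dcp = angio_files["DCP"],
          bscan = basename(paste0(bstem, ".tif")),
          boundaries = basename(paste0(bstem, "_bounds.csv")),
          traces = basename(tr_path), stringsAsFactors = FALSE))
        truth <- rbind(truth, data.frame(
          patient_id = patient, eye_id = eye, group = g,
          density_svp = dens_a["SVP"], density_icp = dens_a["ICP"],
          density_dcp = dens_a["DCP"],
          target_density_svp = dens_t["SVP"],
          centerline_svp = clen["SVP"],
          hrf_ir = n_ir, hrf_or = n_or,
          p1_it = baseline$p1_it + p1_shift, stringsAsFactors = FALSE))
      }
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(manifest_path = manifest_path, truth = truth, dir = dir,
                 geometry_path = geom_path))
}

## random criteria-compliant foci specs inside the central window
plant_compliant_foci <- function(n_ir, n_or, half_window_um = 1350,
                                 lateral_scale = 5.86, min_sep_um = 120) {
  n <- n_ir + n_or
  if (n == 0) return(foci_spec()[0, ])
  lat <- numeric(0)
  while (length(lat) < n) {
    cand <- stats::runif(1, -half_window_um, half_window_um)
    if (all(abs(lat - cand) > min_sep_um)) lat <- c(lat, cand)
  }
  foci_spec(compartment = rep(c("IR", "OR"), c(n_ir, n_or)),
            lateral_um = lat,
            diameter_um = stats::runif(n, 16, 28),
            reflectivity = "moderate", shadow = FALSE)
}
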