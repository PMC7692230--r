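## Run configuration: every tunable threshold in one place, overridable from
## a flat YAML file so a bare run is reproducible.

#' Default pipeline configuration
#'
#' @return Nested list of all tunables with their defaults.
#' @export
default_config <- function() {
  list(
    quality_threshold = 30,
    binarize_method = "otsu",
    laterality = "OD",
    hrf = list(d_min_um = 10, d_max_um = 40, n_scales = 8, threshold = 0.08,
               ridge_frac = 0.25, presmooth_um = 6, window_mm = 1.5,
               max_diameter_um = 30,
               refl_tol = 0.2, shadow_min = 0.8, flank_cols = 3,
               min_contrast = 1.5, ir_definition = "fig1"),
    mferg = list(baseline_ms = 10, n1_window = c(10, 45), p1_max_ms = 60,
                 refine = "fit", z_it = 2, z_amp = -2, rule = "or",
                 amp_feature = "p1_amp"),
    stats = list(alpha = 0.05)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML configuration file over the defaults
#'
#' @param path YAML file; keys mirror [default_config()]. `NULL` gives the
#'   defaults.
#' @return Config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  rq_assert(file.exists(path), sprintf("config not found: %s", path),
            "rq_io_error")
  merge_config(cfg, yaml::read_yaml(path))
}
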