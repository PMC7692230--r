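## End-to-end pipeline: manifest in, per-eye metric table, group-comparison
## and correlation tables, JSONL run log out.

log_line <- function(con, stage, eye_id, status, message = "") {
  if (is.null(con)) return(invisible())
  writeLines(jsonlite::toJSON(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                   stage = stage, eye_id = eye_id,
                                   status = status, message = message),
                              auto_unbox = TRUE), con)
}

eye_metrics_row <- function(row, cfg, log_con) {
  stage <- "read"
  tryCatch({
    out <- list(patient_id = row$patient_id, eye_id = row$eye_id,
                group = row$group)
    ## OCTA: three plexus angiograms
    for (plex in PLEXUS_LEVELS) {
      stage <- paste0("octa_", tolower(plex))
      img_path <- row[[paste0("angio_", tolower(plex))]]
      ang <- read_angiogram(img_path, sub("\\.(tif|tiff|png)$", ".json",
                                          img_path))
      if (!quality_gate(ang, cfg$quality_threshold)) {
        log_line(log_con, stage, row$eye_id, "excluded",
                 sprintf("quality %g below %g", ang$quality,
                         cfg$quality_threshold))
        vm <- list(vad = NA_real_, vlf = NA_real_, vdi_um = NA_real_,
                   fd = NA_real_)
      } else {
        vm <- compute_all_metrics(ang, method = cfg$binarize_method,
                                  quality_threshold = cfg$quality_threshold)
      }
      sfx <- tolower(plex)
      out[[paste0("vad_", sfx)]] <- vm$vad
      out[[paste0("vlf_", sfx)]] <- vm$vlf
      out[[paste0("vdi_", sfx)]] <- vm$vdi_um
      out[[paste0("fd_", sfx)]] <- vm$fd
    }
    ## structural OCT
    stage <- "oct"
    bs <- read_bscan(row$bscan, row$boundaries,
                     sub("\\.(tif|tiff|png)$", ".json", row$bscan))
    hc <- count_hrf(bs, d_min_um = cfg$hrf$d_min_um,
                    d_max_um = cfg$hrf$d_max_um, n_scales = cfg$hrf$n_scales,
                    threshold = cfg$hrf$threshold,
                    ridge_frac = cfg$hrf$ridge_frac,
                    presmooth_um = cfg$hrf$presmooth_um,
                    window_mm = cfg$hrf$window_mm,
                    max_diameter_um = cfg$hrf$max_diameter_um,
                    refl_tol = cfg$hrf$refl_tol,
                    shadow_min = cfg$hrf$shadow_min,
                    flank_cols = cfg$hrf$flank_cols,
                    min_contrast = cfg$hrf$min_contrast,
                    ir_definition = cfg$hrf$ir_definition)
    out$hrf_ir <- hc$n_ir
    out$hrf_or <- hc$n_or
    lt <- layer_thickness(bs, laterality = cfg$laterality)
    for (i in seq_len(nrow(lt$summary))) {
      out[[paste0("th_", tolower(lt$summary$layer[i]), "_central")]] <-
        lt$summary$central[i]
      out[[paste0("th_", tolower(lt$summary$layer[i]), "_ring")]] <-
        lt$summary$ring_mean[i]
    }
    ## mfERG
    stage <- "mferg"
    geom_path <- file.path(dirname(row$traces), "hex_geometry.csv")
    ts <- read_traceset(row$traces, geom_path)
    feats <- extract_eye_features(ts, baseline_ms = cfg$mferg$baseline_ms,
                                  n1_window = cfg$mferg$n1_window,
                                  p1_max_ms = cfg$mferg$p1_max_ms,
                                  refine = cfg$mferg$refine)
    central <- feats[feats$hexagon %in% ts$central_ids, ]
    out$p1_it_central <- mean(central$p1_it)
    out$p1_amp_central <- mean(central$p1_amp)
    log_line(log_con, "eye", row$eye_id, "ok")
    list(row = as.data.frame(out, stringsAsFactors = FALSE),
         features = cbind(eye_id = row$eye_id, feats),
         central_ids = ts$central_ids)
  }, rq_error = function(e) {
    log_line(log_con, stage, row$eye_id, "error", conditionMessage(e))
    rq_stop(sprintf("stage %s failed for eye %s: %s", stage, row$eye_id,
                    conditionMessage(e)), "rq_pipeline_error")
  })
}

#' Run the full quantification pipeline over a cohort manifest
#'
#' Reads every eye's angiograms, B-scan and mfERG traces, computes per-eye
#' metrics (vessel metrics per plexus, HRF counts, layer-thickness
#' summaries, central mfERG features), builds the control-group normative
#' database and abnormal-hexagon counts, runs group comparisons (both
#' patient-mean and naive eye-level clustering) and the OCTA-vs-HRF
#' correlation screen, and writes `metrics.csv`, `comparisons.csv`,
#' `correlations.csv` and `run_log.jsonl` to `out_dir`.
#'
#' @param manifest_path Cohort manifest CSV (see [read_manifest()]).
#' @param config_path Optional YAML config (see [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the metric, comparison and correlation
#'   tables.
#' @export
run_pipeline <- function(manifest_path, config_path = NULL,
                         out_dir = dirname(manifest_path)) {
  cfg <- read_config(config_path)
  manifest <- read_manifest(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run_log.jsonl"), open = "wt")
  on.exit(close(log_con), add = TRUE)

  res <- lapply(seq_len(nrow(manifest)),
                function(i) eye_metrics_row(manifest[i, ], cfg, log_con))
  metrics <- do.call(rbind, lapply(res, `[[`, "row"))

  ## mfERG normative database from control eyes, abnormal counts per eye
  all_feats <- do.call(rbind, lapply(res, `[[`, "features"))
  central_ids <- res[[1]]$central_ids
  ctrl <- all_feats[all_feats$eye_id %in%
                      metrics$eye_id[metrics$group == "control"], ]
  metrics$n_abnormal_hex <- NA_integer_
  if (length(unique(ctrl$eye_id)) >= 2) {
    db <- tryCatch(build_normative_db(ctrl), error = function(e) NULL)
    if (!is.null(db)) {
      for (i in seq_len(nrow(metrics))) {
        ef <- all_feats[all_feats$eye_id == metrics$eye_id[i], ]
        ab <- classify_abnormal(ef, db, central_ids,
                                z_it = cfg$mferg$z_it, z_amp = cfg$mferg$z_amp,
                                rule = cfg$mferg$rule,
                                amp_feature = cfg$mferg$amp_feature)
        metrics$n_abnormal_hex[i] <- ab$n_abnormal
      }
    }
  }
  write_metrics(metrics, file.path(out_dir, "metrics.csv"))

  ## group comparisons for every numeric metric, both clustering modes
  metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                         c())
  comparisons <- NULL
  if (length(unique(metrics$group)) >= 2) {
    for (mc in metric_cols) {
      for (cl in c("patient_mean", "naive")) {
        gc <- tryCatch(compare_groups(metrics, value = mc, clustering = cl),
                       error = function(e) NULL)
        if (is.null(gc)) next
        comparisons <- rbind(comparisons, data.frame(
          metric = mc, clustering = cl, omnibus_p = gc$omnibus_p,
          pair = gc$pairwise$pair, p_raw = gc$pairwise$p_raw,
          p_adj = gc$pairwise$p_adj, stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(comparisons))
    write_metrics(comparisons, file.path(out_dir, "comparisons.csv"))

  ## OCTA-parameter vs HRF-count correlation screen
  octa_cols <- grep("^(vad|vlf|vdi|fd)_", names(metrics), value = TRUE)
  correlations <- NULL
  for (xc in octa_cols) for (yc in c("hrf_ir", "hrf_or")) {
    cr <- tryCatch(correlate(metrics[[xc]], metrics[[yc]],
                             x_name = xc, y_name = yc),
                   error = function(e) NULL)
    if (is.null(cr)) next
    correlations <- rbind(correlations, data.frame(
      x = xc, y = yc, slope = cr$slope, t = cr$t, p = cr$p, n = cr$n,
      stringsAsFactors = FALSE))
  }
  if (!is.null(correlations))
    write_metrics(correlations, file.path(out_dir, "correlations.csv"))
  log_line(log_con, "pipeline", "", "ok",
           sprintf("%d eyes processed", nrow(metrics)))
  invisible(list(metrics = metrics, comparisons = comparisons,
                 correlations = correlations))
}
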