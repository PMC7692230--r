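## Synthetic multifocal ERG traces: biphasic N1/P1 templates built from two
## Gaussian lobes, calibrated so that the rendered waveform's trough and peak
## land exactly at the requested implicit times with the requested
## isoelectric-to-trough (N1-A) and trough-to-peak (P1-A) amplitudes.

#' Standard 103-hexagon ring geometry
#'
#' The eccentricity-scaled stimulus array assigns 1, 6, 12, 18, 24 and 42
#' hexagons to concentric rings R1--R6 (103 total); the 19 hexagons of rings
#' R1--R3 form the central macular set.
#'
#' @return Named integer vector: ring index per hexagon id `h001..h103`.
#' @export
mferg_hex_geometry <- function() {
  ring <- rep(1:6, c(1L, 6L, 12L, 18L, 24L, 42L))
  stats::setNames(as.integer(ring), sprintf("h%03d", seq_along(ring)))
}

## Calibrate the two-lobe template
##   f(t) = -a g(t; mu1, w) + b g(t; mu2, w),  g Gaussian, width w (ms)
## so that min f = -n1_amp at t = n1_it and max f - min f = p1_amp at
## t = p1_it (continuous time). Fixed-point iteration on (a, b, mu1, mu2).
calibrate_biphasic <- function(n1_amp, p1_amp, n1_it, p1_it, w = 6) {
  rq_assert(n1_it > 0 && n1_it < p1_it, "need 0 < n1_it < p1_it",
            "rq_generator_error")
  rq_assert(n1_amp > 0 && p1_amp > n1_amp,
            "need 0 < n1_amp < p1_amp (trough-to-peak exceeds trough depth)",
            "rq_generator_error")
  g <- function(t, mu) exp(-(t - mu)^2 / (2 * w^2))
  a <- n1_amp; b <- p1_amp - n1_amp
  mu1 <- n1_it; mu2 <- p1_it
  grid <- seq(max(0, n1_it - 4 * w), p1_it + 4 * w, by = 0.005)
  for (it in 1:80) {
    f <- -a * g(grid, mu1) + b * g(grid, mu2)
    i_min <- which.min(f); i_max <- which.max(f)
    t_min <- grid[i_min]; t_max <- grid[i_max]
    f_min <- f[i_min]; f_max <- f[i_max]
    err <- max(abs(t_min - n1_it), abs(t_max - p1_it),
               abs(-f_min - n1_amp) / n1_amp,
               abs((f_max - f_min) - p1_amp) / p1_amp)
    if (err < 1e-4) break
    mu1 <- mu1 + (n1_it - t_min)
    mu2 <- mu2 + (p1_it - t_max)
    a <- a * n1_amp / max(1e-12, -f_min)
    b <- b * p1_amp / max(1e-12, f_max - f_min)
  }
  list(a = a, b = b, mu1 = mu1, mu2 = mu2, w = w)
}

biphasic_template <- function(t_ms, pars) {
  g <- function(t, mu) exp(-(t - mu)^2 / (2 * pars$w^2))
  -pars$a * g(t_ms, pars$mu1) + pars$b * g(t_ms, pars$mu2)
}

#' Default per-hexagon wave truth
#'
#' Control-like first-order response parameters: P1 implicit time ~30 ms, N1
#' ~15 ms, ring-1 trough-to-peak amplitude `p1_amp_r1` nV/deg^2, with
#' amplitudes scaled by 1/ring to mimic eccentricity scaling.
#'
#' @param p1_amp_r1 Ring-1 trough-to-peak (P1-A) amplitude, nV/deg^2.
#' @param n1_frac N1-A as a fraction of P1-A.
#' @param n1_it,p1_it Implicit times in ms.
#' @param noise_sd White-noise standard deviation (nV/deg^2) per hexagon.
#' @param geometry Ring assignment, see [mferg_hex_geometry()].
#' @return Data.frame of class `wave_truth`, one row per hexagon.
#' @export
default_wave_truth <- function(p1_amp_r1 = 80, n1_frac = 0.5, n1_it = 15,
                               p1_it = 30, noise_sd = 0,
                               geometry = mferg_hex_geometry()) {
  scale <- 1 / as.numeric(geometry)
  out <- data.frame(hexagon = names(geometry),
                    ring = as.integer(geometry),
                    n1_amp = n1_frac * p1_amp_r1 * scale,
                    p1_amp = p1_amp_r1 * scale,
                    n1_it = n1_it, p1_it = p1_it,
                    noise_sd = noise_sd, stringsAsFactors = FALSE)
  class(out) <- c("wave_truth", "data.frame")
  out
}

#' Generate a single synthetic mfERG trace
#'
#' One biphasic first-order response with calibrated trough/peak (see
#' [generate_traceset()]) plus white Gaussian noise; convenient for per-trace
#' recovery experiments.
#'
#' @param n1_amp,p1_amp Isoelectric-to-trough and trough-to-peak amplitudes
#'   (nV/deg^2).
#' @param n1_it,p1_it Implicit times (ms).
#' @param noise_sd White-noise SD (nV/deg^2).
#' @param sampling_rate Hz.
#' @param duration_ms Trace duration (ms).
#' @param seed Integer RNG seed.
#' @return List: `trace`, `t_ms`, `truth`.
#' @export
generate_trace <- function(n1_amp = 40, p1_amp = 80, n1_it = 15, p1_it = 30,
                           noise_sd = 0, sampling_rate = 1200,
                           duration_ms = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pars <- calibrate_biphasic(n1_amp, p1_amp, n1_it, p1_it)
  n_s <- as.integer(round(duration_ms / 1000 * sampling_rate))
  t_ms <- (seq_len(n_s) - 1) / sampling_rate * 1000
  tr <- biphasic_template(t_ms, pars)
  if (noise_sd > 0) tr <- tr + stats::rnorm(n_s, 0, noise_sd)
  list(trace = tr, t_ms = t_ms,
       truth = list(n1_amp = n1_amp, p1_amp = p1_amp, n1_it = n1_it,
                    p1_it = p1_it, noise_sd = noise_sd))
}

#' Generate an mfERG trace set from wave truth
#'
#' Each hexagon's trace is the calibrated biphasic template (see
#' [default_wave_truth()]) sampled at `sampling_rate`, plus white Gaussian
#' noise of the hexagon's `noise_sd`.
#'
#' @param wave_truth Data.frame as returned by [default_wave_truth()].
#' @param sampling_rate Hz, >= 600.
#' @param duration_ms Trace duration; must cover `p1_it + 20` ms.
#' @param seed Integer RNG seed.
#' @return List with `traceset` (an [mferg_traceset()]) and `truth`
#'   (the wave_truth data.frame).
#' @export
generate_traceset <- function(wave_truth = default_wave_truth(),
                              sampling_rate = 1200, duration_ms = 100,
                              seed = NULL) {
  rq_assert(sampling_rate >= 600, "sampling_rate must be >= 600 Hz")
  rq_assert(all(duration_ms >= wave_truth$p1_it + 20),
            "duration must cover p1_it + 20 ms")
  if (!is.null(seed)) set.seed(seed)
  n_s <- as.integer(round(duration_ms / 1000 * sampling_rate))
  t_ms <- (seq_len(n_s) - 1) / sampling_rate * 1000
  traces <- matrix(0, n_s, nrow(wave_truth),
                   dimnames = list(NULL, wave_truth$hexagon))
  ## hexagons of one ring share parameters -> calibrate once per profile
  key <- with(wave_truth, paste(n1_amp, p1_amp, n1_it, p1_it))
  cache <- new.env()
  for (i in seq_len(nrow(wave_truth))) {
    k <- key[i]
    if (is.null(cache[[k]]))
      cache[[k]] <- calibrate_biphasic(wave_truth$n1_amp[i],
                                       wave_truth$p1_amp[i],
                                       wave_truth$n1_it[i],
                                       wave_truth$p1_it[i])
    tr <- biphasic_template(t_ms, cache[[k]])
    if (wave_truth$noise_sd[i] > 0)
      tr <- tr + stats::rnorm(n_s, 0, wave_truth$noise_sd[i])
    traces[, i] <- tr
  }
  ring <- stats::setNames(as.integer(wave_truth$ring), wave_truth$hexagon)
  list(traceset = mferg_traceset(traces, sampling_rate, ring),
       truth = wave_truth)
}
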