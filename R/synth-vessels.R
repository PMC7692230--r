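## Synthetic vessel-network generator with exact ground truth.
##
## Correlated random walks started at image-edge seeds wander across the
## field, branching with a fixed per-step probability; visited pixels form the
## centerline, which is rasterized by dilation with a disk of the requested
## caliber. Ground-truth bookkeeping is exact: centerline length = number of
## distinct centerline pixels, density = vessel-pixel fraction of the final
## mask, branch count = number of spawn events.

## Discrete disc of the requested diameter. The radius-squared cutoff
## caliber^2/4 - 0.5 keeps a width-3 disc a plus shape (corners excluded) so
## that ribbons keep the nominal caliber along diagonals too; calibers are
## meant to be odd (a width-2 disc cannot be centered on a pixel).
disk_kernel <- function(caliber_px) {
  if (caliber_px <= 2) return(matrix(1, 1, 1))
  n <- as.integer(2 * ceiling(caliber_px / 2) + 1)
  if (n %% 2 == 0) n <- n + 1L
  cc <- (n + 1) / 2
  d2 <- outer((1:n - cc)^2, (1:n - cc)^2, "+")
  (d2 <= caliber_px^2 / 4 - 0.5) * 1
}

dilate_mask <- function(mask, kernel) {
  if (length(kernel) == 1) return(mask)
  conv <- EBImage::filter2(mask * 1, kernel, boundary = 0)
  conv > 0.5
}

#' Generate a synthetic en-face vessel network with known truth
#'
#' @param size_px Image side length in pixels (square image), >= 64.
#' @param seed Integer RNG seed; the same seed reproduces the network exactly.
#' @param n_seeds Walkers spawned per batch from random edge points.
#' @param step_persistence Directional persistence in \[0,1\]; each step turns
#'   by N(0, (1 - persistence) * pi) radians. 1 = straight lines.
#' @param branch_prob Per-step probability of spawning a branch.
#' @param death_prob Per-step probability that a walker terminates. 0 (the
#'   default) lets walkers run until they exit the field; positive values
#'   give finite segments (expected length 1/death_prob) so that, with
#'   `branch_prob < death_prob`, the branching process stays subcritical and
#'   total vessel mass grows with the branching rate.
#' @param caliber_px Vessel caliber (disk diameter) in pixels, >= 1.
#' @param target_density Stop once the vessel-pixel fraction reaches this
#'   value; `NULL` runs exactly one batch of `n_seeds` walkers.
#' @param max_steps Total step budget before giving up on `target_density`.
#' @param noise_amp Background noise amplitude (uniform in \[0, noise_amp\]);
#'   0 gives a noise-free two-level image.
#' @param vessel_level Intensity of vessel pixels.
#' @param scale_um Lateral pixel pitch in micrometers per pixel.
#' @param plexus,eye_id,quality Metadata for the returned angiogram.
#' @param start Optional list(row, col, theta) fixing the first walker's start
#'   and direction (radians; 0 = rightward) for controlled fixtures.
#' @return List with `angiogram` (an [enface_angiogram()]) and `truth`
#'   (class `vessel_truth`: `mask`, `centerline`, `centerline_length_px`,
#'   `mean_caliber_px`, `density`, `branch_count`).
#' @export
generate_vessel_network <- function(size_px = 256, seed = NULL, n_seeds = 12,
                                    step_persistence = 0.95, branch_prob = 0.02,
                                    death_prob = 0, caliber_px = 3,
                                    target_density = 0.35,
                                    max_steps = 500000, noise_amp = 0.05,
                                    vessel_level = 0.9, scale_um = 5.86,
                                    plexus = "SVP", eye_id = "synthetic",
                                    quality = 40, start = NULL) {
  rq_assert(size_px >= 64, "size_px must be >= 64")
  rq_assert(branch_prob >= 0 && branch_prob <= 1, "branch_prob must be in [0,1]")
  rq_assert(caliber_px >= 1, "caliber_px must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(size_px)
  centerline <- matrix(FALSE, n, n)
  kern <- disk_kernel(caliber_px)
  sigma_turn <- (1 - step_persistence) * pi
  branch_count <- 0L
  steps_used <- 0L
  max_walk <- 4L * n

  new_edge_walker <- function() {
    side <- sample.int(4, 1)
    pos <- stats::runif(1, 1, n)
    switch(side,
      list(r = 1, c = pos, theta = pi / 2 + stats::runif(1, -0.5, 0.5)),
      list(r = n, c = pos, theta = -pi / 2 + stats::runif(1, -0.5, 0.5)),
      list(r = pos, c = 1, theta = 0 + stats::runif(1, -0.5, 0.5)),
      list(r = pos, c = n, theta = pi + stats::runif(1, -0.5, 0.5)))
  }
  ## NB: theta convention: dr = sin(theta), dc = cos(theta); rows grow down.

  walk_one <- function(w) {
    ## returns list of spawned branch walkers; marks centerline pixels
    spawned <- list()
    rows <- integer(max_walk); cols <- integer(max_walk)
    r <- w$r; cc <- w$c; theta <- w$theta
    np <- 0L
    for (k in seq_len(max_walk)) {
      if (steps_used + np >= max_steps) break
      ri <- as.integer(round(r)); ci <- as.integer(round(cc))
      if (ri < 1 || ri > n || ci < 1 || ci > n) break
      np <- np + 1L
      rows[np] <- ri; cols[np] <- ci
      if (branch_prob > 0 && stats::runif(1) < branch_prob) {
        branch_count <<- branch_count + 1L
        dtheta <- sample(c(-1, 1), 1) * stats::runif(1, pi / 4.5, pi / 2.6)
        spawned[[length(spawned) + 1L]] <- list(r = r, c = cc,
                                                theta = theta + dtheta)
      }
      if (death_prob > 0 && stats::runif(1) < death_prob) break
      if (sigma_turn > 0) theta <- theta + stats::rnorm(1, 0, sigma_turn)
      r <- r + sin(theta); cc <- cc + cos(theta)
    }
    if (np > 0) {
      centerline[cbind(rows[1:np], cols[1:np])] <<- TRUE
      steps_used <<- steps_used + np
    }
    spawned
  }

  density_now <- function() {
    m <- dilate_mask(centerline, kern)
    list(mask = m, density = sum(m) / length(m))
  }

  ## branching is supercritical for moderate branch_prob, so the density stop
  ## is checked after every finished walker, not only between batches
  check_every <- max(200L, n * n %/% 200L)
  last_check <- 0L
  done <- FALSE
  run_batch <- function(initial) {
    stack <- initial
    while (length(stack) > 0 && !done) {
      w <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      stack <- c(stack, walk_one(w))
      if (!is.null(target_density) && steps_used - last_check >= check_every) {
        last_check <<- steps_used
        if (density_now()$density >= target_density) done <<- TRUE
      }
      if (steps_used >= max_steps) break
    }
  }

  if (!is.null(start)) {
    run_batch(list(start))
    if (n_seeds > 1 && !done && steps_used < max_steps)
      run_batch(replicate(n_seeds - 1L, new_edge_walker(), simplify = FALSE))
  } else {
    run_batch(replicate(n_seeds, new_edge_walker(), simplify = FALSE))
  }

  st <- density_now()
  if (!is.null(target_density)) {
    while (st$density < target_density && steps_used < max_steps && !done) {
      run_batch(replicate(n_seeds, new_edge_walker(), simplify = FALSE))
      st <- density_now()
    }
    st <- density_now()
    if (st$density < target_density)
      rq_stop(sprintf(
        "target density %.3f unreachable in step budget; achieved %.3f",
        target_density, st$density), "rq_generator_error")
  }

  mask <- st$mask
  pixels <- matrix(stats::runif(n * n, 0, noise_amp), n, n)
  pixels[mask] <- vessel_level
  pixels <- pmin(pmax(pixels, 0), 1)

  truth <- structure(list(
    mask = mask, centerline = centerline,
    centerline_length_px = sum(centerline),
    ## exact rendered caliber: vessel pixels per centerline pixel (the
    ## nominal disc diameter is approximate on the pixel grid)
    mean_caliber_px = max(1, sum(mask) / max(1L, sum(centerline))),
    nominal_caliber_px = caliber_px,
    density = sum(mask) / length(mask),
    branch_count = branch_count
  ), class = "vessel_truth")

  list(angiogram = enface_angiogram(pixels, scale_x = scale_um,
                                    scale_y = scale_um, plexus = plexus,
                                    eye_id = eye_id, quality = quality),
       truth = truth)
}

#' @export
print.vessel_truth <- function(x, ...) {
  cat(sprintf("<vessel_truth> density %.4f, centerline %d px, caliber %g px, %d branches\n",
              x$density, x$centerline_length_px, x$mean_caliber_px,
              x$branch_count))
  invisible(x)
}
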