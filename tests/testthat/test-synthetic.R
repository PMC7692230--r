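test_that("a single unbranched straight walk has exact length bookkeeping", {
  net <- generate_vessel_network(
    size_px = 64, seed = 1, n_seeds = 1, step_persistence = 1,
    branch_prob = 0, caliber_px = 1, target_density = NULL, noise_amp = 0,
    start = list(r = 32, c = 1, theta = 0))
  expect_equal(net$truth$branch_count, 0)
  expect_equal(net$truth$centerline_length_px, 64)  # straight traverse
  expect_equal(net$truth$density, 64 / (64 * 64))
  expect_equal(sum(net$truth$mask), 64)
})

test_that("vessel generator hits its density target and is seed-deterministic", {
  net <- generate_vessel_network(size_px = 256, seed = 7, target_density = 0.35)
  expect_gte(net$truth$density, 0.35)
  expect_lte(net$truth$density, 0.37)
  expect_equal(net$truth$density, sum(net$truth$mask) / length(net$truth$mask))

  net2 <- generate_vessel_network(size_px = 256, seed = 7, target_density = 0.35)
  expect_identical(net$truth$mask, net2$truth$mask)
  expect_identical(net$angiogram$pixels, net2$angiogram$pixels)

  expect_error(
    generate_vessel_network(size_px = 128, seed = 1, target_density = 0.9,
                            max_steps = 500),
    "achieved")
})

test_that("B-scan bands are exact without speckle and foci obey their spec", {
  g <- generate_bscan(speckle_level = 0, seed = 1)
  prof <- default_layer_profile()
  ## a row in the middle of the ONL band equals the ONL mean exactly
  onl_row <- round(mean(prof$boundaries_um[c("OPL_ONL", "ELM")]) / 3.9)
  expect_true(all(g$bscan$pixels[onl_row, ] == prof$band_reflectivity["OPL_ONL"]))

  g1 <- generate_bscan(foci = foci_spec("IR", 300, 25), speckle_level = 0,
                       seed = 2)
  expect_equal(nrow(g1$truth), 1)
  expect_equal(g1$truth$compartment, "IR")

  ## a shadowed focus darkens its column strip below the focus
  g2 <- generate_bscan(foci = foci_spec("OR", 0, 25, shadow = TRUE,
                                        depth_frac = 0.5),
                       speckle_level = 0, seed = 3)
  cc <- g2$truth$col
  rows <- (g2$truth$row + 6):floor(g2$bscan$boundaries["BM", cc])
  expect_lt(mean(g2$bscan$pixels[rows, cc]),
            mean(g2$bscan$pixels[rows, cc + 15]))

  ## an oversized focus cannot fit its compartment band
  expect_error(generate_bscan(foci = foci_spec("IR", 0, 200), seed = 4),
               "exceeds")
})

test_that("synthetic traces place extrema and amplitudes as specified", {
  g <- generate_trace(n1_amp = 40, p1_amp = 80, n1_it = 15, p1_it = 30,
                      noise_sd = 0, sampling_rate = 1200)
  i_min <- which.min(g$trace); i_max <- which.max(g$trace)
  dt <- 1000 / 1200
  expect_lte(abs(g$t_ms[i_min] - 15), dt + 1e-9)
  expect_lte(abs(g$t_ms[i_max] - 30), dt + 1e-9)
  expect_equal(max(g$trace) - min(g$trace), 80, tolerance = 0.01)
  expect_equal(-min(g$trace), 40, tolerance = 0.01)

  ## determinism with noise
  a <- generate_trace(noise_sd = 5, seed = 11)$trace
  b <- generate_trace(noise_sd = 5, seed = 11)$trace
  expect_identical(a, b)

  expect_error(generate_trace(n1_it = 30, p1_it = 20), "n1_it < p1_it")

  ## full trace sets: ring scaling carries through
  ts <- generate_traceset(default_wave_truth(), seed = 1)$traceset
  expect_equal(ncol(ts$traces), 103)
  expect_length(ts$central_ids, 19)
})

test_that("cohorts have the right shape and planted effect sizes", {
  m <- simulate_cohort_metrics(n_per_group = 2, seed = 1)
  expect_equal(nrow(m), 12)  # 3 groups x 2 patients x 2 eyes
  expect_equal(sort(unique(m$group)), sort(c("control", "noDR", "DR")))

  ## planted SVP reduction shows up in the truth-level means
  eff <- effect_spec(
    noDR = list(density = c(SVP = 0.85, ICP = 1, DCP = 1),
                branch = c(SVP = 1, ICP = 1, DCP = 1),
                p1_it_shift = 0, hrf_shift = 0),
    DR = list(density = c(SVP = 1, ICP = 1, DCP = 1),
              branch = c(SVP = 1, ICP = 1, DCP = 1),
              p1_it_shift = 0, hrf_shift = 0))
  m2 <- simulate_cohort_metrics(n_per_group = 10, effects = eff, seed = 2)
  ratio <- mean(m2$vad_svp[m2$group == "noDR"]) /
    mean(m2$vad_svp[m2$group == "control"])
  expect_equal(ratio, 0.85, tolerance = 0.05)

  ## identity effects: group means agree within sampling error
  m3 <- simulate_cohort_metrics(n_per_group = 10,
                                effects = identity_effects(), seed = 3)
  mu <- tapply(m3$vad_svp, m3$group, mean)
  expect_lt(diff(range(mu)) / mean(mu), 0.06)
})
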