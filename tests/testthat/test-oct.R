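test_that("ETDRS sectors follow ring radii and quadrant diagonals", {
  g <- etdrs_grid()
  expect_equal(sector_of(c(0, 0), g), "C1")
  expect_equal(sector_of(c(0, 1000), g), "I-sup")
  expect_equal(sector_of(c(3100, 0), g), "outside")
  expect_equal(sector_of(c(1000, 0), g, laterality = "OD"), "I-nas")
  expect_equal(sector_of(c(1000, 0), g, laterality = "OS"), "I-temp")
  expect_equal(sector_of(c(0, -2000), g), "O-inf")
  expect_equal(sector_of(c(400, 0), g), "C1")  # r < 0.5 mm
})

test_that("layer thickness reproduces planted constant and piecewise fields", {
  ## constant GCL thickness of 43 um everywhere
  th_const <- function(x_um) { b <- default_bands; b["GCL_IPL"] <- 43; b }
  lt <- layer_thickness(bscan_from_thickness(th_const))
  gcl <- lt$sector_means["GCL", ]
  expect_true(all(gcl[!is.na(gcl)] == 43))
  expect_equal(lt$summary$central[lt$summary$layer == "GCL"], 43)

  ## piecewise: 50 um in the inner ring, 30 um in the outer -> ring mean 40
  th_piece <- function(x_um) {
    b <- default_bands
    b["GCL_IPL"] <- if (x_um < 1500) 50 else 30
    b
  }
  h <- bscan_from_thickness(th_piece)
  v <- bscan_from_thickness(th_piece, orientation = "vertical")
  lt2 <- layer_thickness(list(h, v))
  expect_equal(lt2$summary$ring_mean[lt2$summary$layer == "GCL"], 40)
  ## all 8 quadrants sampled with two orthogonal scans
  expect_true(all(!is.na(lt2$sector_means["GCL", ])))
})

test_that("per-layer thicknesses reconcile with the total ILM-RPE/BM stack", {
  set.seed(4)
  th_rand <- function(x_um) default_bands * (1 + 0.2 * sin(x_um / 800))
  lt <- layer_thickness(bscan_from_thickness(th_rand))
  tot <- colSums(lt$sector_means)
  dev <- abs(tot - lt$total)
  expect_true(all(dev[!is.na(dev)] <= 1))
})

test_that("HRF detection finds planted foci and honors the central window", {
  ## noise-free planted 25 um focus: exactly one candidate within 2 px
  g <- generate_bscan(foci = foci_spec("IR", 300, 25, depth_frac = 0.4),
                      speckle_level = 0, seed = 1)
  cand <- detect_hrf_candidates(g$bscan)
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$row - g$truth$row), 2)
  expect_lte(abs(cand$col - g$truth$col), 2)

  ## focus 1.8 mm from the fovea is outside the central 3 mm window
  g2 <- generate_bscan(size_px = c(320, 700),
                       foci = foci_spec("IR", 1800, 25, depth_frac = 0.4),
                       speckle_level = 0, seed = 2)
  expect_equal(nrow(detect_hrf_candidates(g2$bscan)), 0)

  ## uniform scan: nothing to detect
  g3 <- generate_bscan(speckle_level = 0, seed = 3)
  expect_equal(nrow(detect_hrf_candidates(g3$bscan)), 0)

  ## window is closed: a focus at exactly 1.5 mm is included, one pixel
  ## beyond is excluded
  lat <- 5.86
  gin <- generate_bscan(foci = foci_spec("IR", 1500, 25, depth_frac = 0.5),
                        speckle_level = 0, seed = 4)
  gout <- generate_bscan(foci = foci_spec("IR", 1500 + lat, 25,
                                          depth_frac = 0.5),
                         speckle_level = 0, seed = 4)
  expect_equal(nrow(detect_hrf_candidates(gin$bscan)), 1)
  expect_equal(nrow(detect_hrf_candidates(gout$bscan)), 0)

  ## scans narrower than 3 mm are refused
  g4 <- generate_bscan(size_px = c(260, 400), seed = 5)
  expect_error(detect_hrf_candidates(g4$bscan), "narrower")
})

test_that("HRF filtering applies the size, reflectivity and shadow criteria", {
  fs <- rbind(foci_spec("IR", -700, 25, depth_frac = 0.5),
              foci_spec("OR", 400, 40, depth_frac = 0.5),
              foci_spec("IR", 900, 25, reflectivity = "high",
                        depth_frac = 0.5),
              foci_spec("OR", -200, 25, shadow = TRUE, depth_frac = 0.5))
  g <- generate_bscan(foci = fs, speckle_level = 0, seed = 6)
  res <- count_hrf(g$bscan)
  expect_equal(res$n_ir, 1)
  expect_equal(res$n_or, 0)
  expect_equal(res$foci$compartment, "IR")
  expect_lte(abs(res$foci$col - g$truth$col[1]), 2)
  expect_lte(res$foci$diameter_um, 30)
  expect_gte(res$foci$reflectivity_rel, 0.8)
  expect_gte(res$foci$shadow_score, 0.8)
})

test_that("reported HRF counts track planted compliant counts one-for-one", {
  ## noise-free: slope of reported vs planted counts within 1 +- 0.1
  planted <- c(0, 2, 4, 6, 8, 10)
  reported <- vapply(seq_along(planted), function(i) {
    n <- planted[i]
    n_ir <- ceiling(n / 2); n_or <- n - n_ir
    set.seed(300 + i)
    fs <- retinaquant:::plant_compliant_foci(n_ir, n_or)
    g <- generate_bscan(size_px = c(320, 620), foci = fs, speckle_level = 0,
                        seed = 300 + i)
    res <- count_hrf(g$bscan)
    res$n_ir + res$n_or
  }, numeric(1))
  sl <- stats::coef(stats::lm(reported ~ planted))[2]
  expect_gte(sl, 0.9); expect_lte(sl, 1.1)
})

test_that("the two inner-retina conventions assign compartments differently", {
  ## a focus in the GCL is IR under the default convention but falls outside
  ## the INL-to-OPL band of the text convention
  g <- generate_bscan(foci = foci_spec("IR", 300, 25, depth_frac = 0.2),
                      speckle_level = 0, seed = 7)
  cand <- detect_hrf_candidates(g$bscan)
  f_fig1 <- filter_hrf(cand, g$bscan, ir_definition = "fig1")
  f_text <- filter_hrf(cand, g$bscan, ir_definition = "text")
  expect_equal(nrow(f_fig1), 1)
  expect_equal(f_fig1$compartment, "IR")
  expect_equal(nrow(f_text), 0)
})
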