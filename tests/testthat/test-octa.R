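test_that("quality gate applies the strict Q-score threshold", {
  ang <- function(q) enface_angiogram(matrix(runif(16), 4), 5.86, 5.86,
                                      "SVP", quality = q)
  expect_true(quality_gate(ang(35)))
  expect_false(quality_gate(ang(29)))
  expect_true(quality_gate(ang(30)))  # "inferior to 30" is strict
  expect_error(compute_all_metrics(ang(20)), "quality gate failed")
})

test_that("binarization separates a two-level image exactly and rejects constants", {
  px <- matrix(0.1, 64, 64); px[20:40, 10:50] <- 0.9
  b <- binarize(px)
  expect_identical(b$mask, px == 0.9)
  expect_error(binarize(matrix(0.4, 32, 32)), "degenerate histogram")

  ## noise-free synthetic network: mask recovered exactly
  net <- generate_vessel_network(size_px = 128, seed = 3,
                                 target_density = 0.2, noise_amp = 0)
  expect_identical(binarize(net$angiogram)$mask, net$truth$mask)
})

test_that("skeletonization thins to one-pixel centerlines preserving structure", {
  ## straight ribbon -> single-pixel line of about the ribbon length
  rib <- matrix(FALSE, 32, 120); rib[14:18, 11:110] <- TRUE
  sk <- skeletonize(rib)
  expect_true(all(sk$mask[!rib] == FALSE))  # subset of input
  expect_equal(sum(sk$mask), 100, tolerance = 0.08)  # ends erode a few px
  ## one-pixel wide: no pixel retains its full 3x3 neighborhood
  m <- sk$mask * 1
  nb <- retinaquant:::shift_mat(m, 1, 0) + retinaquant:::shift_mat(m, -1, 0) +
    retinaquant:::shift_mat(m, 0, 1) + retinaquant:::shift_mat(m, 0, -1) +
    retinaquant:::shift_mat(m, 1, 1) + retinaquant:::shift_mat(m, 1, -1) +
    retinaquant:::shift_mat(m, -1, 1) + retinaquant:::shift_mat(m, -1, -1)
  expect_true(all(nb[sk$mask] < 8))

  ## fixed points and the empty case
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_identical(skeletonize(single)$mask, single)
  expect_equal(sum(skeletonize(matrix(FALSE, 8, 8))$mask), 0)
})

test_that("VAD and VLF are exact pixel-count ratios with vlf <= vad", {
  expect_equal(vessel_area_density(matrix(TRUE, 10, 10)), 1.0)
  half <- matrix(FALSE, 10, 10); half[1:5, ] <- TRUE
  expect_equal(vessel_area_density(half), 0.5)
  expect_equal(vessel_length_fraction(matrix(FALSE, 16, 16)), 0)
  line <- matrix(FALSE, 256, 256); line[100, ] <- TRUE
  expect_equal(vessel_length_fraction(line), 256 / 65536)

  for (s in 1:5) {
    net <- generate_vessel_network(size_px = 128, seed = 100 + s,
                                   target_density = 0.25)
    b <- binarize(net$angiogram)
    expect_equal(vessel_area_density(b), net$truth$density)
    expect_lte(vessel_length_fraction(skeletonize(b)),
               vessel_area_density(b))
  }
})

test_that("VDI recovers ribbon width times scale and guards empty skeletons", {
  for (w in c(3, 5, 9, 15)) {
    rib <- matrix(FALSE, 64, 260)
    rib[(32 - (w - 1) / 2):(32 + (w - 1) / 2), 31:230] <- TRUE
    vdi <- vessel_diameter_index(rib, skeletonize(rib), scale = 6)
    expect_equal(vdi, w * 6, tolerance = 0.1)
  }
  expect_error(
    vessel_diameter_index(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8), 6),
    "empty skeleton")
})

test_that("VDI increases strictly with generated vessel caliber", {
  vdis <- vapply(c(3, 6, 9), function(cal) {
    net <- generate_vessel_network(size_px = 192, seed = 50, caliber_px = cal,
                                   target_density = 0.2)
    b <- binarize(net$angiogram)
    vessel_diameter_index(b, skeletonize(b), scale = 5.86)
  }, numeric(1))
  expect_true(all(diff(vdis) > 0))
})

test_that("fractal dimension is calibrated on lines and planes and matches the oracle", {
  line <- matrix(FALSE, 256, 256); line[77, ] <- TRUE
  fd_line <- fractal_dimension(line)
  expect_gte(fd_line$fd, 0.95); expect_lte(fd_line$fd, 1.05)
  full <- matrix(TRUE, 256, 256)
  fd_full <- fractal_dimension(full)
  expect_gte(fd_full$fd, 1.90); expect_lte(fd_full$fd, 2 + 1e-9)

  ## per-box-size counts equal the brute-force nested-loop oracle
  set.seed(42)
  for (rep in 1:4) {
    net <- generate_vessel_network(size_px = 64, seed = 200 + rep,
                                   target_density = 0.15, caliber_px = 3)
    sk <- skeletonize(net$truth$mask)$mask
    ft <- fractal_dimension(sk)
    for (k in seq_along(ft$sizes))
      expect_equal(ft$counts[k], brute_force_box_count(sk, ft$sizes[k]))
  }

  expect_error(fractal_dimension(matrix(FALSE, 64, 64)), "at least 2")
  tiny <- matrix(FALSE, 16, 16); tiny[3, 3:9] <- TRUE
  expect_error(fractal_dimension(tiny), "fewer than 3")
})

test_that("fractal dimension is rotation-robust", {
  net <- generate_vessel_network(size_px = 192, seed = 9, target_density = 0.15)
  bin <- binarize(net$angiogram)
  sk <- skeletonize(bin)$mask
  fd0 <- fractal_dimension(sk)$fd
  ## 90 degrees: boxes map onto boxes, FD identical
  expect_identical(fractal_dimension(t(sk[nrow(sk):1, ]))$fd, fd0)
  ## 45 degrees: rasterize the same continuous curve structure at both
  ## orientations (a pixel-level rotation of an already-rasterized skeleton
  ## only measures resampling loss, not the estimator)
  mk_poly <- function(theta0, seed) {
    set.seed(seed)
    pts <- NULL
    for (w in 1:14) {
      x <- runif(1, 30, 160); y <- runif(1, 30, 160); th <- runif(1, 0, 2 * pi)
      for (i in 1:600) {
        th <- th + rnorm(1, 0, 0.1)
        x <- x + 0.5 * cos(th); y <- y + 0.5 * sin(th)
        pts <- rbind(pts, c(x, y))
      }
    }
    ctr <- c(96, 96)
    rot <- cbind(
      ctr[1] + cos(theta0) * (pts[, 1] - ctr[1]) - sin(theta0) * (pts[, 2] - ctr[2]),
      ctr[2] + sin(theta0) * (pts[, 1] - ctr[1]) + cos(theta0) * (pts[, 2] - ctr[2]))
    m <- matrix(FALSE, 320, 320)
    ij <- round(rot) + 96
    keep <- ij[, 1] >= 1 & ij[, 1] <= 320 & ij[, 2] >= 1 & ij[, 2] <= 320
    m[ij[keep, , drop = FALSE]] <- TRUE
    m
  }
  sizes <- c(2, 4, 8, 16, 32, 64)
  f0 <- fractal_dimension(mk_poly(0, 77), sizes)$fd
  f45 <- fractal_dimension(mk_poly(pi / 4, 77), sizes)$fd
  expect_lt(abs(f45 - f0), 0.05)
})

test_that("FAZ polygon area follows the shoelace formula in mm^2", {
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_equal(faz_area(sq, 5, 5), 0.25)
  tri <- cbind(c(0, 100, 0), c(0, 0, 100))
  expect_equal(faz_area(tri, 10, 10), 0.5)
  expect_error(faz_area(cbind(c(0, 1), c(0, 1)), 5, 5), "at least 3")
  bow <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))
  expect_error(faz_area(bow, 5, 5), "self-intersecting")
})

test_that("compute_all_metrics chains the stages deterministically", {
  net <- generate_vessel_network(size_px = 128, seed = 77, target_density = 0.25)
  vm <- compute_all_metrics(net$angiogram,
                            faz_polygon = cbind(c(10, 40, 40, 10),
                                                c(10, 10, 40, 40)))
  expect_true(all(is.finite(c(vm$vad, vm$vlf, vm$vdi_um, vm$fd, vm$faz_mm2))))
  expect_lte(vm$vlf, vm$vad)
  expect_gte(vm$vdi_um, sqrt(net$angiogram$scale_x * net$angiogram$scale_y))
  vm2 <- compute_all_metrics(net$angiogram,
                             faz_polygon = cbind(c(10, 40, 40, 10),
                                                 c(10, 10, 40, 40)))
  expect_identical(as.data.frame(vm), as.data.frame(vm2))
})
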