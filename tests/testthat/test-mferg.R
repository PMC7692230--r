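test_that("noise-free extraction matches the generator closed form", {
  cases <- list(c(40, 80, 15, 30), c(25, 60, 14, 28), c(50, 120, 18, 35))
  dt <- 1000 / 1200
  for (cs in cases) {
    g <- generate_trace(n1_amp = cs[1], p1_amp = cs[2], n1_it = cs[3],
                        p1_it = cs[4], noise_sd = 0)
    f <- extract_wave_features(g$trace, 1200)
    expect_equal(f$n1_amp, cs[1], tolerance = 0.01)
    expect_equal(f$p1_amp, cs[2], tolerance = 0.01)
    expect_lte(abs(f$n1_it - cs[3]), dt + 1e-9)
    expect_lte(abs(f$p1_it - cs[4]), dt + 1e-9)
  }
})

test_that("implicit times are time-equivariant and amplitudes shift-invariant", {
  g <- generate_trace(noise_sd = 0)
  shift_n <- 6  # 5 ms at 1200 Hz
  shifted <- c(rep(g$trace[1], shift_n),
               g$trace[1:(length(g$trace) - shift_n)])
  f0 <- extract_wave_features(g$trace, 1200)
  f1 <- extract_wave_features(shifted, 1200)
  expect_equal(f1$n1_it - f0$n1_it, 5, tolerance = 1e-9)
  expect_equal(f1$p1_it - f0$p1_it, 5, tolerance = 1e-9)
  expect_equal(f1$p1_amp, f0$p1_amp, tolerance = 0.01)
})

test_that("degenerate traces are refused", {
  expect_error(extract_wave_features(rep(0, 120), 1200), "degenerate")
  expect_error(extract_wave_features(generate_trace()$trace[1:60], 1200),
               "80 ms")
})

test_that("ring summaries average traces before extraction", {
  ## identical traces in every hexagon: all six rings equal the single-trace
  ## features
  wt <- default_wave_truth()
  wt$n1_amp <- 40; wt$p1_amp <- 80  # undo ring scaling
  ts <- generate_traceset(wt)$traceset
  rs <- ring_summary(ts)
  f1 <- extract_wave_features(ts$traces[, 1], ts$sampling_rate)
  expect_equal(nrow(rs), 6)
  expect_true(all(abs(rs$p1_amp - f1$p1_amp) < 1e-6))
  expect_true(all(abs(rs$p1_it - f1$p1_it) < 1e-9))

  ## 1/ring amplitude scaling gives strictly decreasing ring P1-A
  ts2 <- generate_traceset(default_wave_truth())$traceset
  rs2 <- ring_summary(ts2)
  expect_true(all(diff(rs2$p1_amp) < 0))

  ## missing ring assignment is refused at construction
  ring <- mferg_hex_geometry()
  ring <- ring[-5]
  expect_error(mferg_traceset(ts$traces, 1200, ring), "ring")
})

test_that("the normative database uses sample moments and guards degeneracy", {
  mk <- function(eye, it, amp) data.frame(eye_id = eye, hexagon = "h007",
                                          p1_it = it, p1_amp = amp)
  db <- build_normative_db(rbind(mk("a", 30, 70), mk("b", 32, 90)))
  expect_equal(db$mu[db$feature == "p1_it"], 31)
  expect_equal(db$sigma[db$feature == "p1_it"], sqrt(2))
  expect_equal(db$mu[db$feature == "p1_amp"], 80)

  expect_error(build_normative_db(mk("a", 30, 70)), "at least 2")
  expect_error(build_normative_db(rbind(mk("a", 30, 70), mk("b", 30, 70))),
               "degenerate normative variance")
})

test_that("abnormal hexagons follow the inclusive z-score rule", {
  ids <- sprintf("h%03d", 1:19)
  ## exactly representable normative moments so the z = 2 boundary is exact
  db <- data.frame(hexagon = rep(ids, each = 2),
                   feature = rep(c("p1_it", "p1_amp"), 19),
                   mu = rep(c(30, 80), 19), sigma = rep(c(2, 8), 19), n = 3)
  sd_it <- 2; sd_am <- 8
  ef <- data.frame(hexagon = ids, p1_it = 30, p1_amp = 80)
  ## z_it exactly 2 -> abnormal ("2 or higher" is inclusive)
  ef$p1_it[3] <- 30 + 2 * sd_it
  ## z_it 1.9 and z_amp -1.9 -> normal
  ef$p1_it[5] <- 30 + 1.9 * sd_it
  ef$p1_amp[5] <- 80 - 1.9 * sd_am
  ## z_amp exactly -2 -> abnormal
  ef$p1_amp[9] <- 80 - 2 * sd_am
  res <- classify_abnormal(ef, db, ids)
  expect_true(res$hexagons$abnormal[3])
  expect_false(res$hexagons$abnormal[5])
  expect_true(res$hexagons$abnormal[9])
  expect_equal(res$n_abnormal, 2)
  expect_true(res$eye_abnormal)

  ## the AND rule needs both criteria in one hexagon
  res_and <- classify_abnormal(ef, db, ids, rule = "and")
  expect_equal(res_and$n_abnormal, 0)

  ## missing hexagon in the database is an error
  expect_error(classify_abnormal(ef, db[db$hexagon != "h004", ], ids),
               "missing from normative")
})

test_that("classification agrees with a brute-force z-score oracle", {
  ids <- sprintf("h%03d", 1:19)
  set.seed(7)
  for (rep in 1:50) {
    ctrl <- do.call(rbind, lapply(1:6, function(e)
      data.frame(eye_id = sprintf("e%d", e), hexagon = ids,
                 p1_it = rnorm(19, 30, 1.2), p1_amp = rnorm(19, 80, 9))))
    db <- build_normative_db(ctrl)
    ef <- data.frame(hexagon = ids, p1_it = rnorm(19, 31, 2),
                     p1_amp = rnorm(19, 72, 12))
    res <- classify_abnormal(ef, db, ids)
    expect_identical(res$hexagons$abnormal,
                     oracle_classify(ef, db, ids))
    expect_identical(res$eye_abnormal, any(oracle_classify(ef, db, ids)))
  }
})

test_that("band-pass filtering preserves the biphasic waveform", {
  g <- generate_trace(noise_sd = 0)
  filt <- bandpass_traces(g$trace, 1200)
  f <- extract_wave_features(filt, 1200)
  expect_lte(abs(f$p1_it - 30), 1000 / 1200 + 1e-9)
  expect_equal(f$p1_amp, 80, tolerance = 0.1)
})
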