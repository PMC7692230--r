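test_that("with two groups the omnibus F-test reduces to the t-test", {
  set.seed(21)
  d <- data.frame(patient_id = sprintf("P%02d", 1:24), eye_id = 1:24,
                  group = rep(c("control", "DR"), each = 12),
                  value = rnorm(24, 10, 2))
  gc <- compare_groups(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_lt(abs(gc$omnibus_p - tt$p.value), 1e-10)
  expect_equal(gc$pairwise$p_adj, gc$pairwise$p_raw)  # one pair, m = 1
})

test_that("identical group patterns give an omnibus p of 1", {
  jit <- 1 + c(1, 2, 3, 4) * 1e-9
  d <- data.frame(patient_id = sprintf("P%02d", 1:12), eye_id = 1:12,
                  group = rep(c("control", "noDR", "DR"), each = 4),
                  value = rep(jit, 3))
  expect_equal(compare_groups(d)$omnibus_p, 1, tolerance = 1e-6)
})

test_that("Bonferroni adjustment scales raw p by the pair count, capped at 1", {
  set.seed(8)
  d <- data.frame(patient_id = sprintf("P%02d", 1:30), eye_id = 1:30,
                  group = rep(c("control", "noDR", "DR"), each = 10),
                  value = rnorm(30))
  gc <- compare_groups(d)
  expect_equal(nrow(gc$pairwise), 3)
  expect_equal(gc$pairwise$p_adj, pmin(1, 3 * gc$pairwise$p_raw))
  expect_true(all(gc$pairwise$p_adj >= gc$pairwise$p_raw))
  expect_true(all(gc$pairwise$p_adj <= 1))
})

test_that("patient-mean clustering is invariant to fellow-eye labels", {
  m1 <- simulate_cohort_metrics(n_per_group = 6, seed = 31)
  i1 <- seq(1, nrow(m1), by = 2)
  m2 <- m1[c(rbind(i1 + 1, i1)), ]  # swap fellow eyes
  p1 <- compare_groups(m1, "vad_svp")$omnibus_p
  p2 <- compare_groups(m2, "vad_svp")$omnibus_p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("group comparison rejects groups with fewer than two units", {
  d <- data.frame(patient_id = c("P1", "P2", "P3"), eye_id = 1:3,
                  group = c("control", "control", "DR"), value = rnorm(3))
  expect_error(compare_groups(d), "< 2 units")
})

test_that("regression correlation recovers exact linear relations", {
  x <- 1:10
  suppressWarnings(cr <- correlate(x, 2 * x))
  expect_equal(cr$slope, 2)
  expect_lt(cr$p, 1e-10)
  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
})
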