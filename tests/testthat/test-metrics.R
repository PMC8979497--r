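test_that("activity mask applies the >= threshold rule", {
  s <- epoch_series(c(0, 1, 2, 3), c(0, 0, 0, 0))
  m <- active_mask(s, 2)
  expect_equal(m$active_p, c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(active_mask(epoch_series(rep(0, 5), rep(0, 5)))$active_p))
  fx <- active_mask(fixture_series(), 2)
  expect_equal(which(fx$active_p), c(3, 4, 5, 8))
  expect_equal(which(fx$active_np), c(2, 3, 8, 9, 10))
})

test_that("the worked fixture reproduces every enumerated 1 Hz value", {
  m <- compute_all_metrics(fixture_series())
  expect_equal(unname(m["hours_p"]), 4 / 3600)
  expect_equal(unname(m["hours_np"]), 5 / 3600)
  expect_equal(unname(m["iso_hours_p"]), 2 / 3600)
  expect_equal(unname(m["iso_hours_np"]), 3 / 3600)
  expect_equal(unname(m["med_accel_p"]), 5)
  expect_equal(unname(m["bilateral_magnitude"]), 8)
  expect_equal(unname(m["accel_var_p"]), 2.0)
  expect_equal(unname(m["use_ratio"]), 0.8)
  expect_equal(unname(m["magnitude_ratio"]), log(5 / 3) / 2)
  expect_true(all(is.na(m[c("jerk_asym", "sparc_p", "sparc_np")])))
})

test_that("degenerate streams hit the documented fallbacks", {
  z <- epoch_series(rep(0, 10), rep(0, 10))
  m <- compute_all_metrics(z)
  expect_equal(unname(m[c("hours_p", "med_accel_p", "bilateral_magnitude",
                          "accel_var_p")]), c(0, 0, 0, 0))
  expect_true(is.na(m["use_ratio"]))
  # paretic silent, non-paretic active: use ratio 0
  s <- epoch_series(rep(0, 10), rep(5, 10))
  expect_equal(unname(compute_all_metrics(s)["use_ratio"]), 0)
  # identical streams: perfect symmetry
  v <- c(0, 4, 9, 3, 0, 8)
  ms <- compute_all_metrics(epoch_series(v, v))
  expect_equal(unname(ms["use_ratio"]), 1)
  expect_equal(unname(ms["magnitude_ratio"]), 0)
})

test_that("swapping limb roles anti-symmetrizes the ratio metrics", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_stream(400); b <- random_stream(400)
    m1 <- compute_all_metrics(epoch_series(a, b))
    m2 <- compute_all_metrics(epoch_series(b, a))
    expect_equal(unname(m1["hours_p"]), unname(m2["hours_np"]))
    expect_equal(unname(m1["iso_hours_p"]), unname(m2["iso_hours_np"]))
    if (!is.na(m1["use_ratio"]) && !is.na(m2["use_ratio"]) &&
        m1["use_ratio"] > 0)
      expect_equal(unname(m1["use_ratio"]), 1 / unname(m2["use_ratio"]))
    if (!is.na(m1["magnitude_ratio"]))
      expect_equal(unname(m1["magnitude_ratio"]),
                   -unname(m2["magnitude_ratio"]))
  }
})

test_that("appending inactive seconds changes no metric", {
  set.seed(8)
  a <- random_stream(500); b <- random_stream(500)
  m1 <- compute_all_metrics(epoch_series(a, b))
  m2 <- compute_all_metrics(epoch_series(c(a, rep(0, 300)),
                                         c(b, rep(0, 300))))
  expect_identical(m1, m2)
})

test_that("vectorized 1 Hz metrics equal the per-second enumeration oracle", {
  set.seed(9)
  for (i in 1:50) {
    a <- random_stream(300); b <- random_stream(300)
    got <- compute_all_metrics(epoch_series(a, b))[1:9]
    expect_identical(got, oracle_metrics(a, b))
  }
})

test_that("jerk asymmetry follows its definition and sign convention", {
  r <- raw_recording(rnorm(100), rnorm(100), rnorm(100))
  expect_equal(jerk_asymmetry_index(r, r), 0)
  # paretic jerk 2x the non-paretic: index = 1/3
  t <- seq(0, 10, by = 1 / 30)
  mk <- function(amp) raw_recording(amp * sin(2 * pi * t), 0 * t, 0 * t)
  expect_equal(jerk_asymmetry_index(mk(2), mk(1)), 1 / 3, tolerance = 1e-10)
  # constant (zero-jerk) paretic vs moving non-paretic: boundary -1
  still <- raw_recording(rep(1, 301), rep(0, 301), rep(0, 301))
  expect_equal(jerk_asymmetry_index(still, mk(1)), -1)
  bad <- raw_recording(rnorm(10), rnorm(10), rnorm(10), sample_rate = 60)
  expect_error(jerk_asymmetry_index(r, bad), "sample-rate")
})

test_that("SPARC: DC limit, amplitude invariance, noise ordering", {
  # constant-magnitude bout: spectrum concentrated at DC, SAL -> -1
  const <- raw_recording(rep(0.5, 1800), rep(0, 1800), rep(0, 1800))
  expect_equal(sparc(const, rep(TRUE, 60)), -1, tolerance = 0.05)

  b <- generate_raw_bout(8, smoothness = "noisy", noise_amp = 0.05, seed = 3)
  s0 <- sparc(b, rep(TRUE, 8))
  expect_lte(s0, -1)
  b2 <- b; b2$ax <- 2 * b$ax; b2$ay <- 2 * b$ay; b2$az <- 2 * b$az
  expect_identical(sparc(b2, rep(TRUE, 8)), s0)  # scale cancels exactly

  # smoothness ordering: a rippled copy of a smooth bout is less smooth
  for (i in 1:10) {
    sm <- generate_raw_bout(8, smoothness = "smooth", seed = i)
    no <- generate_raw_bout(8, smoothness = "noisy", noise_amp = 0.1,
                            seed = i)
    expect_gt(sparc(sm, rep(TRUE, 8)), sparc(no, rep(TRUE, 8)))
  }
  # no active second: undefined
  expect_true(is.na(sparc(const, rep(FALSE, 60))))
})

test_that("30 Hz variables join the assembled metric vector when raw given", {
  pair <- ulperf:::generate_raw_subject(0.3, 0.05, seed = 11)
  s <- epoch_series(random_stream(60), random_stream(60))
  m <- compute_all_metrics(s, pair$raw_p, pair$raw_np)
  expect_false(anyNA(m[c("jerk_asym", "sparc_p", "sparc_np")]))
  expect_gt(m["jerk_asym"], 0)          # noisier paretic limb
  expect_lt(m["sparc_p"], m["sparc_np"])  # and less smooth
  expect_true(m["jerk_asym"] >= -1 && m["jerk_asym"] <= 1)
  # identical raw recordings: symmetric quality metrics
  m2 <- compute_all_metrics(s, pair$raw_p, pair$raw_p)
  expect_equal(unname(m2["jerk_asym"]), 0)
  expect_equal(unname(m2["sparc_p"]), unname(m2["sparc_np"]))
})
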