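test_that("winsorization clips exactly to percentile bounds", {
  # constant and singleton series are unchanged
  expect_equal(winsorize_series(rep(3, 50)), rep(3, 50))
  expect_equal(winsorize_series(7), 7)
  expect_error(winsorize_series(numeric(0)), "empty")

  # an extreme outlier is pulled back to the 99th percentile of the input,
  # against a sort-based percentile oracle
  x <- as.numeric(1:1000)
  x[500] <- 1e6
  w <- winsorize_series(x, 1, 99)
  expect_equal(max(w), oracle_percentile(x, 99))
  expect_equal(min(w), oracle_percentile(x, 1))

  # values inside the band are untouched
  inside <- x > oracle_percentile(x, 1) & x < oracle_percentile(x, 99)
  expect_equal(w[inside], x[inside])
})

test_that("winsorization is idempotent and matches the oracle on random series", {
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(50:500, 1), sd = sample(1:20, 1))
    w <- winsorize_series(x)
    expect_equal(w, oracle_winsorize(x))
    # idempotent up to interpolation at the clip boundary: re-clipping only
    # touches values sitting at the clip bounds, and moves them at most
    # within the tie-induced percentile gap
    w2 <- winsorize_series(w)
    inner <- w > oracle_percentile(w, 1) & w < oracle_percentile(w, 99)
    expect_equal(w2[inner], w[inner])
    expect_lt(max(abs(w2 - w)), 0.05 * diff(range(w)) + 1e-12)
  }
})

test_that("moving-average smoothing is centered with edge shrinkage", {
  x <- rnorm(100)
  expect_equal(smooth_series(x, 1), x)
  expect_error(smooth_series(x, 0), ">= 1")

  # interior of a linear ramp is invariant under a centered window,
  # via a direct convolution oracle
  ramp <- seq(0, 10, length.out = 200)
  sm <- smooth_series(ramp, 5)
  expect_equal(sm[3:198], ramp[3:198])
  expect_equal(sm, oracle_smooth(ramp, 5))

  set.seed(1)
  for (w in c(2, 3, 7, 10)) {
    z <- rnorm(57)
    expect_equal(smooth_series(z, w), oracle_smooth(z, w))
  }

  # variance of smoothed iid noise shrinks like 1/window
  set.seed(2)
  n <- 1e4
  noise <- rnorm(n)
  for (w in c(5, 9)) {
    v <- var(smooth_series(noise, w)[w:(n - w)])
    expect_lt(abs(v - 1 / w) / (1 / w), 0.2)
  }
})

test_that("movement counting obeys the hysteresis rule", {
  # monotone ramps and constants have no direction change
  expect_equal(count_movements(seq(0, 50, by = 0.5)), 0L)
  expect_equal(count_movements(rep(2, 100)), 0L)
  expect_equal(count_movements(numeric(0)), 0L)

  # triangle wave with 9 interior extrema, amplitude far above hysteresis
  tri <- 20 * rep(c(seq(0, 1, by = 0.1), seq(0.9, 0.1, by = -0.1)), 5)
  expect_equal(count_movements(tri, 2), oracle_movements(tri, 2))
  expect_equal(count_movements(tri, 2), 9L)

  # a stream constructed with 10 qualifying direction changes
  zigzag <- 15 * sin(2 * pi * seq(0, 5, by = 0.01))  # 10 interior extrema
  expect_equal(count_movements(zigzag, 2), 10L)

  # sub-hysteresis wiggles do not count
  small <- 0.5 * sin(2 * pi * seq(0, 5, by = 0.01))
  expect_equal(count_movements(small, 2), 0L)
})

test_that("movement count is offset- and scale-invariant above hysteresis", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_stream(400)
    base <- count_movements(s$angle_deg, 2)
    expect_equal(count_movements(s$angle_deg + 100, 2), base)
    # scaling amplitude and hysteresis together preserves the count
    expect_equal(count_movements(3 * s$angle_deg, 6), base)
    expect_equal(base, oracle_movements(s$angle_deg, 2))
  }
})

test_that("directional forces match the analytic sinusoid derivative", {
  expect_equal(centripetal_forces(rep(1, 100), 30), c(F_flex = 0, F_ext = 0))
  expect_error(centripetal_forces(c(1, 2), 30), "3 samples")

  A <- 30; f <- 0.5; rate <- 30
  t <- seq(0, 20, by = 1 / rate)
  theta <- A * sin(2 * pi * f * t)
  expected <- (2 * pi * f * A * pi / 180)^2
  ff <- centripetal_forces(theta, rate, 1)
  expect_lt(abs(ff["F_ext"] - expected) / expected, 0.01)
  expect_lt(abs(-ff["F_flex"] - expected) / expected, 0.01)
  # pure sinusoid: flexion and extension maxima are symmetric
  expect_lt(abs(ff["F_ext"] + ff["F_flex"]), 1e-6 * expected)
})

test_that("force sign convention holds on arbitrary streams", {
  set.seed(4)
  for (i in 1:20) {
    s <- random_stream(200)
    ff <- centripetal_forces(s$angle_deg, 30, 1)
    expect_lte(ff["F_flex"], 0)
    expect_gte(ff["F_ext"], 0)
    expect_equal(ff, oracle_forces(s$angle_deg, 30, 1))
  }
})

test_that("an idle stream summarizes to zeros with full game time", {
  s <- make_stream(rep(0, 450), rep(0, 450), rate_hz = 30)
  f <- summarize_activity(s)
  expect_equal(f$R_min, 0)
  expect_equal(f$R_max, 0)
  expect_equal(f$R_mean, 0)
  expect_equal(f$P_min, 0)
  expect_equal(f$P_max, 0)
  expect_equal(f$P_mean, 0)
  expect_equal(f$N_mov, 0L)
  expect_equal(f$F_flex, 0)
  expect_equal(f$F_ext, 0)
  expect_equal(f$t_game, 15)
  expect_equal(f$Score, 0)
})

test_that("the feature row carries exactly the data-dictionary fields", {
  f <- summarize_activity(make_stream(rnorm(100)))
  expect_setequal(
    names(f),
    c("patient", "session", "game", rehab_feature_names(include_r_mean = TRUE))
  )
  expect_length(rehab_feature_names(), 11)
})

test_that("summaries agree with a naive full-scan oracle and ROM is recovered", {
  params <- cleaning_params()
  set.seed(6)
  for (i in 1:30) {
    s <- random_stream(sample(150:600, 1))
    f <- summarize_activity(s, params)
    clean_a <- oracle_smooth(oracle_winsorize(s$angle_deg), params$smooth_window)
    clean_p <- oracle_smooth(oracle_winsorize(s$pressure_psi), params$smooth_window)
    expect_equal(f$R_min, min(clean_a))
    expect_equal(f$R_max, max(clean_a))
    expect_equal(f$R_mean, mean(clean_a))
    expect_equal(f$P_min, min(clean_p))
    expect_equal(f$P_max, max(clean_p))
    expect_equal(f$P_mean, mean(clean_p))
    expect_equal(f$N_mov, oracle_movements(clean_a, params$movement_hysteresis_deg))
    expect_equal(
      c(F_flex = f$F_flex, F_ext = f$F_ext),
      oracle_forces(clean_a, 30, params$force_constant)
    )
    # order invariants
    expect_lte(f$R_min, f$R_mean)
    expect_lte(f$R_mean, f$R_max)
    expect_lte(f$P_min, f$P_mean)
    expect_lte(f$P_mean, f$P_max)
  }

  # known waveform: extracted ROM within 5% of the configured excursion
  A <- 25
  p <- class_profile("high", c(A, 0), c(2, 0), 0.8, noise_sd_deg = 0,
                     spike_prob = 0)
  f <- summarize_activity(simulate_activity(p, 120, 30, seed = 13), params)
  expect_lt(abs((f$R_max - f$R_min) - 2 * A) / (2 * A), 0.05)
})

test_that("score feature is the maximum cumulative score", {
  ev <- data.frame(time_s = c(1, 4, 9), score = c(10, 25, 18))
  f <- summarize_activity(make_stream(rnorm(300), score = ev))
  expect_equal(f$Score, 25)
})
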