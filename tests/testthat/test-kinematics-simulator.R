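test_that("stream length follows duration x rate", {
  p <- default_profiles()$high
  s <- simulate_activity(p, duration_s = 60, rate_hz = 30, seed = 1)
  expect_length(s$angle_deg, 1800)
  expect_length(s$pressure_psi, 1800)
  expect_length(s$time_s, 1800)
  expect_true(all(diff(s$time_s) > 0))
  expect_equal(diff(s$time_s), rep(1 / 30, 1799))

  expect_error(simulate_activity(p, duration_s = 0), "positive")
  expect_error(simulate_activity(p, duration_s = 10, rate_hz = -1), "positive")
})

test_that("degenerate zero-amplitude profile yields a constant angle channel", {
  p <- class_profile("no", c(0, 0), c(1, 0), movement_rate_hz = 0.5,
                     noise_sd_deg = 0, spike_prob = 0, spike_scale = 0)
  s <- simulate_activity(p, 30, 30, seed = 4)
  expect_equal(s$angle_deg, rep(0, length(s$angle_deg)))
})

test_that("noise-free empirical range matches the closed-form waveform amplitude", {
  A <- 40
  p <- class_profile("high", c(A, 0), c(1, 0), movement_rate_hz = 0.8,
                     noise_sd_deg = 0, spike_prob = 0, spike_scale = 0)
  s <- simulate_activity(p, 120, 30, seed = 9)
  emp_range <- max(s$angle_deg) - min(s$angle_deg)
  expect_lt(abs(emp_range - 2 * A) / (2 * A), 0.05)

  # dense evaluation of the configured two-sinusoid waveform reaches the
  # same peak-to-peak range for arbitrary phase draws
  f <- 0.4
  t <- seq(0, 120, by = 1 / 300)
  set.seed(11)
  for (rep in 1:5) {
    phi <- runif(2, 0, 2 * pi)
    w <- A * (0.85 * sin(2 * pi * f * t + phi[1]) +
                0.15 * sin(2 * pi * pi * f * t + phi[2]))
    expect_lt(abs((max(w) - min(w)) - 2 * A) / (2 * A), 0.05)
  }
})

test_that("simulated assessments are label-consistent and protocol-shaped", {
  profs <- default_profiles()
  # emitted label always equals the generating truth label
  for (lv in class_levels()) {
    labs <- vapply(1:100, function(i) {
      simulate_assessment(lv, profs[[lv]], seed = i)$label
    }, character(1))
    expect_true(all(labs == lv))
  }
  # assessment type rules: high always assisted, no always passive
  types_high <- vapply(1:50, function(i)
    simulate_assessment("high", profs$high, seed = i)$assessment, character(1))
  types_no <- vapply(1:50, function(i)
    simulate_assessment("no", profs$no, seed = i)$assessment, character(1))
  types_low <- vapply(1:100, function(i)
    simulate_assessment("low", profs$low, seed = i)$assessment, character(1))
  expect_true(all(types_high == "assisted"))
  expect_true(all(types_no == "passive"))
  expect_setequal(unique(types_low), c("passive", "assisted"))

  # a no-ROM record is shaped like a passive clinician row: positive max,
  # negative min, plausible wrist angles
  a <- simulate_assessment("no", profs$no, seed = 3, patient = 1495L)
  expect_equal(a$assessment, "passive")
  expect_equal(a$label, "no")
  expect_true(a$max_angle > 0 && a$max_angle < 90)
  expect_true(a$min_angle < 0 && a$min_angle > -60)

  # zero-ROM zero-noise profile collapses to the rest angle
  pz <- class_profile("no", c(0, 0), c(1, 0), 0.5, noise_sd_deg = 0,
                      spike_prob = 0, spike_scale = 0)
  az <- simulate_assessment("no", pz, seed = 1)
  expect_equal(az$max_angle, 0)
  expect_equal(az$min_angle, 0)

  expect_error(simulate_assessment("none", profs$no), "arg")
})

test_that("cohorts are reproducible, sized, and within configured ranges", {
  cfg <- simulation_config(n_patients = 6, sessions_per_patient_range = c(2, 3),
                           session_minutes_range = c(5, 20), seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  c2 <- simulate_cohort(simulation_config(n_patients = 6,
                                          sessions_per_patient_range = c(2, 3),
                                          session_minutes_range = c(5, 20),
                                          seed = 22))
  expect_false(identical(serialize(a, NULL), serialize(c2, NULL)))

  expect_equal(length(unique(vapply(a$streams, `[[`, numeric(1), "patient"))), 6)
  expect_equal(length(a$truth_labels), 6)
  expect_equal(nrow(a$assessments), 6)
  # every stream's patient has exactly one truth label, consistent with the
  # assessment table
  for (s in a$streams) {
    expect_true(as.character(s$patient) %in% names(a$truth_labels))
  }
  expect_equal(
    unname(a$truth_labels[as.character(a$assessments$patient)]),
    a$assessments$label
  )

  # session durations and activity counts within configured ranges
  key <- paste(vapply(a$streams, `[[`, numeric(1), "patient"),
               vapply(a$streams, `[[`, numeric(1), "session"))
  durs <- vapply(a$streams, function(s) length(s$time_s) / s$rate_hz, numeric(1))
  session_minutes <- tapply(durs, key, sum) / 60
  expect_true(all(session_minutes >= 5 - 1e-6 & session_minutes <= 20 + 1e-6))
  acts_per_session <- as.vector(table(key))
  expect_true(all(acts_per_session >= 1 & acts_per_session <= 10))
})

test_that("an empty cohort is valid", {
  cfg <- simulation_config(n_patients = 0, seed = 1)
  co <- simulate_cohort(cfg)
  expect_length(co$streams, 0)
  expect_length(co$truth_labels, 0)
  expect_equal(nrow(co$assessments), 0)
})

test_that("invalid class mixtures are rejected", {
  expect_error(simulation_config(class_mix = c(0.5, 0.5, 0.5)), "sum")
  expect_error(simulation_config(class_mix = c(-0.2, 0.6, 0.6)), "nonnegative")
})

test_that("mean empirical ROM is ordered no < low < high under default profiles", {
  profs <- default_profiles()
  rom <- sapply(class_levels(), function(lv) {
    mean(vapply(1:100, function(i) {
      s <- simulate_activity(profs[[lv]], 40, 30, seed = 7000 + i)
      f <- summarize_activity(s)
      f$R_max - f$R_min
    }, numeric(1)))
  })
  expect_lt(rom["no"], rom["low"])
  expect_lt(rom["low"], rom["high"])
})

test_that("streaming feature generation matches the materialized cohort path", {
  cfg <- simulation_config(n_patients = 4, sessions_per_patient_range = c(2, 2),
                           session_minutes_range = c(5, 10), seed = 31)
  via_stream <- simulate_features(cfg)
  via_cohort <- cohort_features(simulate_cohort(cfg))
  expect_equal(via_stream$features, via_cohort, ignore_attr = TRUE)
})

test_that("monotone-scoring games have nondecreasing cumulative scores", {
  set.seed(5)
  mono <- 0
  for (i in 1:200) {
    ev <- rehabsev:::.simulate_score_events(300)
    if (nrow(ev) >= 2 && all(diff(ev$score) >= 0)) mono <- mono + 1
    if (nrow(ev) >= 2) expect_true(all(diff(ev$time_s) >= 0))
  }
  expect_gt(mono, 0)  # monotone games exist; non-monotone ones are allowed
})
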