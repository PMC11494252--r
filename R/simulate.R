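# Synthetic cohort generator: 30 Hz angle/pressure streams for three
# residual-severity classes, with clinician-style assessments carrying the
# ground-truth labels.

#' Simulate one therapeutic activity's sensor stream
#'
#' Generates a raw 30 Hz (by default) angle/pressure stream for a single
#' therapeutic activity (game). The angle channel is the sum of a
#' quasi-periodic volitional waveform, Gaussian sensor noise, and occasional
#' outlier spikes; the pressure channel is an assistance level modulated in
#' antiphase with the movement plus sensor noise. Score events arrive as a
#' sparse cumulative series with a per-game (unstandardized) scale.
#'
#' The volitional waveform is `A * ((1-j) sin(2 pi f t + phi1) +
#' j sin(2 pi (pi f) t + phi2))` with jitter fraction `j = 0.15`: a slow
#' task-following sinusoid at `f = movement_rate_hz / 2` plus a faster,
#' incommensurate jitter sinusoid. The irrational frequency ratio makes the
#' envelope sweep its full range over an activity, so the peak-to-peak
#' excursion approaches `2A` regardless of the phase draw, while the jitter
#' never adds direction changes (its slope contribution is below the main
#' component's).
#'
#' @param profile A [class_profile()].
#' @param duration_s Activity duration in seconds (> 0).
#' @param rate_hz Sampling rate in Hz (> 0), 30 by default.
#' @param peripheral `"hand"` or `"foot"`.
#' @param seed Optional integer seed; given the same seed the stream is
#'   reproduced exactly.
#' @param ids Named list/vector with `patient`, `session`, `game`
#'   identifiers.
#' @return An object of class `sensor_stream`: list with `time_s`,
#'   `angle_deg`, `pressure_psi`, `score_events` (data.frame `time_s`,
#'   `score`), `peripheral`, `rate_hz` and the identifiers.
#' @export
simulate_activity <- function(profile, duration_s, rate_hz = 30,
                              peripheral = c("hand", "foot"), seed = NULL,
                              ids = list(patient = 1L, session = 1L, game = 1L)) {
  if (!inherits(profile, "class_profile")) stop("profile must be a class_profile")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  peripheral <- match.arg(peripheral)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- ceiling(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz

  # volitional component around the 0 deg rest midpoint
  amp <- max(stats::rnorm(1, profile$volitional_amplitude_deg[1],
                          profile$volitional_amplitude_deg[2]), 0)
  f <- profile$movement_rate_hz / 2
  phi <- stats::runif(2, 0, 2 * pi)
  jit <- 0.15
  wave <- (1 - jit) * sin(2 * pi * f * t + phi[1]) +
    jit * sin(2 * pi * (pi * f) * t + phi[2])
  angle <- amp * wave + stats::rnorm(n, 0, profile$noise_sd_deg)

  # outlier spikes: transient sensor faults at rest +/- spike_scale * amp
  spike <- stats::runif(n) < profile$spike_prob
  n_spike <- sum(spike)
  if (n_spike > 0) {
    angle[spike] <- sample(c(-1, 1), n_spike, replace = TRUE) *
      profile$spike_scale * max(amp, 1)
  }

  # assistance pressure, modulated in antiphase with the volitional wave
  p0 <- max(stats::rnorm(1, profile$assist_pressure_psi[1],
                         profile$assist_pressure_psi[2]), 0)
  pressure <- p0 * (0.6 + 0.4 * sin(2 * pi * f * t + phi[1] + pi)) +
    stats::rnorm(n, 0, 0.15)

  score_events <- .simulate_score_events(duration_s)

  structure(
    list(
      time_s = t,
      angle_deg = angle,
      pressure_psi = pressure,
      score_events = score_events,
      peripheral = peripheral,
      rate_hz = rate_hz,
      patient = ids$patient,
      session = ids$session,
      game = ids$game
    ),
    class = "sensor_stream"
  )
}

# Sparse cumulative score events with a per-game scale; ~70% of games score
# monotonically, the rest can lose points.
.simulate_score_events <- function(duration_s, event_rate = 0.15) {
  n_ev <- stats::rpois(1, event_rate * duration_s)
  if (n_ev == 0) {
    return(data.frame(time_s = numeric(0), score = numeric(0)))
  }
  times <- sort(stats::runif(n_ev, 0, duration_s))
  scale <- exp(stats::runif(1, 0, 4))       # scores are not standardized
  monotone <- stats::runif(1) < 0.7
  inc <- (stats::rpois(n_ev, 3) + 1) * scale
  if (!monotone) {
    flip <- stats::runif(n_ev) < 0.15
    inc[flip] <- -inc[flip]
  }
  data.frame(time_s = times, score = round(cumsum(inc)))
}

#' Simulate a clinician-style range-of-motion assessment
#'
#' Draws a Table-1-shaped assessment record (max/min angle reached, the most
#' arduous assessment type performed, and the severity label) consistent
#' with a class profile. Stretch gains are class-conditional: patients with
#' no volitional ROM are stretched passively far beyond their own movement,
#' while high-ROM patients reach angles comparable to their volitional
#' excursion under assistance. The emitted label always equals the
#' generating truth label; the clinician's judgment itself is not modeled.
#'
#' Assessment type follows the labeling protocol: every high-ROM patient
#' completed the assisted assessment; low-ROM patients completed either the
#' passive or the assisted one; no-ROM patients only the passive one.
#'
#' @param truth_label `"no"`, `"low"`, or `"high"`.
#' @param profile The [class_profile()] the patient was generated from.
#' @param seed Optional integer seed.
#' @param patient Patient identifier carried into the record.
#' @param subtype For low-ROM patients, optionally force the `"passive"` or
#'   `"assisted"` subtype (otherwise drawn at the protocol's 60/40 rate).
#' @return One-row data.frame with columns `patient`, `max_angle`,
#'   `min_angle`, `assessment`, `label`.
#' @export
simulate_assessment <- function(truth_label, profile, seed = NULL,
                                patient = NA_integer_, subtype = NULL) {
  truth_label <- match.arg(truth_label, class_levels())
  if (!inherits(profile, "class_profile")) stop("profile must be a class_profile")
  if (!is.null(seed)) set.seed(as.integer(seed))

  gains <- switch(truth_label,
    no = c(max = 12, min = 5),
    low = c(max = 2.2, min = 1.2),
    high = c(max = 0.5, min = 0.45)
  )
  amp <- max(stats::rnorm(1, profile$volitional_amplitude_deg[1],
                          profile$volitional_amplitude_deg[2]), 0)
  jitter_sd <- 3 * profile$noise_sd_deg
  max_angle <- round(gains["max"] * amp + stats::rnorm(1, 0, jitter_sd))
  min_angle <- round(-gains["min"] * amp + stats::rnorm(1, 0, jitter_sd))
  if (min_angle > max_angle) min_angle <- max_angle

  assessment <- switch(truth_label,
    no = "passive",
    low = if (!is.null(subtype) && !is.na(subtype)) subtype
          else sample(c("passive", "assisted"), 1, prob = c(0.6, 0.4)),
    high = "assisted"
  )
  data.frame(
    patient = patient,
    max_angle = as.numeric(max_angle),
    min_angle = as.numeric(min_angle),
    assessment = assessment,
    label = truth_label,
    stringsAsFactors = FALSE
  )
}

# Deterministic cohort plan: all patient/session/activity-level draws are
# made here under the master seed, and each stream gets its own derived seed
# (seed * 1009 + stream counter, mod 2^31 - 1) so any single stream can be
# regenerated without replaying the whole cohort.
.cohort_plan <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0) {
    return(list(activities = NULL, patients = NULL))
  }
  pid <- sample(1000:2999, n)
  cls <- sample(class_levels(), n, replace = TRUE, prob = config$class_mix)
  periph <- ifelse(stats::runif(n) < config$foot_prob, "foot", "hand")

  patients <- data.frame(
    patient = pid, class = cls, peripheral = periph,
    stringsAsFactors = FALSE
  )
  rows <- vector("list", n)
  counter <- 0L
  modulus <- 2147483647
  for (i in seq_len(n)) {
    prof <- config$profiles[[cls[i]]]
    scale <- if (periph[i] == "foot") config$foot_rom_scale else 1
    # Between-patient heterogeneity is deliberately larger than
    # within-patient variability: each patient gets their own amplitude,
    # assistance and pace drawn from wide class distributions (patient
    # clusters from different classes interleave in feature space), while
    # activities of one patient stay tightly clustered.
    amp_base <- max(stats::rnorm(1, prof$volitional_amplitude_deg[1],
                                 prof$volitional_amplitude_deg[2]), 0.3)
    assist_mean <- max(stats::rnorm(1, prof$assist_pressure_psi[1],
                                    prof$assist_pressure_psi[2]), 0.3)
    rate_mult <- 1
    # The low-ROM label pools two subpopulations (the labeling protocol
    # keeps patients who did and did not tolerate the assisted assessment):
    # a passive subtype with modest excursion under little assistance, and
    # an assisted subtype whose slow device-driven excursion exceeds even
    # the high-ROM volitional range under near-maximal assistance.
    subtype <- NA_character_
    if (cls[i] == "low") {
      subtype <- if (stats::runif(1) < 0.4) "assisted" else "passive"
      if (subtype == "assisted") {
        amp_base <- amp_base * 3.2
        assist_mean <- max(stats::rnorm(1, 6.5, 2), 0.3)
        rate_mult <- 0.75
      } else {
        amp_base <- amp_base * 0.75
        assist_mean <- max(stats::rnorm(1, 3, 1.5), 0.3)
      }
    }
    amp_mean <- amp_base * scale
    amp_sd <- 0.08 * amp_mean + 0.3
    rate <- prof$movement_rate_hz * stats::runif(1, 0.6, 1.4) * rate_mult

    n_sessions <- sample(seq(config$sessions_per_patient_range[1],
                             config$sessions_per_patient_range[2]), 1)
    per_patient <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      minutes <- stats::runif(1, config$session_minutes_range[1],
                              config$session_minutes_range[2])
      n_act <- sample(seq(config$activities_per_session_range[1],
                          config$activities_per_session_range[2]), 1)
      w <- stats::rexp(n_act) + 0.5
      durations <- minutes * 60 * w / sum(w)
      games <- sample(1:30, n_act, replace = TRUE)
      seeds <- (as.numeric(config$seed) * 1009 + counter + seq_len(n_act)) %% modulus
      counter <- counter + n_act
      per_patient[[s]] <- data.frame(
        patient = pid[i], class = cls[i], subtype = subtype,
        peripheral = periph[i],
        session = s, game = games, duration_s = durations,
        stream_seed = seeds,
        amp_mean = amp_mean, amp_sd = amp_sd,
        assist_mean = assist_mean, assist_sd = 0.25,
        rate = rate, noise = prof$noise_sd_deg,
        spike_prob = prof$spike_prob, spike_scale = prof$spike_scale,
        stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- do.call(rbind, per_patient)
  }
  activities <- do.call(rbind, rows)
  activities$assess_seed <-
    (as.numeric(config$seed) * 1009 + 500000000 +
       match(activities$patient, pid)) %% modulus
  list(activities = activities, patients = patients)
}

.profile_from_plan_row <- function(row) {
  class_profile(row$class,
    volitional_amplitude_deg = c(row$amp_mean, row$amp_sd),
    assist_pressure_psi = c(row$assist_mean, row$assist_sd),
    movement_rate_hz = row$rate,
    noise_sd_deg = row$noise,
    spike_prob = row$spike_prob,
    spike_scale = row$spike_scale
  )
}

.plan_assessments <- function(plan, config) {
  if (is.null(plan$patients)) {
    return(data.frame(patient = integer(0), max_angle = numeric(0),
                      min_angle = numeric(0), assessment = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  first_rows <- plan$activities[!duplicated(plan$activities$patient), ]
  out <- lapply(seq_len(nrow(first_rows)), function(i) {
    row <- first_rows[i, ]
    simulate_assessment(row$class, .profile_from_plan_row(row),
                        seed = row$assess_seed, patient = row$patient,
                        subtype = row$subtype)
  })
  do.call(rbind, out)
}

#' Simulate a full therapy cohort with raw streams
#'
#' Generates `n_patients` patients, each with several sessions of 1-10
#' activities and session lengths in the configured 5-60 minute range,
#' together with one clinician-style assessment per patient carrying the
#' ground-truth severity label. Fully reproducible from `config$seed`.
#'
#' For large cohorts the raw streams dominate memory; use
#' [simulate_features()] to stream activity-by-activity directly into
#' feature rows instead.
#'
#' @param config A [simulation_config()].
#' @return An object of class `cohort`: list with `streams` (list of
#'   [simulate_activity()] streams), `truth_labels` (named character vector,
#'   patient -> class), `assessments` (data.frame), and `config`.
#' @export
simulate_cohort <- function(config) {
  plan <- .cohort_plan(config)
  assessments <- .plan_assessments(plan, config)
  acts <- plan$activities
  streams <- list()
  if (!is.null(acts)) {
    streams <- lapply(seq_len(nrow(acts)), function(i) {
      row <- acts[i, ]
      simulate_activity(.profile_from_plan_row(row), row$duration_s,
                        rate_hz = config$sample_rate_hz,
                        peripheral = row$peripheral, seed = row$stream_seed,
                        ids = list(patient = row$patient, session = row$session,
                                   game = row$game))
    })
  }
  truth <- character(0)
  if (!is.null(plan$patients)) {
    truth <- stats::setNames(plan$patients$class,
                             as.character(plan$patients$patient))
  }
  structure(
    list(streams = streams, truth_labels = truth,
         assessments = assessments, config = config),
    class = "cohort"
  )
}

#' Simulate a cohort directly to activity-level feature rows
#'
#' Equivalent to [simulate_cohort()] followed by [cohort_features()], but
#' each raw stream is summarized and discarded immediately, so memory stays
#' flat regardless of cohort size. The same derived per-stream seeds are
#' used, so features agree exactly with the materialized-cohort path.
#'
#' @param config A [simulation_config()].
#' @param params A [cleaning_params()].
#' @return List with `features` (data.frame of activity feature rows),
#'   `assessments`, and `truth_labels`.
#' @export
simulate_features <- function(config, params = cleaning_params()) {
  plan <- .cohort_plan(config)
  assessments <- .plan_assessments(plan, config)
  acts <- plan$activities
  feats <- NULL
  if (!is.null(acts)) {
    rows <- lapply(seq_len(nrow(acts)), function(i) {
      row <- acts[i, ]
      stream <- simulate_activity(.profile_from_plan_row(row), row$duration_s,
                                  rate_hz = config$sample_rate_hz,
                                  peripheral = row$peripheral,
                                  seed = row$stream_seed,
                                  ids = list(patient = row$patient,
                                             session = row$session,
                                             game = row$game))
      summarize_activity(stream, params)
    })
    feats <- do.call(rbind, rows)
  }
  truth <- character(0)
  if (!is.null(plan$patients)) {
    truth <- stats::setNames(plan$patients$class,
                             as.character(plan$patients$patient))
  }
  list(features = feats, assessments = assessments, truth_labels = truth)
}

#' Summarize every stream of a cohort into feature rows
#'
#' @param cohort A [simulate_cohort()] result.
#' @param params A [cleaning_params()].
#' @return data.frame with one [summarize_activity()] row per stream.
#' @export
cohort_features <- function(cohort, params = cleaning_params()) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(cohort$streams) == 0) return(NULL)
  do.call(rbind, lapply(cohort$streams, summarize_activity, params = params))
}
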