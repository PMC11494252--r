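#' Severity class levels
#'
#' Canonical ordering of the residual-severity classes and their integer
#' encoding. Classes are ordered by increasing residual range of motion:
#' `"no"` (0), `"low"` (1), `"high"` (2).
#'
#' @return Character vector `c("no", "low", "high")`.
#' @export
class_levels <- function() c("no", "low", "high")

#' Define a severity class profile for the kinematics simulator
#'
#' A class profile describes the statistical signature of one residual
#' severity class: how much volitional range of motion (ROM) patients in the
#' class generate on their own, how much pneumatic assistance the device
#' supplies, how often they reverse direction, and how noisy the angle
#' sensor channel is.
#'
#' @param label One of `"no"`, `"low"`, `"high"`.
#' @param volitional_amplitude_deg Length-2 numeric `c(mean, sd)`: half
#'   peak-to-peak amplitude, in degrees, of the self-generated angular
#'   excursion around the rest midpoint.
#' @param assist_pressure_psi Length-2 numeric `c(mean, sd)`: assistance
#'   pressure level in PSI.
#' @param movement_rate_hz Mean rate of direction changes per second.
#' @param noise_sd_deg Standard deviation of additive sensor noise, degrees.
#' @param spike_prob Per-sample probability of an outlier spike.
#' @param spike_scale Spike magnitude as a multiple of the activity
#'   amplitude.
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(label,
                          volitional_amplitude_deg,
                          assist_pressure_psi,
                          movement_rate_hz,
                          noise_sd_deg = 0.8,
                          spike_prob = 0.002,
                          spike_scale = 4) {
  label <- match.arg(label, class_levels())
  volitional_amplitude_deg <- as.numeric(volitional_amplitude_deg)
  assist_pressure_psi <- as.numeric(assist_pressure_psi)
  if (length(volitional_amplitude_deg) != 2 || any(volitional_amplitude_deg < 0))
    stop("volitional_amplitude_deg must be c(mean, sd) with both >= 0")
  if (length(assist_pressure_psi) != 2 || any(assist_pressure_psi < 0))
    stop("assist_pressure_psi must be c(mean, sd) with both >= 0")
  if (movement_rate_hz <= 0) stop("movement_rate_hz must be positive")
  if (noise_sd_deg < 0) stop("noise_sd_deg must be >= 0")
  if (spike_prob < 0 || spike_prob > 1) stop("spike_prob must be in [0, 1]")
  if (spike_scale < 0) stop("spike_scale must be >= 0")
  structure(
    list(
      label = label,
      volitional_amplitude_deg = volitional_amplitude_deg,
      assist_pressure_psi = assist_pressure_psi,
      movement_rate_hz = movement_rate_hz,
      noise_sd_deg = noise_sd_deg,
      spike_prob = spike_prob,
      spike_scale = spike_scale
    ),
    class = "class_profile"
  )
}

#' Default class profiles
#'
#' The default statistical signatures of the three severity classes, on the
#' hand (wrist) angular scale. Volitional amplitude is ordered
#' no < low < high; assistance pressure is ordered the opposite way, since
#' the device supplies the most help to the patients with the least
#' volitional movement. Movement rate rises with residual function. All
#' classes share the same sensor-noise and spike parameters: outlier spikes
#' model transient sensor faults, which do not depend on the patient.
#'
#' @return Named list of three [class_profile()] objects (`no`, `low`,
#'   `high`).
#' @export
default_profiles <- function() {
  list(
    no = class_profile("no",
      volitional_amplitude_deg = c(3, 1.5),
      assist_pressure_psi = c(8, 2),
      movement_rate_hz = 0.40
    ),
    low = class_profile("low",
      volitional_amplitude_deg = c(14, 5),
      assist_pressure_psi = c(5, 1.5),
      movement_rate_hz = 0.50
    ),
    high = class_profile("high",
      volitional_amplitude_deg = c(34, 10),
      assist_pressure_psi = c(2.5, 1.5),
      movement_rate_hz = 0.60
    )
  )
}

#' Simulation configuration for a synthetic therapy cohort
#'
#' Describes the study conditions under which a cohort of in-home therapy
#' sessions is generated: number of patients, class mixture, session length
#' and activity-count ranges, sampling rate, and the per-class profiles.
#'
#' Two cohort-level mechanisms make the class geometry realistic (and
#' nonlinear in feature space). First, severity expresses at different
#' angular scales on the two peripherals: ankle range of motion is roughly
#' half of wrist range of motion, so foot streams are generated with
#' amplitudes scaled by `foot_rom_scale`. Second, the low-ROM label pools
#' two subpopulations, mirroring the labeling protocol (which keeps in one
#' class patients who did and did not tolerate the assisted assessment): a
#' passive subtype with modest excursion under little assistance, and an
#' assisted subtype whose device-driven excursion reaches the high-ROM
#' angular range under near-maximal assistance. The low class therefore
#' occupies opposite corners of the ROM-by-pressure plane, while the no and
#' high classes occupy the other two corners — no single hyperplane
#' separates them, though mean ROM stays ordered no < low < high.
#'
#' @param n_patients Number of patients (>= 0).
#' @param class_mix Length-3 probability vector over (no, low, high); must
#'   sum to 1.
#' @param session_minutes_range Length-2 range of session durations,
#'   minutes.
#' @param activities_per_session_range Length-2 integer range of activities
#'   per session.
#' @param sessions_per_patient_range Length-2 integer range of sessions per
#'   patient.
#' @param sample_rate_hz Sampling frequency of angle/pressure channels.
#' @param foot_rom_scale Multiplier applied to volitional amplitude on the
#'   foot peripheral.
#' @param foot_prob Probability that a patient uses the foot peripheral.
#' @param profiles Named list of three [class_profile()] objects.
#' @param seed Master integer seed; every random draw in the cohort derives
#'   from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 33,
                              class_mix = c(no = 1 / 3, low = 1 / 3, high = 1 / 3),
                              session_minutes_range = c(5, 60),
                              activities_per_session_range = c(1, 10),
                              sessions_per_patient_range = c(9, 15),
                              sample_rate_hz = 30,
                              foot_rom_scale = 0.5,
                              foot_prob = 0.35,
                              profiles = default_profiles(),
                              seed = 1L) {
  if (n_patients < 0) stop("n_patients must be >= 0")
  if (length(class_mix) != 3 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must be 3 nonnegative probabilities summing to 1")
  names(class_mix) <- class_levels()
  stopifnot(
    length(session_minutes_range) == 2,
    session_minutes_range[1] > 0,
    diff(session_minutes_range) >= 0,
    length(activities_per_session_range) == 2,
    activities_per_session_range[1] >= 1,
    diff(activities_per_session_range) >= 0,
    length(sessions_per_patient_range) == 2,
    sessions_per_patient_range[1] >= 1,
    diff(sessions_per_patient_range) >= 0
  )
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  if (foot_rom_scale <= 0) stop("foot_rom_scale must be positive")
  if (foot_prob < 0 || foot_prob > 1) stop("foot_prob must be in [0, 1]")
  if (!all(class_levels() %in% names(profiles)))
    stop("profiles must contain entries named no, low, high")
  for (lv in class_levels()) {
    if (!inherits(profiles[[lv]], "class_profile"))
      stop("profiles$", lv, " is not a class_profile")
  }
  amps <- vapply(class_levels(),
                 function(lv) profiles[[lv]]$volitional_amplitude_deg[1],
                 numeric(1))
  if (is.unsorted(amps)) {
    stop("profile amplitudes must satisfy no <= low <= high")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      class_mix = class_mix,
      session_minutes_range = session_minutes_range,
      activities_per_session_range = as.integer(activities_per_session_range),
      sessions_per_patient_range = as.integer(sessions_per_patient_range),
      sample_rate_hz = sample_rate_hz,
      foot_rom_scale = foot_rom_scale,
      foot_prob = foot_prob,
      profiles = profiles[class_levels()],
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}
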