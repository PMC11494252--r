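# Activity-level feature extraction: winsorize -> smooth -> summarize one
# raw stream into the 11-feature activity row.

#' Cleaning parameters for feature extraction
#'
#' @param winsor_low_pct,winsor_high_pct Winsorization percentiles (default
#'   1 and 99): samples outside the band are replaced by the band edge.
#' @param smooth_window Centered moving-average window in samples (default
#'   5, about 0.17 s at 30 Hz).
#' @param movement_hysteresis_deg Minimum angular excursion (degrees) since
#'   the last counted extremum before a direction change counts as a
#'   movement; keeps residual noise from inflating the movement count.
#' @param force_constant Effective mass-times-lever-arm constant c in the
#'   force summary F = c * omega^2, in N s^2/rad^2. Only relative magnitudes
#'   matter downstream (features are z-scored before modeling).
#' @return An object of class `cleaning_params`.
#' @export
cleaning_params <- function(winsor_low_pct = 1, winsor_high_pct = 99,
                            smooth_window = 5, movement_hysteresis_deg = 2,
                            force_constant = 1) {
  if (!(winsor_low_pct >= 0 && winsor_low_pct < winsor_high_pct &&
        winsor_high_pct <= 100))
    stop("require 0 <= winsor_low_pct < winsor_high_pct <= 100")
  if (smooth_window < 1) stop("smooth_window must be >= 1")
  if (movement_hysteresis_deg < 0) stop("movement_hysteresis_deg must be >= 0")
  if (force_constant <= 0) stop("force_constant must be positive")
  structure(
    list(winsor_low_pct = winsor_low_pct, winsor_high_pct = winsor_high_pct,
         smooth_window = as.integer(smooth_window),
         movement_hysteresis_deg = movement_hysteresis_deg,
         force_constant = force_constant),
    class = "cleaning_params"
  )
}

#' Winsorize a numeric series
#'
#' Replaces values below the `low_pct` percentile and above the `high_pct`
#' percentile with the percentile values themselves (linear-interpolation
#' percentiles). Values inside the band are unchanged and length is
#' preserved. Because the percentiles interpolate between order statistics,
#' re-applying the operation can move boundary values only within the
#' tie-induced percentile gap (idempotent to that tolerance).
#'
#' @param x Nonempty numeric vector.
#' @param low_pct,high_pct Percentile bounds in `[0, 100]`.
#' @return Numeric vector of the same length.
#' @export
winsorize_series <- function(x, low_pct = 1, high_pct = 99) {
  if (length(x) == 0) stop("cannot winsorize an empty series")
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop("require 0 <= low_pct < high_pct <= 100")
  q <- stats::quantile(x, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  pmin(pmax(x, q[1]), q[2])
}

#' Centered moving-average smoothing
#'
#' Centered moving average with edge shrinkage: near the ends the window is
#' truncated to the available samples, so length is preserved and no edge
#' padding value is invented. `window = 1` is the identity.
#'
#' @param x Numeric vector.
#' @param window Window width in samples (>= 1); odd widths are symmetric.
#' @return Numeric vector of the same length.
#' @export
smooth_series <- function(x, window = 5) {
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  n <- length(x)
  if (n == 0 || window == 1) return(x)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Count movements (direction changes) in an angle series
#'
#' A movement is a change of direction in the (already smoothed) angle
#' signal. A direction change is counted only after the signal has moved at
#' least `hysteresis_deg` degrees away from the last counted extremum, so
#' sub-threshold oscillations do not count. Empty, constant, or monotone
#' series yield 0. The count is invariant to adding a constant offset and to
#' amplitude scaling, provided excursions stay above the hysteresis.
#'
#' @param angle Numeric vector (smoothed angle, degrees).
#' @param hysteresis_deg Nonnegative threshold in degrees.
#' @return Integer count of direction changes.
#' @export
count_movements <- function(angle, hysteresis_deg = 2) {
  if (hysteresis_deg < 0) stop("hysteresis_deg must be >= 0")
  if (length(angle) < 2) return(0L)
  count_movements_cpp(as.numeric(angle), as.numeric(hysteresis_deg))
}

#' Directional force summaries from the angle derivative
#'
#' Computes angular velocity by central differences at the sampling rate
#' (converted from deg/s to rad/s), the force magnitude `F = c * omega^2`
#' per sample, and splits the maxima by direction: `F_ext` is the maximum
#' over samples moving upward (extension, omega > 0) and `F_flex` is minus
#' the maximum over samples moving downward (flexion, omega < 0), reported
#' negative by convention.
#'
#' @param angle Numeric vector of at least 3 samples, degrees.
#' @param rate_hz Sampling rate in Hz.
#' @param force_constant Constant c in N s^2/rad^2.
#' @return Named numeric vector `c(F_flex = <= 0, F_ext = >= 0)`.
#' @export
centripetal_forces <- function(angle, rate_hz, force_constant = 1) {
  n <- length(angle)
  if (n < 3) stop("need at least 3 samples to estimate the derivative")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  omega_deg <- (angle[3:n] - angle[1:(n - 2)]) / 2 * rate_hz
  omega <- omega_deg * pi / 180
  force <- force_constant * omega^2
  f_ext <- if (any(omega > 0)) max(force[omega > 0]) else 0
  f_flex <- if (any(omega < 0)) max(force[omega < 0]) else 0
  c(F_flex = -f_flex, F_ext = f_ext)
}

#' Names of the activity-level model features
#'
#' Canonical ordering of the 11 model features of the activity data
#' dictionary: directional force maxima, movement count, ROM extremes, game
#' time, pressure summaries, maximum score, and the peripheral indicator.
#' `R_mean` is additionally computed by [summarize_activity()] and can be
#' included via `include_r_mean`.
#'
#' @param include_r_mean Also include `R_mean` (default `FALSE`).
#' @return Character vector of feature column names.
#' @export
rehab_feature_names <- function(include_r_mean = FALSE) {
  base <- c("F_flex", "F_ext", "N_mov", "R_min", "R_max", "t_game",
            "P_min", "P_max", "P_mean", "Score", "h")
  if (include_r_mean) append(base, "R_mean", after = 5) else base
}

#' Summarize a raw sensor stream into one activity feature row
#'
#' Applies the cleaning pipeline (winsorize, then smooth) to the angle and
#' pressure channels and computes the activity data-dictionary row:
#' ROM summaries `R_min`/`R_max`/`R_mean` (degrees), pressure summaries
#' `P_min`/`P_max`/`P_mean` (PSI), movement count `N_mov`, directional force
#' maxima `F_flex`/`F_ext`, total game time `t_game` (seconds), the maximum
#' cumulative `Score`, and the peripheral indicator `h` (hand = 1,
#' foot = 0), keyed by the (patient, session, game) identifiers.
#' Winsorization percentiles are computed per activity.
#'
#' @param stream A `sensor_stream` (see [simulate_activity()]).
#' @param params A [cleaning_params()].
#' @return One-row data.frame.
#' @export
summarize_activity <- function(stream, params = cleaning_params()) {
  if (!inherits(stream, "sensor_stream")) stop("stream must be a sensor_stream")
  n <- length(stream$angle_deg)
  if (n == 0) stop("cannot summarize an empty stream")

  angle <- smooth_series(
    winsorize_series(stream$angle_deg, params$winsor_low_pct,
                     params$winsor_high_pct),
    params$smooth_window
  )
  pressure <- smooth_series(
    winsorize_series(stream$pressure_psi, params$winsor_low_pct,
                     params$winsor_high_pct),
    params$smooth_window
  )

  forces <- if (n >= 3) {
    centripetal_forces(angle, stream$rate_hz, params$force_constant)
  } else {
    c(F_flex = 0, F_ext = 0)
  }
  score <- if (nrow(stream$score_events) > 0) {
    max(stream$score_events$score)
  } else {
    0
  }

  data.frame(
    patient = stream$patient,
    session = stream$session,
    game = stream$game,
    F_flex = unname(forces["F_flex"]),
    F_ext = unname(forces["F_ext"]),
    N_mov = count_movements(angle, params$movement_hysteresis_deg),
    R_min = min(angle),
    R_max = max(angle),
    R_mean = mean(angle),
    t_game = (stream$time_s[n] - stream$time_s[1]) + 1 / stream$rate_hz,
    P_min = min(pressure),
    P_max = max(pressure),
    P_mean = mean(pressure),
    Score = score,
    h = if (stream$peripheral == "hand") 1 else 0,
    stringsAsFactors = FALSE
  )
}
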