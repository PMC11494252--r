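# Independent brute-force oracles used to cross-check the signal-feature
# implementations. These deliberately use naive per-index loops and
# sort-based arithmetic, not the package's code paths.

# Linear-interpolation percentile from an explicit sort
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_winsorize <- function(x, low = 1, high = 99) {
  ql <- oracle_percentile(x, low)
  qh <- oracle_percentile(x, high)
  out <- x
  out[out < ql] <- ql
  out[out > qh] <- qh
  out
}

# Direct per-index truncated-window mean
oracle_smooth <- function(x, window) {
  n <- length(x)
  left <- (window - 1) %/% 2
  right <- window - 1 - left
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - left):min(n, i + right)])
  }, numeric(1))
}

# Brute-force extremum enumeration: collapse plateaus, list the alternating
# candidate extrema, then walk them with the hysteresis rule.
oracle_movements <- function(x, h) {
  if (length(x) < 2) return(0L)
  x <- x[c(TRUE, diff(x) != 0)]
  if (length(x) < 2) return(0L)
  s <- sign(diff(x))
  ext_idx <- unique(c(1L, which(diff(s) != 0) + 1L, length(x)))
  pts <- x[ext_idx]
  h <- max(h, 1e-12)
  count <- 0L
  dir <- 0L
  lo <- pts[1]
  hi <- pts[1]
  ext <- pts[1]
  for (v in pts[-1]) {
    if (dir == 0L) {
      if (v < lo) lo <- v
      if (v > hi) hi <- v
      if (v - lo >= h) {
        dir <- 1L
        ext <- v
      } else if (hi - v >= h) {
        dir <- -1L
        ext <- v
      }
    } else if (dir == 1L) {
      if (v > ext) {
        ext <- v
      } else if (ext - v >= h) {
        count <- count + 1L
        dir <- -1L
        ext <- v
      }
    } else {
      if (v < ext) {
        ext <- v
      } else if (v - ext >= h) {
        count <- count + 1L
        dir <- 1L
        ext <- v
      }
    }
  }
  count
}

# Naive central-difference force scan
oracle_forces <- function(angle, rate_hz, const = 1) {
  n <- length(angle)
  f_ext <- 0
  f_flex <- 0
  for (i in 2:(n - 1)) {
    omega <- (angle[i + 1] - angle[i - 1]) / 2 * rate_hz * pi / 180
    f <- const * omega^2
    if (omega > 0 && f > f_ext) f_ext <- f
    if (omega < 0 && f > f_flex) f_flex <- f
  }
  c(F_flex = -f_flex, F_ext = f_ext)
}

# Build a sensor_stream object from raw channels
make_stream <- function(angle, pressure = NULL, rate_hz = 30,
                        peripheral = "hand", score = NULL,
                        patient = 1L, session = 1L, game = 1L) {
  n <- length(angle)
  if (is.null(pressure)) pressure <- numeric(n)
  events <- if (is.null(score)) {
    data.frame(time_s = numeric(0), score = numeric(0))
  } else {
    score
  }
  structure(
    list(
      time_s = (seq_len(n) - 1) / rate_hz,
      angle_deg = angle,
      pressure_psi = pressure,
      score_events = events,
      peripheral = peripheral,
      rate_hz = rate_hz,
      patient = patient, session = session, game = game
    ),
    class = "sensor_stream"
  )
}

# A small random smooth-ish stream for property checks
random_stream <- function(n = 300, rate_hz = 30) {
  angle <- cumsum(rnorm(n, 0, 2))
  angle <- angle - mean(angle) + 5 * sin(2 * pi * 0.4 * (seq_len(n) - 1) / rate_hz)
  pressure <- abs(cumsum(rnorm(n, 0, 0.3)))
  make_stream(angle, pressure, rate_hz = rate_hz)
}

# Quick labeled feature rows with controllable class geometry, for model
# and dataset tests that do not need the full simulator
make_labeled_rows <- function(n_per_class = 40, separation = 6, seed = 1) {
  set.seed(seed)
  classes <- rep(class_levels(), each = n_per_class)
  shift <- (match(classes, class_levels()) - 1) * separation
  n <- length(classes)
  df <- data.frame(
    patient = rep(1:3, each = n_per_class),
    session = 1L, game = 1L,
    F_flex = -abs(rnorm(n, 1 + shift)), F_ext = abs(rnorm(n, 1 + shift)),
    N_mov = rpois(n, 10 + 4 * shift), R_min = -shift - abs(rnorm(n)),
    R_max = shift + abs(rnorm(n)), t_game = runif(n, 30, 300),
    P_min = rnorm(n, 0, 0.1), P_max = 8 - shift / 3 + rnorm(n, 0, 0.5),
    P_mean = 4 - shift / 6 + rnorm(n, 0, 0.3),
    Score = rpois(n, 50), h = rbinom(n, 1, 0.5)
  )
  df$Class <- factor(classes, levels = class_levels())
  df
}
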