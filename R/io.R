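# Plain-text persistence: one CSV per activity stream, a cohort manifest,
# and the assessment table.

#' Write a cohort to a directory of delimited text files
#'
#' Each activity stream becomes one CSV with columns `time_s`, `angle_deg`,
#' `pressure_psi`, `score` (cumulative score carried forward between score
#' events, starting at 0). A `manifest.csv` records the (patient, session,
#' game) key, peripheral, rate and file name per stream, and
#' `assessments.csv` holds the clinician-style assessment table.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(seq_along(cohort$streams), function(i) {
    s <- cohort$streams[[i]]
    file <- sprintf("stream_p%s_s%s_g%s_%04d.csv", s$patient, s$session,
                    s$game, i)
    score <- numeric(length(s$time_s))
    if (nrow(s$score_events) > 0) {
      idx <- findInterval(s$time_s, s$score_events$time_s)
      score <- c(0, s$score_events$score)[idx + 1]
    }
    utils::write.csv(
      data.frame(time_s = s$time_s, angle_deg = s$angle_deg,
                 pressure_psi = s$pressure_psi, score = score),
      file.path(dir, file), row.names = FALSE
    )
    data.frame(patient = s$patient, session = s$session, game = s$game,
               peripheral = s$peripheral, rate_hz = s$rate_hz, file = file,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, manifest)
  if (is.null(manifest)) {
    manifest <- data.frame(patient = integer(0), session = integer(0),
                           game = integer(0), peripheral = character(0),
                           rate_hz = numeric(0), file = character(0))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$assessments, file.path(dir, "assessments.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read one activity stream written by [write_cohort()]
#'
#' Score events are reconstructed from the changes in the carried-forward
#' cumulative score column.
#'
#' @param file Path to a stream CSV.
#' @param patient,session,game,peripheral,rate_hz Stream metadata (from the
#'   manifest).
#' @return A `sensor_stream`.
#' @export
read_sensor_stream <- function(file, patient = NA_integer_,
                               session = NA_integer_, game = NA_integer_,
                               peripheral = "hand", rate_hz = 30) {
  df <- utils::read.csv(file)
  change <- which(c(df$score[1] != 0, diff(df$score) != 0))
  structure(
    list(time_s = df$time_s, angle_deg = df$angle_deg,
         pressure_psi = df$pressure_psi,
         score_events = data.frame(time_s = df$time_s[change],
                                   score = df$score[change]),
         peripheral = peripheral, rate_hz = rate_hz,
         patient = patient, session = session, game = game),
    class = "sensor_stream"
  )
}
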