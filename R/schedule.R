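# Heating schedules: piecewise-linear temperature as a function of
# simulation time. Temperatures are carried in kelvin internally
# (degC + 273.15, so a -273 degC start maps to 0.15 K exactly).

#' Convert between Celsius and kelvin
#' @param x temperature values.
#' @return Converted values.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' Piecewise-linear temperature schedule
#'
#' @param segments data.frame with columns `t_start`, `t_end` (ns) and
#'   `T_start`, `T_end` (K); segments must be contiguous, time-increasing
#'   and start at t = 0.
#' @param hold_after_end hold the final temperature after the last
#'   segment (otherwise times beyond the schedule are an error).
#' @return Object of class `temperature_schedule`.
#' @export
temperature_schedule <- function(segments, hold_after_end = TRUE) {
  need <- c("t_start", "t_end", "T_start", "T_end")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)))
  if (segments$t_start[1] != 0) stop("first segment must start at t = 0")
  if (any(segments$t_end <= segments$t_start)) stop("segments must be time-increasing")
  if (nrow(segments) > 1L &&
      any(abs(segments$t_start[-1] - segments$t_end[-nrow(segments)]) > 1e-9)) {
    stop("segments must be contiguous")
  }
  structure(list(segments = segments, hold_after_end = hold_after_end),
            class = "temperature_schedule")
}

#' The two-segment heating schedule used for domain melting runs
#'
#' Rapid heating from -273 degC to -73 degC over 4 ns, then a slow ramp
#' from -73 degC to 127 degC over 200 ns, holding 127 degC afterwards
#' (runs continue to 1 us).
#'
#' @return A [temperature_schedule()].
#' @export
fcmur_heating_schedule <- function() {
  temperature_schedule(data.frame(
    t_start = c(0, 4), t_end = c(4, 204),
    T_start = celsius_to_kelvin(c(-273, -73)),
    T_end   = celsius_to_kelvin(c(-73, 127))
  ), hold_after_end = TRUE)
}

#' Temperature at given times under a schedule
#'
#' Linear interpolation within the active segment; after the last segment
#' the final temperature is held if `hold_after_end`, otherwise an error.
#'
#' @param schedule a [temperature_schedule()].
#' @param t time(s) in ns (>= 0).
#' @return Temperature(s) in K.
#' @export
frame_temperature <- function(schedule, t) {
  if (any(t < 0)) stop("t must be >= 0")
  seg <- schedule$segments
  t_max <- seg$t_end[nrow(seg)]
  if (any(t > t_max + 1e-9) && !schedule$hold_after_end) {
    stop("time beyond schedule end and hold_after_end is FALSE")
  }
  out <- numeric(length(t))
  for (k in seq_along(t)) {
    tk <- min(t[k], t_max)
    i <- max(which(seg$t_start <= tk + 1e-12))
    f <- (tk - seg$t_start[i]) / (seg$t_end[i] - seg$t_start[i])
    f <- min(max(f, 0), 1)
    out[k] <- seg$T_start[i] + f * (seg$T_end[i] - seg$T_start[i])
  }
  out
}

#' Read a temperature schedule from YAML
#'
#' Layout: `segments:` list of `{t_start, t_end, T_start, T_end}` (K),
#' plus optional `hold_after_end`.
#'
#' @param path YAML file.
#' @return A [temperature_schedule()].
#' @export
read_schedule_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(raw$segments, as.data.frame))
  temperature_schedule(seg, hold_after_end = isTRUE(raw$hold_after_end) ||
                         is.null(raw$hold_after_end))
}
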