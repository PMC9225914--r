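# Moxa-stick source temperature: harmonic burning law with periodic
# ash-cleaning windows.

#' Define a moxa-stick burning schedule
#'
#' The burning-end temperature follows a simple harmonic,
#' \deqn{T_a(\tau) = (T_{max} - A) + A \cos(2\pi \tau / P),}
#' with peak `max_temperature`, amplitude `A = amplitude` (default 200
#' degrees C) and period `P = period` (default 500 s). The harmonic is a
#' surrogate for ash gradually covering the glowing end and throttling its
#' radiation. Once per `clean_interval` (default 60 s) the ash is cleaned:
#' for `clean_duration` seconds the stick is withdrawn and the source
#' temperature is held at `clean_temperature` (50 degrees C, the warmed air
#' left behind).
#'
#' With `reset_on_clean = TRUE` (the default) the harmonic phase restarts
#' from its peak after every cleaning window: ash accumulation begins anew
#' on the freshly cleaned end, so with the default 60 s cleaning interval
#' only the first 60 s of the 500 s cosine is ever traversed and the source
#' stays within roughly 546-600 degrees C between cleanings. With
#' `reset_on_clean = FALSE` the cosine is evaluated on absolute time,
#' letting the source sweep its full peak-to-trough range regardless of
#' cleaning.
#'
#' @param max_temperature peak burning temperature, degrees C.
#' @param amplitude harmonic amplitude, degrees C.
#' @param period harmonic period, s.
#' @param clean_interval time between ash cleanings, s.
#' @param clean_duration length of each cleaning window, s (0 disables
#'   cleaning).
#' @param clean_temperature source temperature during cleaning, degrees C.
#' @param reset_on_clean logical; restart the harmonic from its peak after
#'   each cleaning window.
#' @return an object of class `burn_schedule`.
#' @export
burn_schedule <- function(max_temperature = 600, amplitude = 200,
                          period = 500, clean_interval = 60,
                          clean_duration = 5, clean_temperature = 50,
                          reset_on_clean = TRUE) {
  check_num(max_temperature, "schedule$max_temperature")
  check_num(amplitude, "schedule$amplitude", nonneg = TRUE)
  if (max_temperature <= amplitude)
    stop_field("schedule$max_temperature", "must exceed the amplitude")
  check_num(period, "schedule$period", positive = TRUE)
  check_num(clean_duration, "schedule$clean_duration", nonneg = TRUE)
  check_num(clean_interval, "schedule$clean_interval", positive = TRUE)
  if (clean_interval <= clean_duration)
    stop_field("schedule$clean_interval", "must exceed clean_duration")
  check_num(clean_temperature, "schedule$clean_temperature")
  if (clean_duration > 0 &&
      clean_temperature >= max_temperature - amplitude)
    stop_field("schedule$clean_temperature",
               "must lie below the harmonic trough")
  if (!is.logical(reset_on_clean) || length(reset_on_clean) != 1L ||
      is.na(reset_on_clean))
    stop_field("schedule$reset_on_clean", "must be TRUE or FALSE")
  structure(list(max_temperature = max_temperature, amplitude = amplitude,
                 period = period, clean_interval = clean_interval,
                 clean_duration = clean_duration,
                 clean_temperature = clean_temperature,
                 reset_on_clean = reset_on_clean),
            class = "burn_schedule")
}

#' Rescale the standard schedule to another peak temperature
#'
#' Shifts the harmonic offset so the cosine peak equals `max_temperature`,
#' leaving amplitude and period unchanged; this is how the 600/650/700 (and
#' 600/625/650) degree-C levels of the parameter studies are produced.
#'
#' @param max_temperature desired peak burning temperature, degrees C.
#' @param base schedule to rescale (default the standard one).
#' @return a [burn_schedule()].
#' @export
schedule_for_max <- function(max_temperature, base = burn_schedule()) {
  stopifnot(inherits(base, "burn_schedule"))
  check_num(max_temperature, "max_temperature")
  if (max_temperature <= base$amplitude)
    stop_field("max_temperature", "must exceed the harmonic amplitude")
  base$max_temperature <- max_temperature
  base
}

# Cleaning windows start at t = k * clean_interval, k = 1, 2, ... (the stick
# is lit, not cleaned, at t = 0) and last clean_duration seconds.
in_cleaning_window <- function(t, schedule) {
  if (schedule$clean_duration <= 0) return(rep(FALSE, length(t)))
  (t >= schedule$clean_interval) &
    (t %% schedule$clean_interval) < schedule$clean_duration
}

#' Source temperature at time t
#'
#' Evaluates the burning-end temperature: `clean_temperature` inside a
#' cleaning window, otherwise the harmonic burning law (see
#' [burn_schedule()] for the phase convention).
#'
#' @param t time(s) since the stick was lit, s (vectorized).
#' @param schedule a [burn_schedule()].
#' @return source temperature(s), degrees C.
#' @export
source_temperature <- function(t, schedule = burn_schedule()) {
  stopifnot(inherits(schedule, "burn_schedule"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop_field("t", "must be non-negative")
  offset <- schedule$max_temperature - schedule$amplitude
  cleaning <- in_cleaning_window(t, schedule)
  if (schedule$reset_on_clean && schedule$clean_duration > 0) {
    # phase measured from the end of the most recent cleaning window
    k <- pmax(0, floor(t / schedule$clean_interval))
    origin <- ifelse(k == 0, 0,
                     k * schedule$clean_interval + schedule$clean_duration)
    # inside a window the origin is irrelevant (overridden below); just
    # avoid a negative phase there
    tau <- pmax(0, t - origin)
  } else {
    tau <- t
  }
  out <- offset + schedule$amplitude * cos(2 * pi * tau / schedule$period)
  out[cleaning] <- schedule$clean_temperature
  out
}

#' Sample the burning schedule on a regular grid
#'
#' @param schedule a [burn_schedule()].
#' @param duration total time, s.
#' @param dt sample spacing, s.
#' @return a data.frame with columns `t_s` and `temp_C` on the closed grid
#'   `seq(0, duration, by = dt)`.
#' @export
temperature_series <- function(schedule = burn_schedule(), duration = 900,
                               dt = 1) {
  check_num(duration, "duration", positive = TRUE)
  check_num(dt, "dt", positive = TRUE)
  t <- seq(0, duration, by = dt)
  data.frame(t_s = t, temp_C = source_temperature(t, schedule))
}

#' @export
print.burn_schedule <- function(x, ...) {
  cat(sprintf(paste0("<burn_schedule> peak %g C, amplitude %g C, period %g s;",
                     " ash-clean %g s @ every %g s (%g C)%s\n"),
              x$max_temperature, x$amplitude, x$period, x$clean_duration,
              x$clean_interval, x$clean_temperature,
              if (x$reset_on_clean) ", phase reset on cleaning" else ""))
  invisible(x)
}
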