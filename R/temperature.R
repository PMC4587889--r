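#' Temperature series constructor
#'
#' Paired pile and ambient temperature observations over composting time.
#' Times are days since pile construction and may be sub-daily.
#'
#' @param times Days since pile construction; non-negative, strictly
#'   increasing.
#' @param pile_temp,ambient_temp Temperatures in degrees C, within
#'   \[-20, 90\].
#' @param turning_days Optional vector of days on which the pile was turned.
#' @return An object of class `temperature_series` (a tibble with attribute
#'   `turning_days`).
#' @export
temperature_series <- function(times, pile_temp, ambient_temp,
                               turning_days = NULL) {
  stopifnot(length(times) == length(pile_temp),
            length(times) == length(ambient_temp))
  if (length(times) == 0) stop("temperature_series: empty series")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("temperature_series: times must be non-negative and strictly increasing")
  rng_ok <- function(x) all(is.na(x) | (x >= -20 & x <= 90))
  if (!rng_ok(pile_temp) || !rng_ok(ambient_temp))
    stop("temperature_series: temperatures must lie in [-20, 90] degC")
  out <- tibble::tibble(time = times, pile_temp = pile_temp,
                        ambient_temp = ambient_temp)
  attr(out, "turning_days") <- turning_days
  class(out) <- c("temperature_series", class(out))
  out
}

#' Daily means of a temperature series
#'
#' Averages all observations falling in each whole-day bin \[d, d+1); days
#' without observations are absent from the output. An already-daily series
#' is returned unchanged (idempotent).
#'
#' @param series A `temperature_series` (or data frame with columns `time`,
#'   `pile_temp`, `ambient_temp`).
#' @return A `temperature_series` with one row per observed day and integer
#'   `time`.
#' @export
daily_means <- function(series) {
  if (nrow(series) == 0) stop("daily_means: empty series")
  day <- floor(series$time)
  pile <- tapply(series$pile_temp, day, mean)
  amb <- tapply(series$ambient_temp, day, mean)
  temperature_series(as.numeric(names(pile)), as.numeric(pile),
                     as.numeric(amb),
                     turning_days = attr(series, "turning_days"))
}

#' Detect the end of the bio-oxidative phase
#'
#' The bio-oxidative phase is considered finished when the pile temperature
#' stays close to ambient and re-heating does not occur: the first day `d`
#' such that |pile - ambient| < `delta` for all of the `persistence`
#' consecutive days starting at `d`.
#'
#' @param series A daily `temperature_series` (see [daily_means()]).
#' @param delta Closeness threshold, degrees C (> 0).
#' @param persistence Number of consecutive days required (>= 1).
#' @return The day index (value of `time`), or the day after the last
#'   observation (with a warning) if the condition is never met.
#' @export
detect_bio_oxidative_end <- function(series, delta = 2, persistence = 7) {
  stopifnot(delta > 0, persistence >= 1)
  close_enough <- abs(series$pile_temp - series$ambient_temp) < delta
  n <- length(close_enough)
  run <- min(persistence, n)
  for (i in seq_len(n - run + 1)) {
    if (all(close_enough[i:(i + run - 1)])) return(series$time[i])
  }
  warning("detect_bio_oxidative_end: pile never stayed within ", delta,
          " degC of ambient for ", persistence,
          " days; returning end of series")
  series$time[n] + 1
}

#' Exothermic index (EXI)
#'
#' Cumulated degrees C released above ambient during the bio-oxidative
#' phase: the sum over days 0 .. `end_day` - 1 of the daily pile-minus-
#' ambient difference. With `clip_negative = TRUE` negative daily terms are
#' set to zero before summation.
#'
#' @param series A daily `temperature_series`.
#' @param end_day Exclusive upper day bound (e.g. from
#'   [detect_bio_oxidative_end()]); must not exceed the day after the last
#'   observation.
#' @param clip_negative Clip negative daily differences at zero?
#' @return EXI in cumulated degrees C.
#' @export
exothermic_index <- function(series, end_day, clip_negative = FALSE) {
  if (end_day > max(series$time) + 1)
    stop("exothermic_index: end_day beyond the series")
  if (end_day <= 0) return(0)
  keep <- series$time < end_day
  diffs <- series$pile_temp[keep] - series$ambient_temp[keep]
  if (anyNA(diffs)) {
    warning("exothermic_index: days with missing readings skipped")
    diffs <- diffs[!is.na(diffs)]
  }
  if (clip_negative) diffs <- pmax(diffs, 0)
  sum(diffs)
}

#' Read a temperature series from CSV
#'
#' @param path CSV with columns `day` (or `day_or_datetime`),
#'   `pile_temp_c`, `ambient_temp_c`.
#' @return A `temperature_series`.
#' @export
read_temperature_series <- function(path) {
  df <- utils::read.csv(path)
  daycol <- intersect(c("day", "day_or_datetime"), names(df))[1]
  if (is.na(daycol) || !all(c("pile_temp_c", "ambient_temp_c") %in% names(df)))
    stop("read_temperature_series: need columns day (or day_or_datetime), ",
         "pile_temp_c, ambient_temp_c")
  temperature_series(as.numeric(df[[daycol]]), df$pile_temp_c,
                     df$ambient_temp_c)
}
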