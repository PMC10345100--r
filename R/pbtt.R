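#' Photo-beta thermal time parameters
#'
#' Daily photo-beta thermal time is the product of a beta-shaped
#' temperature response and a bounded photoperiod multiplier; cumulated
#' over a trial window it gives a single environmental covariate that
#' orders environments by how favourable their temperature and day length
#' were for development.
#'
#' The temperature response is the beta function commonly used in crop
#' phenology (Yin-style): zero at or below `t_base` and at or above
#' `t_ceil`, with its maximum of 1 at `t_opt`:
#' \deqn{f_\beta(T) = \left[\left(\frac{T - T_b}{T_o - T_b}\right)
#'   \left(\frac{T_c - T}{T_c - T_o}\right)^{(T_c - T_o)/(T_o - T_b)}
#'   \right]^{c}}
#' The photoperiod multiplier is a linear clipped factor in `[0, 1]`:
#' 1 at or above the critical photoperiod `p_crit`, declining with slope
#' `p_sens` per hour of day length below it, so environments with long
#' days and temperatures near the optimum accumulate the most
#' photo-thermal time (the axis on which the stability lines read
#' "rising = better where days were long and temperatures high").
#' Defaults follow a standard potato parameterization of the beta
#' function, `t_base = 5.5`, `t_opt = 23.4`, `t_ceil = 34.6` (degrees C),
#' curvature 1, with `p_crit = 14` h and `p_sens = 0.15` per hour.
#'
#' @param t_base,t_opt,t_ceil cardinal temperatures, degrees C; must be
#'   strictly increasing.
#' @param curvature exponent applied to the beta response (>= 0, finite).
#' @param p_crit critical photoperiod, hours.
#' @param p_sens photoperiod sensitivity, fractional reduction per hour of
#'   day length below `p_crit`.
#' @return a `fp_pbtt_params` list.
#' @export
pbtt_params <- function(t_base = 5.5, t_opt = 23.4, t_ceil = 34.6,
                        curvature = 1, p_crit = 14, p_sens = 0.15) {
  vals <- c(t_base, t_opt, t_ceil, curvature, p_crit, p_sens)
  if (any(!is.finite(vals))) stop_fp("all PBTT parameters must be finite")
  if (!(t_base < t_opt && t_opt < t_ceil))
    stop_fp("cardinal temperatures must satisfy t_base < t_opt < t_ceil")
  structure(list(t_base = t_base, t_opt = t_opt, t_ceil = t_ceil,
                 curvature = curvature, p_crit = p_crit, p_sens = p_sens),
            class = "fp_pbtt_params")
}

#' Beta temperature response
#' @param temp daily mean temperature(s), degrees C.
#' @param params a [pbtt_params()].
#' @return response in `[0, 1]`; 0 at/below `t_base` and at/above `t_ceil`.
#' @export
beta_response <- function(temp, params = pbtt_params()) {
  with(params, {
    out <- numeric(length(temp))
    inside <- temp > t_base & temp < t_ceil
    tt <- temp[inside]
    ex <- (t_ceil - t_opt) / (t_opt - t_base)
    out[inside] <- (((tt - t_base) / (t_opt - t_base)) *
                      ((t_ceil - tt) / (t_ceil - t_opt))^ex)^curvature
    out
  })
}

#' Photoperiod multiplier
#' @param photoperiod day length(s), hours in `[0, 24]`.
#' @param params a [pbtt_params()].
#' @return multiplier in `[0, 1]`.
#' @export
photoperiod_factor <- function(photoperiod, params = pbtt_params()) {
  with(params, pmin(1, pmax(0, 1 - p_sens * (p_crit - photoperiod))))
}

#' Cumulative photo-beta thermal time over a study window
#'
#' Sums, for every calendar day in `[start_date, end_date]`, the product
#' of the photoperiod multiplier and the beta temperature response at that
#' day's station readings. Both series must cover the window: a gap is an
#' error listing the missing dates unless `on_missing = "skip"`, which
#' skips gap days with a warning.
#'
#' @param weather weather-observation data frame ([weather_observations()]).
#' @param station_id the station serving this study's location.
#' @param start_date,end_date ISO dates delimiting the window (inclusive).
#' @param params a [pbtt_params()].
#' @param on_missing `"error"` (default) or `"skip"`.
#' @return a single non-negative number; 0 for an empty window, and
#'   monotone non-decreasing as the window extends.
#' @export
cumulative_pbtt <- function(weather, station_id, start_date, end_date,
                            params = pbtt_params(),
                            on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  if (is.na(start_date) || is.na(end_date)) stop_fp("window dates are required")
  s <- as.Date(start_date); e <- as.Date(end_date)
  if (e < s) return(0)
  days <- format(seq(s, e, by = "day"), "%Y-%m-%d")
  w <- weather[weather$station_id == station_id, , drop = FALSE]
  series <- function(var) {
    m <- w[w$variable == var, , drop = FALSE]
    stats::setNames(m$value, m$date)[days]
  }
  temp <- series("daily_mean_temperature_C")
  photo <- series("photoperiod_hours")
  gaps <- days[is.na(temp) | is.na(photo)]
  if (length(gaps) > 0L) {
    if (on_missing == "error")
      stop_fp("station '%s' has no complete weather for date(s): %s", station_id,
              paste(utils::head(gaps, 10), collapse = ", "))
    warning(sprintf("skipping %d day(s) with missing weather at station '%s'",
                    length(gaps), station_id), call. = FALSE)
    keep <- !(days %in% gaps)
    temp <- temp[keep]; photo <- photo[keep]
  }
  sum(photoperiod_factor(photo, params) * beta_response(temp, params))
}

#' PBTT for every study of an investigation
#'
#' Windows each study from its start date to its end date (an open-ended
#' study uses the last date its station reports) at its matched station.
#' @param inv investigation (for study windows).
#' @param matches station matches ([match_weather_stations()] output).
#' @param weather weather observations.
#' @param params a [pbtt_params()].
#' @param on_missing forwarded to [cumulative_pbtt()].
#' @return data frame `study_id`, `pbtt`.
#' @export
study_pbtt <- function(inv, matches, weather, params = pbtt_params(),
                       on_missing = "error") {
  rows <- lapply(inv$studies, function(s) {
    st <- matches$station_id[matches$study_id == s$id]
    if (length(st) != 1L) stop_fp("no station match for study '%s'", s$id)
    end <- s$end_date
    if (is.na(end)) {
      have <- weather$date[weather$station_id == st]
      if (length(have) == 0L) stop_fp("station '%s' has no observations", st)
      end <- max(have)
    }
    data.frame(study_id = s$id,
               pbtt = cumulative_pbtt(weather, st, s$start_date, end, params,
                                      on_missing = on_missing),
               stringsAsFactors = FALSE)
  })
  out <- rbind_all(rows, empty_df(study_id = "character", pbtt = "numeric"))
  out[c_order(out$study_id), , drop = FALSE]
}
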