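synth_weather <- function(station = "w1", start = "2000-06-01", n = 10,
                          temps = NULL, photos = NULL) {
  days <- format(seq(as.Date(start), by = "day", length.out = n), "%Y-%m-%d")
  if (is.null(temps)) temps <- seq(8, 26, length.out = n)
  if (is.null(photos)) photos <- seq(12, 17, length.out = n)
  rbind(data.frame(station_id = station, date = days,
                   variable = "daily_mean_temperature_C", value = temps,
                   stringsAsFactors = FALSE),
        data.frame(station_id = station, date = days,
                   variable = "photoperiod_hours", value = photos,
                   stringsAsFactors = FALSE))
}

test_that("parameter validation enforces the cardinal-temperature ordering", {
  expect_error(pbtt_params(t_base = 25, t_opt = 20), "t_base < t_opt")
  expect_error(pbtt_params(p_sens = Inf), "finite")
  p <- pbtt_params()
  expect_lt(p$t_base, p$t_opt)
  expect_lt(p$t_opt, p$t_ceil)
})

test_that("the beta response is zero at the cardinals' edges and maximal at optimum", {
  p <- pbtt_params()
  expect_equal(beta_response(c(p$t_base, p$t_ceil, p$t_base - 5, p$t_ceil + 5), p),
               c(0, 0, 0, 0))
  expect_equal(beta_response(p$t_opt, p), 1)
  grid <- seq(p$t_base, p$t_ceil, by = 0.1)
  expect_true(all(beta_response(grid, p) <= 1 + 1e-12))
  expect_true(all(beta_response(grid, p) >= 0))
})

test_that("the photoperiod multiplier is bounded and saturates at the critical value", {
  p <- pbtt_params()
  f <- photoperiod_factor(c(0, 8, p$p_crit, 20, 24), p)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(photoperiod_factor(p$p_crit, p), 1)
  expect_equal(photoperiod_factor(24, p), 1)
  expect_true(photoperiod_factor(8, p) < photoperiod_factor(12, p))
})

test_that("an empty window accumulates zero", {
  w <- synth_weather()
  expect_equal(cumulative_pbtt(w, "w1", "2000-06-05", "2000-06-04"), 0)
})

test_that("days at or below base temperature contribute nothing", {
  p <- pbtt_params()
  w <- synth_weather(temps = rep(p$t_base, 10))
  expect_equal(cumulative_pbtt(w, "w1", "2000-06-01", "2000-06-10", p), 0)
  w2 <- synth_weather(temps = rep(p$t_base - 3, 10))
  expect_equal(cumulative_pbtt(w2, "w1", "2000-06-01", "2000-06-10", p), 0)
})

test_that("cumulative PBTT equals an independently coded per-day loop", {
  set.seed(81)
  p <- pbtt_params()
  temps <- runif(10, 2, 38); photos <- runif(10, 8, 20)
  w <- synth_weather(temps = temps, photos = photos)
  oracle <- 0
  for (i in 1:10) {
    fb <- 0
    if (temps[i] > p$t_base && temps[i] < p$t_ceil) {
      ex <- (p$t_ceil - p$t_opt) / (p$t_opt - p$t_base)
      fb <- (((temps[i] - p$t_base) / (p$t_opt - p$t_base)) *
               ((p$t_ceil - temps[i]) / (p$t_ceil - p$t_opt))^ex)^p$curvature
    }
    fp <- min(1, max(0, 1 - p$p_sens * (p$p_crit - photos[i])))
    oracle <- oracle + fp * fb
  }
  expect_equal(cumulative_pbtt(w, "w1", "2000-06-01", "2000-06-10", p), oracle,
               tolerance = 1e-12)
})

test_that("PBTT is additive over adjacent windows and monotone in window length", {
  w <- synth_weather(n = 20)
  whole <- cumulative_pbtt(w, "w1", "2000-06-01", "2000-06-20")
  a <- cumulative_pbtt(w, "w1", "2000-06-01", "2000-06-08")
  b <- cumulative_pbtt(w, "w1", "2000-06-09", "2000-06-20")
  expect_equal(a + b, whole, tolerance = 1e-9)
  prev <- 0
  for (k in 1:20) {
    cur <- cumulative_pbtt(w, "w1", "2000-06-01",
                           format(as.Date("2000-05-31") + k, "%Y-%m-%d"))
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
  expect_gte(whole, 0)
})

test_that("weather gaps fail listing the missing dates, or skip with a warning", {
  w <- synth_weather(n = 10)
  w <- w[w$date != "2000-06-04", ]
  expect_error(cumulative_pbtt(w, "w1", "2000-06-01", "2000-06-10"), "2000-06-04")
  expect_warning(
    v <- cumulative_pbtt(w, "w1", "2000-06-01", "2000-06-10", on_missing = "skip"),
    "skipping 1 day")
  expect_gte(v, 0)
})

test_that("per-study PBTT windows open-ended studies to the station's last day", {
  fx <- generate_fixture(tiny_spec(82))
  inv <- fx$investigation
  closed <- study_pbtt(inv, fx$truth$station_matches, fx$weather)
  expect_equal(closed$pbtt, fx$truth$pbtt$pbtt, tolerance = 1e-9)
  inv$studies[[1]]$end_date <- NA_character_
  open <- study_pbtt(inv, fx$truth$station_matches, fx$weather)
  expect_equal(open$pbtt, closed$pbtt, tolerance = 1e-9)  # station covers exactly the window
})
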