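# Forward simulation of a tidal creek oxygen series with known metabolism,
# inverted by nem_series() in tests.

#' Configuration for the tidal-creek oxygen simulator
#'
#' @param days Simulated duration, days (default 6).
#' @param dt_min Output sampling step, minutes (default 10).
#' @param tidal_amplitude Tidal amplitude, m (default 0.75).
#' @param tidal_period_h Tidal period, hours (default 12.4, semidiurnal).
#' @param depth_offset Mean water depth, m (default 1).
#' @param spring_neap Fractional spring-neap modulation of the amplitude
#'   over a 14.77-day cycle (default 0.15); makes only the biggest tides
#'   overtop the platform flooding elevation.
#' @param p0 Peak gross production, mmol O2 m^-1 min^-1 (default 1.2);
#'   production follows a half-sine between 06:00 and 18:00.
#' @param respiration Constant respiration, mmol O2 m^-1 min^-1
#'   (default 0.5).
#' @param k_scale Scalar on the gas transfer velocity (default 1; 0 turns
#'   gas exchange off).
#' @param noise_sd Gaussian observation noise on the emitted O2 saturation,
#'   percent saturation (default 0).
#' @param temperature,salinity Constant water properties.
#' @param wind Constant wind speed, m s^-1 (default 3).
#' @param start Series start time (default 2012-08-01 00:00 UTC).
#' @param seed Integer seed (mandatory).
#' @return A `creek_sim_config` list.
#' @export
creek_sim_config <- function(days = 6, dt_min = 10, tidal_amplitude = 0.75,
                             tidal_period_h = 12.4, depth_offset = 1,
                             spring_neap = 0.15, p0 = 1.2, respiration = 0.5,
                             k_scale = 1, noise_sd = 0, temperature = 25,
                             salinity = 30, wind = 3,
                             start = as.POSIXct("2012-08-01 00:00:00",
                                                tz = "UTC"),
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (p0 < 0 || respiration < 0)
    stop("p0 and respiration must be >= 0", call. = FALSE)
  if (depth_offset - tidal_amplitude * (1 + spring_neap) <= 0)
    stop("configuration produces non-positive depth at low tide",
         call. = FALSE)
  structure(as.list(environment()), class = "creek_sim_config")
}

# half-sine daylight curve, 06:00-18:00
production_curve <- function(minutes_of_day, p0) {
  h <- minutes_of_day / 60
  ifelse(h >= 6 & h <= 18, p0 * sin(pi * (h - 6) / 12), 0)
}

#' Forward-simulate a tidal creek oxygen series with known metabolism
#'
#' Depth follows a spring-neap-modulated sinusoidal tide; gross production
#' is a daylight half-sine and respiration constant, so the true NEM is
#' `P(t) - R`. Oxygen is integrated forward (Euler, 1-min internal step)
#' under `V dC/dt = NEM + F_gas`, i.e. a well-mixed control volume whose
#' advective exchange carries the in-creek concentration (the same boundary
#' convention [nem_series()] inverts); current speed is the advective
#' volume flux divided by the wetted cross-section. Gaussian noise is added
#' to the emitted saturation series only — the truth is noise-free.
#'
#' @param config A [creek_sim_config()].
#' @param geometry A [creek_geometry()] (default geometry).
#' @param model,coef Gas-exchange parameterization passed to
#'   [gas_exchange_flux()].
#' @return List with `series` (a `creek_series` sampled at
#'   `config$dt_min`) and `truth` (data frame: `timestamp`, `minutes`,
#'   `production`, `respiration`, `nem`, `conc`).
#' @export
simulate_tidal_creek <- function(config, geometry = creek_geometry(),
                                 model = "wind_current",
                                 coef = list(wind = 0.266, current = 16.4)) {
  stopifnot(inherits(config, "creek_sim_config"))
  set.seed(config$seed)
  dt_sim <- 1 # minutes
  minutes <- seq(0, config$days * 24 * 60, by = dt_sim)
  # spring-neap phase starts at neap so the simulated week spans the rise
  # toward spring tides and only the biggest tides overtop the platform
  amp <- config$tidal_amplitude *
    (1 + config$spring_neap *
       sin(2 * pi * minutes / (14.77 * 24 * 60) - pi / 2))
  depth <- config$depth_offset + amp * sin(2 * pi * minutes /
                                             (config$tidal_period_h * 60))
  vol <- wetted_volume(geometry, depth)
  dvdt <- finite_diff(vol, dt_sim)
  # cross-sectionally averaged speed: Q [m^3 m^-1 s^-1] / area [m^2 m^-1];
  # the wetted area per unit creek length equals the per-length volume
  current <- (abs(dvdt) / 60) / pmax(vol, 1e-6)
  prod <- production_curve(minutes %% (24 * 60), config$p0)
  nem_true <- prod - config$respiration
  csat <- o2_saturation_concentration(config$temperature, config$salinity)
  n <- length(minutes)
  conc <- numeric(n)
  conc[1L] <- csat
  for (i in seq_len(n - 1L)) {
    f_gas <- gas_exchange_flux(config$wind, current[i], depth[i], conc[i],
                               config$temperature, config$salinity, geometry,
                               model = model, coef = coef,
                               k_scale = config$k_scale)
    conc[i + 1L] <- conc[i] + dt_sim * (nem_true[i] + f_gas) / vol[i]
  }
  keep <- seq(1L, n, by = as.integer(round(config$dt_min / dt_sim)))
  ts <- config$start + minutes[keep] * 60
  sat <- 100 * conc[keep] / csat
  if (config$noise_sd > 0)
    sat <- sat + stats::rnorm(length(keep), 0, config$noise_sd)
  series <- as_creek_series(data.frame(
    timestamp = ts,
    depth_m = depth[keep],
    temperature_c = config$temperature,
    salinity = config$salinity,
    o2_saturation_pct = sat,
    wind_m_s = config$wind,
    current_m_s = current[keep]))
  truth <- data.frame(timestamp = ts, minutes = minutes[keep],
                      production = prod[keep],
                      respiration = config$respiration,
                      nem = nem_true[keep], conc = conc[keep])
  list(series = series, truth = truth)
}
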