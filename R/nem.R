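# Non-steady-state dissolved-oxygen mass balance for a tidal creek control
# volume. All per-length quantities are per metre of creek; oxygen in
# mmol m^-3, fluxes in mmol O2 m^-1 min^-1, positive NEM = net autotrophy.

#' Seawater density at atmospheric pressure
#'
#' One-atmosphere International Equation of State of Seawater (EOS-80).
#' Check value: `seawater_density(5, 35) = 1027.67547` kg m^-3.
#'
#' @param temperature Water temperature, degrees C.
#' @param salinity Practical salinity.
#' @return Density, kg m^-3.
#' @export
seawater_density <- function(temperature, salinity) {
  t <- temperature; s <- salinity
  rw <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 + 1.001685e-4 * t^3 -
    1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  rw + a * s + b * s^1.5 + 4.8314e-4 * s^2
}

# Garcia & Gordon (1992) combined-fit coefficients on the Benson & Krause
# data; yields umol O2 per kg at equilibrium with water-saturated air.
.o2_A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
.o2_B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
.o2_C0 <- -2.75915e-7

#' Oxygen solubility (air-saturation concentration)
#'
#' Equilibrium dissolved-oxygen concentration from the combined-fit
#' solubility function in scaled temperature, converted from umol kg^-1 to
#' mmol m^-3 with the EOS-80 surface density. Check value: 274.610
#' umol kg^-1 at `temperature = 10, salinity = 35`.
#'
#' @param temperature Water temperature, degrees C, in `[-2, 40]`.
#' @param salinity Practical salinity in `[0, 42]`.
#' @param unit `"mmol_m3"` (default) or `"umol_kg"`.
#' @return Saturation concentration in the requested unit.
#' @export
o2_saturation_concentration <- function(temperature, salinity,
                                        unit = c("mmol_m3", "umol_kg")) {
  unit <- match.arg(unit)
  if (any(temperature < -2 | temperature > 40))
    stop("temperature out of range [-2, 40] C", call. = FALSE)
  if (any(salinity < 0 | salinity > 42))
    stop("salinity out of range [0, 42]", call. = FALSE)
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  lnc <- .o2_A[1] + .o2_A[2] * ts + .o2_A[3] * ts^2 + .o2_A[4] * ts^3 +
    .o2_A[5] * ts^4 + .o2_A[6] * ts^5 +
    salinity * (.o2_B[1] + .o2_B[2] * ts + .o2_B[3] * ts^2 + .o2_B[4] * ts^3) +
    .o2_C0 * salinity^2
  umol_kg <- exp(lnc)
  if (unit == "umol_kg") return(umol_kg)
  umol_kg * seawater_density(temperature, salinity) / 1000
}

#' Schmidt number for oxygen in (sea)water
#'
#' Fourth-order polynomial fits in temperature for fresh water and
#' salinity-35 seawater, interpolated linearly in salinity.
#'
#' @inheritParams seawater_density
#' @return Dimensionless Schmidt number.
#' @export
schmidt_o2 <- function(temperature, salinity = 35) {
  t <- temperature
  sc_fw <- 1745.1 - 124.34 * t + 4.8055 * t^2 - 0.10115 * t^3 + 8.6842e-4 * t^4
  sc_sw <- 1920.4 - 135.6 * t + 5.2122 * t^2 - 0.10939 * t^3 + 9.3777e-4 * t^4
  sc_fw + (sc_sw - sc_fw) * pmin(salinity, 35) / 35
}

#' Gas transfer velocity for oxygen
#'
#' Registered parameterizations for a shallow, limited-fetch tidal channel:
#' an additive wind-speed plus current-velocity model (default), and
#' current-only / wind-only variants. The wind term is quadratic in wind
#' speed; the current term scales with `sqrt(current / depth)`
#' (surface-renewal form). Coefficients give k600 in cm h^-1 and are
#' configurable; the result is Schmidt-scaled (`(Sc/600)^-1/2`) and
#' returned in m min^-1. Every model is non-decreasing in wind at fixed
#' current and in current at fixed wind.
#'
#' @param wind Wind speed at 10 m, m s^-1.
#' @param current Depth-averaged current speed, m s^-1.
#' @param depth Water depth, m (> 0).
#' @param temperature,salinity Water properties for Schmidt scaling.
#' @param model `"wind_current"`, `"current_only"` or `"wind_only"`.
#' @param coef Named list of k600 coefficients (`wind` in
#'   cm h^-1 (m s^-1)^-2, `current` in cm h^-1 per sqrt(s^-1)).
#' @return Gas transfer velocity k, m min^-1.
#' @export
gas_transfer_velocity <- function(wind, current, depth, temperature = 20,
                                  salinity = 30,
                                  model = c("wind_current", "current_only",
                                            "wind_only"),
                                  coef = list(wind = 0.266, current = 16.4)) {
  model <- match.arg(model)
  if (any(depth <= 0)) stop("depth must be > 0", call. = FALSE)
  wind_term <- coef$wind * wind^2
  current_term <- coef$current * sqrt(pmax(current, 0) / depth)
  k600_cmh <- switch(model,
                     wind_current = wind_term + current_term,
                     current_only = current_term,
                     wind_only = wind_term)
  sc <- schmidt_o2(temperature, salinity)
  k600_cmh * (sc / 600)^(-0.5) / 100 / 60
}

#' Tidal creek control-volume geometry
#'
#' Trapezoidal cross-section: surface width
#' `bottom_width + 2 bank_slope depth`, wetted volume per unit creek length
#' `bottom_width depth + bank_slope depth^2`. Both are non-decreasing in
#' depth.
#'
#' @param bottom_width Channel bottom width, m (> 0).
#' @param bank_slope Horizontal run per unit rise of the banks (>= 0).
#' @param flood_elevation Depth (m) above which the marsh platform floods
#'   and high-tide NEM windows are flagged for possible bias.
#' @param length Control-volume creek length, m (results are per unit
#'   length; this is metadata).
#' @return A `creek_geometry` list.
#' @export
creek_geometry <- function(bottom_width = 4, bank_slope = 2,
                           flood_elevation = 1.75, length = 1) {
  if (bottom_width <= 0 || length <= 0)
    stop("bottom_width and length must be > 0", call. = FALSE)
  if (bank_slope < 0) stop("bank_slope must be >= 0", call. = FALSE)
  structure(list(bottom_width = bottom_width, bank_slope = bank_slope,
                 flood_elevation = flood_elevation, length = length),
            class = "creek_geometry")
}

#' @rdname creek_geometry
#' @param geometry A `creek_geometry`.
#' @param depth Water depth, m.
#' @export
channel_width <- function(geometry, depth) {
  geometry$bottom_width + 2 * geometry$bank_slope * depth
}

#' @rdname creek_geometry
#' @export
wetted_volume <- function(geometry, depth) {
  geometry$bottom_width * depth + geometry$bank_slope * depth^2
}

# centred finite difference with one-sided stencils at the ends,
# per minute
finite_diff <- function(x, dt_min) {
  n <- length(x)
  if (n < 3L) stop("need >= 3 points for finite differences", call. = FALSE)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / dt_min
  d[n] <- (x[n] - x[n - 1L]) / dt_min
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt_min)
  d
}

#' Tidally varying water balance from depth and geometry
#'
#' Per-unit-length wetted volume from the cross-section, its time
#' derivative by centred finite differences (one-sided at the ends), and
#' the advective volume flux `Q_adv = dV/dt` (freshwater, porewater and
#' platform-drainage fluxes are negligible for this balance and excluded).
#'
#' @param depth Water depth series, m (uniform step).
#' @param dt_min Series step, minutes.
#' @param geometry A `creek_geometry`.
#' @return List with `volume` (m^3 m^-1), `dVdt` and `q_adv`
#'   (m^3 m^-1 min^-1).
#' @export
water_balance <- function(depth, dt_min, geometry) {
  if (any(depth < 0)) stop("negative depth", call. = FALSE)
  v <- wetted_volume(geometry, depth)
  dvdt <- finite_diff(v, dt_min)
  list(volume = v, dVdt = dvdt, q_adv = dvdt)
}

#' Air-water oxygen exchange flux per unit creek length
#'
#' `F = k(wind, current, depth) (C_sat - C) width(depth)`; positive fluxes
#' add oxygen to the water, supersaturation outgasses.
#'
#' @param wind,current,depth Series as in [gas_transfer_velocity()].
#' @param conc Dissolved O2, mmol m^-3.
#' @param temperature,salinity Water properties.
#' @param geometry A `creek_geometry`.
#' @inheritParams gas_transfer_velocity
#' @param k_scale Scalar multiplier on k (default 1).
#' @return Flux, mmol O2 m^-1 min^-1.
#' @export
gas_exchange_flux <- function(wind, current, depth, conc, temperature,
                              salinity, geometry,
                              model = "wind_current",
                              coef = list(wind = 0.266, current = 16.4),
                              k_scale = 1) {
  k <- gas_transfer_velocity(wind, current, depth, temperature, salinity,
                             model = model, coef = coef) * k_scale
  csat <- o2_saturation_concentration(temperature, salinity)
  k * (csat - conc) * channel_width(geometry, depth)
}

#' Net ecosystem metabolism from a creek oxygen series
#'
#' Solves the non-steady-state oxygen mass balance for a well-mixed control
#' volume per unit creek length:
#' `NEM(t) = d(VC)/dt - Q_adv C - F_gas`, where the advective boundary
#' concentration is the measured in-creek concentration (single-sensor,
#' well-mixed assumption), so biological production/consumption is the
#' residual of storage change, advection and gas exchange. Positive NEM is
#' net autotrophy.
#'
#' @param series A `creek_series` (see [read_creek_series()]).
#' @param geometry A `creek_geometry`.
#' @inheritParams gas_exchange_flux
#' @param dt_eval Evaluation interval, minutes; must be a multiple of the
#'   series step (default 10).
#' @return A `nem_result`: data frame with `timestamp`, `minutes`, `depth`,
#'   `nem`, `gas_flux`, `advective`, `storage`, `volume`, `conc`; the
#'   geometry and evaluation step are attached as attributes.
#' @export
nem_series <- function(series, geometry, model = "wind_current",
                       coef = list(wind = 0.266, current = 16.4),
                       k_scale = 1, dt_eval = 10) {
  stopifnot(inherits(series, "creek_series"))
  dt <- attr(series, "dt_min")
  if (is.na(dt)) stop("series too short", call. = FALSE)
  if (abs(dt_eval / dt - round(dt_eval / dt)) > 1e-8 || dt_eval < dt)
    stop("dt_eval must be a multiple of the series step (", dt, " min)",
         call. = FALSE)
  csat <- o2_saturation_concentration(series$temperature_c, series$salinity)
  conc <- if ("o2_mmol_m3" %in% names(series)) series$o2_mmol_m3
          else series$o2_saturation_pct / 100 * csat
  wb <- water_balance(series$depth_m, dt, geometry)
  f_gas <- gas_exchange_flux(series$wind_m_s, series$current_m_s,
                             series$depth_m, conc, series$temperature_c,
                             series$salinity, geometry,
                             model = model, coef = coef, k_scale = k_scale)
  storage <- finite_diff(wb$volume * conc, dt)
  advective <- wb$q_adv * conc
  nem <- storage - advective - f_gas
  keep <- seq(1L, nrow(series), by = as.integer(round(dt_eval / dt)))
  out <- data.frame(timestamp = series$timestamp[keep],
                    minutes = (as.numeric(series$timestamp[keep]) -
                               as.numeric(series$timestamp[1L])) / 60,
                    depth = series$depth_m[keep],
                    nem = nem[keep],
                    gas_flux = f_gas[keep],
                    advective = advective[keep],
                    storage = storage[keep],
                    volume = wb$volume[keep],
                    conc = conc[keep])
  structure(out, geometry = geometry, dt_eval = dt_eval,
            class = c("nem_result", "data.frame"))
}

# local depth maxima separated by at least min_separation (minutes);
# ties broken toward the earlier point, highest peak wins within a window
find_high_tides <- function(depth, minutes, min_separation) {
  n <- length(depth)
  cand <- which(diff(sign(diff(depth))) < 0) + 1L
  cand <- cand[order(depth[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(minutes[i] - minutes[keep]) >= min_separation))
      keep <- c(keep, i)
  }
  sort(keep)
}

#' High-tide window means of NEM
#'
#' Identifies local depth maxima (separated by at least
#' `min_separation_h` hours, matching a semidiurnal tide) and summarises
#' NEM over a window of `window_min` minutes centred on each maximum.
#' Windows truncated by the series boundary are dropped with a warning;
#' windows whose peak depth exceeds the geometry's platform flooding
#' elevation are flagged `peak_flood_bias` (possible positive bias from
#' platform drainage at the biggest tides).
#'
#' @param result A `nem_result` from [nem_series()].
#' @param window_min Window width, minutes (default 60).
#' @param min_separation_h Minimum separation between high tides, hours
#'   (default 6).
#' @return Data frame: `centre_minutes`, `centre_time`, `mean_nem`,
#'   `sd_nem`, `n`, `peak_depth`, `peak_flood_bias`.
#' @export
high_tide_means <- function(result, window_min = 60, min_separation_h = 6) {
  stopifnot(inherits(result, "nem_result"))
  geometry <- attr(result, "geometry")
  peaks <- find_high_tides(result$depth, result$minutes, min_separation_h * 60)
  if (!length(peaks)) stop("no high-tide maxima found", call. = FALSE)
  half <- window_min / 2
  rows <- lapply(peaks, function(i) {
    inwin <- abs(result$minutes - result$minutes[i]) <= half
    if (result$minutes[i] - half < min(result$minutes) ||
        result$minutes[i] + half > max(result$minutes)) {
      warning("dropping high-tide window truncated by series boundary at ",
              format(result$timestamp[i]), call. = FALSE)
      return(NULL)
    }
    data.frame(centre_minutes = result$minutes[i],
               centre_time = result$timestamp[i],
               mean_nem = mean(result$nem[inwin]),
               sd_nem = stats::sd(result$nem[inwin]),
               n = sum(inwin),
               peak_depth = max(result$depth[inwin]),
               peak_flood_bias = max(result$depth[inwin]) >
                 geometry$flood_elevation)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all high-tide windows truncated", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Paired high-tide NEM difference between two creeks
#'
#' Matches high-tide windows of two creeks by tide time (within
#' `tolerance_min`) and returns the per-window difference of mean NEM
#' (`a - b`), with standard deviations propagated in quadrature.
#'
#' @param a,b High-tide window summaries from [high_tide_means()]
#'   (conventionally `a` = enriched creek, `b` = reference creek).
#' @param tolerance_min Maximum tide-time mismatch, minutes (default 60).
#' @return Data frame: `centre_minutes`, `diff_nem`, `sd_diff`,
#'   `peak_flood_bias` (either creek flagged).
#' @export
creek_difference <- function(a, b, tolerance_min = 60) {
  if (nrow(a) != nrow(b))
    stop("unmatched window counts: ", nrow(a), " vs ", nrow(b), call. = FALSE)
  dtime <- abs(a$centre_minutes - b$centre_minutes)
  if (any(dtime > tolerance_min))
    stop("window centres differ by more than ", tolerance_min, " min",
         call. = FALSE)
  data.frame(centre_minutes = (a$centre_minutes + b$centre_minutes) / 2,
             diff_nem = a$mean_nem - b$mean_nem,
             sd_diff = sqrt(a$sd_nem^2 + b$sd_nem^2),
             peak_flood_bias = a$peak_flood_bias | b$peak_flood_bias)
}

#' Constant bias correction for platform-flooding windows
#'
#' Subtracts a constant positive bias (oxygen attributed to the creek by
#' drainage of an adjacent platform at peak tides) from the mean NEM of the
#' flagged high-tide windows only.
#'
#' @param windows High-tide window summary from [high_tide_means()].
#' @param bias Bias to subtract, mmol O2 m^-1 min^-1 (>= 0).
#' @return The window summary with corrected `mean_nem`; attribute
#'   `bias_applied` records the correction.
#' @export
apply_bias_correction <- function(windows, bias = 0.35) {
  if (bias < 0) stop("bias must be >= 0", call. = FALSE)
  flagged <- windows$peak_flood_bias
  if (!any(flagged)) {
    warning("no flagged windows; bias correction is the identity",
            call. = FALSE)
  } else {
    windows$mean_nem[flagged] <- windows$mean_nem[flagged] - bias
  }
  attr(windows, "bias_applied") <- bias
  windows
}
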