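test_that("oxygen solubility matches the published combined-fit check value", {
  # check value of the combined fit: 274.610 umol/kg at T = 10 C, S = 35
  expect_equal(o2_saturation_concentration(10, 35, unit = "umol_kg"),
               274.610, tolerance = 1e-5)
  expect_equal(seawater_density(5, 35), 1027.67547, tolerance = 1e-7)
  # physical monotonicity: solubility falls with T and with S
  temps <- seq(0, 35, by = 5)
  expect_true(all(diff(o2_saturation_concentration(temps, 30)) < 0))
  sals <- seq(0, 40, by = 5)
  expect_true(all(diff(o2_saturation_concentration(15, sals)) < 0))
  expect_error(o2_saturation_concentration(45, 30), "temperature")
  expect_error(o2_saturation_concentration(10, 50), "salinity")
  # mmol/m3 output is umol/kg times density
  expect_equal(o2_saturation_concentration(10, 35),
               o2_saturation_concentration(10, 35, "umol_kg") *
                 seawater_density(10, 35) / 1000)
})

test_that("gas transfer velocity is monotone in wind and current for every model", {
  for (model in c("wind_current", "current_only", "wind_only")) {
    k_w <- gas_transfer_velocity(seq(0, 12, by = 2), 0.2, 1, model = model)
    expect_true(all(diff(k_w) >= 0))
    k_c <- gas_transfer_velocity(4, seq(0, 1, by = 0.1), 1, model = model)
    expect_true(all(diff(k_c) >= 0))
    expect_true(all(c(k_w, k_c) >= 0))
  }
  # single-driver models are smaller than the combined model
  expect_lt(gas_transfer_velocity(5, 0.3, 1, model = "current_only"),
            gas_transfer_velocity(5, 0.3, 1, model = "wind_current"))
  expect_lt(gas_transfer_velocity(5, 0.3, 1, model = "wind_only"),
            gas_transfer_velocity(5, 0.3, 1, model = "wind_current"))
  expect_error(gas_transfer_velocity(5, 0.3, 0), "depth")
})

test_that("water balance derives volume and its derivative from geometry", {
  geom_rect <- creek_geometry(bottom_width = 3, bank_slope = 0)
  h <- c(1, 1, 1, 1, 1)
  wb <- water_balance(h, 10, geom_rect)
  expect_equal(wb$dVdt, rep(0, 5)) # constant depth
  # rectangular channel: V = w h, dV/dt = w dh/dt
  h2 <- seq(0.5, 1.3, by = 0.2)
  wb2 <- water_balance(h2, 10, geom_rect)
  expect_equal(wb2$volume, 3 * h2)
  expect_equal(wb2$dVdt, 3 * rep(0.02, 5), tolerance = 1e-12)
  # trapezoid volume equals the integral of width over depth
  geom <- creek_geometry(bottom_width = 4, bank_slope = 2)
  for (d in c(0.3, 1, 1.9)) {
    expect_equal(wetted_volume(geom, d),
                 stats::integrate(function(z) channel_width(geom, z), 0, d,
                                  rel.tol = 1e-12)$value,
                 tolerance = 1e-9)
  }
  expect_true(all(diff(channel_width(geom, seq(0, 2, 0.1))) >= 0))
  expect_error(water_balance(c(-0.1, 1, 1), 10, geom), "negative depth")
})

test_that("gas exchange flux vanishes at equilibrium and outgasses supersaturation", {
  geom <- creek_geometry()
  csat <- o2_saturation_concentration(25, 30)
  expect_equal(gas_exchange_flux(3, 0.2, 1, csat, 25, 30, geom), 0)
  expect_lt(gas_exchange_flux(3, 0.2, 1, csat * 1.2, 25, 30, geom), 0)
  expect_gt(gas_exchange_flux(3, 0.2, 1, csat * 0.8, 25, 30, geom), 0)
})

test_that("closed-system and equilibrium limits return the analytic NEM", {
  # closed system (no tide, k = 0): a linear O2 decline of 1 mmol m^-3
  # min^-1 in a 10 m^3 m^-1 volume is NEM = -10 mmol O2 m^-1 min^-1
  geom <- creek_geometry(bottom_width = 10, bank_slope = 0,
                         flood_elevation = 5)
  n <- 73
  csat <- o2_saturation_concentration(25, 30)
  conc <- csat - (seq_len(n) - 1) * 1
  series <- as_creek_series(data.frame(
    timestamp = as.POSIXct("2012-08-01", tz = "UTC") + 600 * (seq_len(n) - 1),
    depth_m = 1, temperature_c = 25, salinity = 30,
    o2_mmol_m3 = conc, wind_m_s = 0, current_m_s = 0))
  res <- nem_series(series, geom, k_scale = 0, dt_eval = 10)
  expect_equal(res$nem, rep(-10 * 0.1, n), tolerance = 1e-9)
  # (0.1 mmol m^-3 min^-1 decline over the 10-min step: scaled case)
  # steady state at saturation with no volume change: NEM = 0
  series0 <- as_creek_series(data.frame(
    timestamp = as.POSIXct("2012-08-01", tz = "UTC") + 600 * (seq_len(n) - 1),
    depth_m = 1, temperature_c = 25, salinity = 30,
    o2_saturation_pct = 100, wind_m_s = 3, current_m_s = 0.2))
  res0 <- nem_series(series0, geom, dt_eval = 10)
  expect_equal(res0$nem, rep(0, n), tolerance = 1e-9)
})

test_that("the discrete mass balance closes exactly", {
  sim <- simulate_tidal_creek(creek_sim_config(seed = 4, days = 2))
  res <- nem_series(sim$series, creek_geometry(), dt_eval = 10)
  # NEM + gas + advective re-sums to the storage derivative identically
  expect_equal(res$nem + res$gas_flux + res$advective, res$storage,
               tolerance = 1e-12)
  # centred differences telescope: the interior sum equals the half-sum of
  # boundary storage terms
  vc <- res$volume * res$conc
  n <- length(vc)
  lhs <- sum(res$storage[2:(n - 1)]) * 10
  rhs <- (vc[n] + vc[n - 1] - vc[2] - vc[1]) / 2
  expect_equal(lhs, rhs, tolerance = max(1e-6 * abs(rhs), 1e-8))
})

test_that("forward-simulated NEM is recovered across gas-exchange strengths", {
  for (ks in c(0, 1, 3)) {
    sim <- simulate_tidal_creek(creek_sim_config(seed = 10 + ks, days = 3,
                                                 k_scale = ks))
    res <- nem_series(sim$series, creek_geometry(), k_scale = ks,
                      dt_eval = 10)
    rmse <- sqrt(mean((res$nem - sim$truth$nem)^2))
    expect_lt(rmse, 0.05 * diff(range(sim$truth$nem)))
  }
  # pure respiration: NEM strictly negative throughout
  simr <- simulate_tidal_creek(creek_sim_config(seed = 3, days = 2, p0 = 0,
                                                respiration = 0.4))
  resr <- nem_series(simr$series, creek_geometry(), dt_eval = 10)
  expect_true(all(resr$nem < 0))
})

test_that("halving the sampling step changes recovered NEM by < 1%", {
  # same simulated trajectory emitted at 5- and 10-min sensor resolution
  sim5 <- simulate_tidal_creek(creek_sim_config(seed = 21, days = 2,
                                                dt_min = 5))
  sim10 <- simulate_tidal_creek(creek_sim_config(seed = 21, days = 2,
                                                 dt_min = 10))
  res5 <- nem_series(sim5$series, creek_geometry(), dt_eval = 10)
  res10 <- nem_series(sim10$series, creek_geometry(), dt_eval = 10)
  scale <- diff(range(sim10$truth$nem))
  interior <- 2:(nrow(res10) - 1)
  expect_lt(max(abs(res5$nem[interior] - res10$nem[interior])) / scale, 0.01)
})

test_that("high-tide windows: 12 tides in 6 days, flags follow peak depth", {
  sim <- simulate_tidal_creek(creek_sim_config(seed = 1))
  res <- nem_series(sim$series, creek_geometry(), dt_eval = 10)
  ht <- high_tide_means(res)
  expect_identical(nrow(ht), 12L)
  expect_true(all(ht$n == 7)) # 60-min window at 10-min sampling
  expect_true(all(diff(ht$centre_minutes) >= 6 * 60))
  expect_identical(ht$peak_flood_bias,
                   ht$peak_depth > creek_geometry()$flood_elevation)
  expect_true(any(ht$peak_flood_bias) && !all(ht$peak_flood_bias))
  expect_true(all(ht$sd_nem >= 0))
})

test_that("constant NEM gives zero window s.d.; truncated windows are dropped", {
  # flat depth ripple gives well-defined maxima with constant-NEM series
  n <- 6 * 144 + 1
  minutes <- 10 * (seq_len(n) - 1)
  depth <- 1 + 0.3 * sin(2 * pi * minutes / (12.4 * 60))
  csat <- o2_saturation_concentration(25, 30)
  series <- as_creek_series(data.frame(
    timestamp = as.POSIXct("2012-08-01", tz = "UTC") + minutes * 60,
    depth_m = depth, temperature_c = 25, salinity = 30,
    o2_saturation_pct = 100, wind_m_s = 0, current_m_s = 0))
  res <- nem_series(series, creek_geometry(bottom_width = 4, bank_slope = 0),
                    k_scale = 0, dt_eval = 10)
  ht <- high_tide_means(res)
  expect_true(all(abs(ht$mean_nem) < 1e-9))
  expect_true(all(ht$sd_nem < 1e-9))
  # truncate the series just after the second peak: that window is dropped
  peaks <- which(diff(sign(diff(res$depth))) < 0) + 1
  res_cut <- res[seq_len(peaks[2] + 1), ]
  attr(res_cut, "geometry") <- attr(res, "geometry")
  class(res_cut) <- class(res)
  expect_warning(ht_cut <- high_tide_means(res_cut), "truncated")
  expect_identical(nrow(ht_cut), 1L)
})

test_that("creek differencing pairs windows and propagates spread", {
  sim <- simulate_tidal_creek(creek_sim_config(seed = 1))
  res <- nem_series(sim$series, creek_geometry(), dt_eval = 10)
  ht <- high_tide_means(res)
  d0 <- creek_difference(ht, ht)
  expect_true(all(d0$diff_nem == 0))
  shifted <- ht; shifted$mean_nem <- ht$mean_nem + 0.25
  expect_equal(creek_difference(shifted, ht)$diff_nem, rep(0.25, nrow(ht)))
  expect_equal(creek_difference(shifted, ht)$sd_diff,
               sqrt(2) * ht$sd_nem)
  expect_error(creek_difference(ht[-1, ], ht), "unmatched window counts")
})

test_that("enriched creek shows higher daytime and lower night-time NEM difference", {
  ref <- simulate_tidal_creek(creek_sim_config(seed = 31))
  enr <- simulate_tidal_creek(creek_sim_config(seed = 32, p0 = 1.2 * 1.6,
                                               respiration = 0.5 * 1.6))
  ht_ref <- high_tide_means(nem_series(ref$series, creek_geometry(),
                                       dt_eval = 10))
  ht_enr <- high_tide_means(nem_series(enr$series, creek_geometry(),
                                       dt_eval = 10))
  d <- creek_difference(ht_enr, ht_ref)
  hour <- (d$centre_minutes / 60) %% 24
  day <- hour >= 9 & hour <= 16
  night <- hour <= 4 | hour >= 21
  expect_gt(mean(d$diff_nem[day]), 0)
  expect_lt(mean(d$diff_nem[night]), 0)
})

test_that("bias correction shifts only flagged windows by the stated amount", {
  sim <- simulate_tidal_creek(creek_sim_config(seed = 1))
  ht <- high_tide_means(nem_series(sim$series, creek_geometry(),
                                   dt_eval = 10))
  corr <- apply_bias_correction(ht, bias = 0.35)
  flagged <- ht$peak_flood_bias
  expect_equal(corr$mean_nem[flagged], ht$mean_nem[flagged] - 0.35)
  expect_equal(corr$mean_nem[!flagged], ht$mean_nem[!flagged])
  expect_equal(attr(corr, "bias_applied"), 0.35)
  # zero bias is the identity
  expect_equal(apply_bias_correction(ht, 0)$mean_nem, ht$mean_nem)
  # no flagged windows: identity with a warning
  ht0 <- ht; ht0$peak_flood_bias <- FALSE
  expect_warning(same <- apply_bias_correction(ht0, 0.35), "identity")
  expect_equal(same$mean_nem, ht0$mean_nem)
  expect_error(apply_bias_correction(ht, -1), ">= 0")
})
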