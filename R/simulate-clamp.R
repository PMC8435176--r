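# piecewise-exponential approach to a sequence of phase targets;
# each segment starts from the value reached at the previous boundary
relax_profile <- function(t, breaks, targets, taus) {
  stopifnot(length(targets) == length(breaks) + 1,
            length(taus) == length(breaks))
  out <- rep(targets[1], length(t))
  start_val <- targets[1]
  for (k in seq_along(breaks)) {
    t0 <- breaks[k]
    # value actually reached at this boundary under the previous segment
    if (k > 1) {
      start_val <- targets[k] + (start_val - targets[k]) *
        exp(-(t0 - breaks[k - 1]) / taus[k - 1])
    }
    idx <- t >= t0
    out[idx] <- targets[k + 1] + (start_val - targets[k + 1]) *
      exp(-(t[idx] - t0) / taus[k])
  }
  out
}

#' Simulate a two-step hyperinsulinaemic-euglycaemic clamp time series
#'
#' Generates a basal / low-insulin / high-insulin clamp time course for one
#' participant-regimen: plasma glucose, tracer-to-tracee ratio (TTR), the
#' constant tracer infusion and the exogenous glucose infusion rate (GIR).
#' Infusion rates and EGP approach their phase targets exponentially, plasma
#' glucose is clamped near euglycaemia, and the TTR trajectory is obtained by
#' integrating the single-pool tracer mass balance
#' \eqn{Z'(t) = (F - R_a(t) Z(t)) / (p_V C(t))}, so at zero measurement noise
#' the Steele estimator applied to the output recovers the generating fluxes
#' up to discretisation error.
#'
#' @param profile One row of [generate_profiles()] (data frame or list) for
#'   the participant-regimen to simulate.
#' @param cfg A [cohort_config()].
#' @param seed Integer seed for measurement noise.
#' @param noise_scale Multiplier on the configured measurement-noise SDs
#'   (0 gives a noise-free series).
#' @param pv Effective glucose distribution volume, l/kg.
#' @return A tibble with columns `time_min`, `phase` (basal/low/high),
#'   `glucose_mmol_l`, `ttr`, `tracer_umol_kg_min`, `gir_umol_kg_min`; the
#'   generating truth is attached as attribute `"truth"`.
#' @export
generate_clamp_timeseries <- function(profile, cfg, seed = 1L,
                                      noise_scale = 1, pv = 0.160) {
  profile <- as.list(profile)
  if (is.null(profile$body_mass) || profile$body_mass <= 0) {
    stop("profile body mass must be positive", call. = FALSE)
  }
  set.seed(seed)
  f_tracer <- tracer_umol_kg_min(cfg)
  ph <- cfg$phase_minutes
  t_low <- unname(ph[["basal"]])
  t_high <- t_low + unname(ph[["low"]])
  t_end <- t_high + unname(ph[["high"]])
  tau_inf <- 20   # min, approach of infusion/EGP targets
  tau_glc <- 15   # min, glucose clamping dynamics

  dt <- 0.25
  tt <- seq(0, t_end, by = dt)
  gir <- relax_profile(tt, c(t_low, t_high),
                       c(0, profile$gir_low, profile$gir_high),
                       c(tau_inf, tau_inf))
  egp <- relax_profile(tt, c(t_low, t_high),
                       c(profile$true_egp_basal, profile$true_egp_low,
                         profile$true_egp_high),
                       c(tau_inf, tau_inf))
  glc <- relax_profile(tt, c(t_low, t_high),
                       c(cfg$glucose_basal, cfg$glucose_clamp,
                         cfg$glucose_clamp),
                       c(tau_glc, tau_glc))
  ra <- egp + gir
  c_umol <- glc * 1000

  # RK4 integration of the tracer pool; the primed infusion puts Z near its
  # basal plateau from the start
  z <- numeric(length(tt))
  z[1] <- 0.9 * f_tracer / ra[1]
  zdot <- function(zi, rai, ci) (f_tracer - rai * zi) / (pv * ci)
  for (k in seq_len(length(tt) - 1)) {
    ra_mid <- (ra[k] + ra[k + 1]) / 2
    c_mid <- (c_umol[k] + c_umol[k + 1]) / 2
    k1 <- zdot(z[k], ra[k], c_umol[k])
    k2 <- zdot(z[k] + dt / 2 * k1, ra_mid, c_mid)
    k3 <- zdot(z[k] + dt / 2 * k2, ra_mid, c_mid)
    k4 <- zdot(z[k] + dt * k3, ra[k + 1], c_umol[k + 1])
    z[k + 1] <- z[k] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  keep <- which(tt %% cfg$sample_interval_min == 0)
  ts <- tt[keep]
  phase <- ifelse(ts < t_low, "basal", ifelse(ts < t_high, "low", "high"))
  glc_meas <- glc[keep] +
    stats::rnorm(length(keep), 0, noise_scale * cfg$glucose_noise_sd)
  ttr_meas <- z[keep] *
    (1 + stats::rnorm(length(keep), 0, noise_scale * cfg$ttr_noise_cv))

  out <- tibble::tibble(
    time_min = ts,
    phase = phase,
    glucose_mmol_l = glc_meas,
    ttr = ttr_meas,
    tracer_umol_kg_min = f_tracer,
    gir_umol_kg_min = gir[keep]
  )
  attr(out, "truth") <- profile
  out
}

#' Simulate steady-state gas exchange per clamp phase
#'
#' Produces one (VO2, VCO2) pair per clamp phase, consistent by construction
#' with the participant's basal RER and the regimen's true high-insulin
#' carbohydrate oxidation (inverted through the Frayn equations, assuming a
#' small residual insulin-suppressed fat oxidation); the low-insulin phase is
#' intermediate.
#'
#' @inheritParams generate_clamp_timeseries
#' @return A tibble with columns `phase`, `vo2_l_min`, `vco2_l_min`.
#' @export
generate_gas_exchange <- function(profile, cfg, seed = 1L, noise_scale = 1) {
  profile <- as.list(profile)
  set.seed(seed)
  vo2_b <- profile$vo2_baseline
  vco2_b <- profile$rer_basal * vo2_b

  cho_g_high <- profile$true_cho_ox_high * 180.16 * profile$body_mass / 1e6
  d_high <- cfg$fat_ox_high_g_min / 1.67
  vco2_h <- (cho_g_high + 3.21 * d_high) / 1.34
  vo2_h <- vco2_h + d_high

  vo2 <- c(basal = vo2_b, low = (vo2_b + vo2_h) / 2, high = vo2_h)
  vco2 <- c(basal = vco2_b, low = (vco2_b + vco2_h) / 2, high = vco2_h)
  noise <- noise_scale * cfg$gas_noise_sd
  tibble::tibble(
    phase = names(vo2),
    vo2_l_min = pmax(0.05, unname(vo2) + stats::rnorm(3, 0, noise)),
    vco2_l_min = pmax(0.04, unname(vco2) + stats::rnorm(3, 0, noise))
  )
}
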