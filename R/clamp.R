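#' Kinetics configuration for Steele flux estimation
#'
#' @param pv Effective glucose distribution volume, l/kg. The study constant
#'   is 0.160 l/kg.
#' @param window_min Length of the steady-state averaging window at the end of
#'   each phase, minutes.
#' @param smooth Logical; apply a 3-point moving average to the measured TTR
#'   and glucose before differentiation. Off by default.
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(pv = 0.160, window_min = 30, smooth = FALSE) {
  if (pv <= 0) stop("pv must be > 0", call. = FALSE)
  if (window_min <= 0) stop("window_min must be > 0", call. = FALSE)
  structure(list(pv = pv, window_min = window_min, smooth = smooth),
            class = "kinetics_config")
}

moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

#' Steele single-pool non-steady-state glucose fluxes
#'
#' Estimates the glucose rate of appearance (Ra) and disappearance (Rd) on
#' every interval between consecutive samples using Steele's single-pool
#' non-steady-state equations with a tracer-to-tracee ratio (TTR) enrichment
#' measure. For consecutive samples 1, 2 with glucose C (converted to
#' umol/l), TTR Z and tracer infusion F (umol kg-1 min-1):
#' \deqn{R_a = \frac{F - p_V \bar{C} (Z_2 - Z_1)/(t_2 - t_1)}{\bar{Z}}}
#' \deqn{R_d = R_a - p_V (C_2 - C_1)/(t_2 - t_1)}
#' with arithmetic midpoints for \eqn{\bar{C}} and \eqn{\bar{Z}}.
#'
#' @param series Clamp time-series tibble with columns `time_min`, `phase`,
#'   `glucose_mmol_l`, `ttr`, `tracer_umol_kg_min`, `gir_umol_kg_min`.
#' @param cfg A [kinetics_config()].
#' @return A tibble with one row per interval: midpoint time `time_mid`,
#'   `phase` (NA for intervals crossing a phase boundary), `ra`, `rd`
#'   (umol kg-1 min-1), mean `gir`, and a `flag` column marking undefined
#'   fluxes (mean TTR <= 0).
#' @export
steele_fluxes <- function(series, cfg = kinetics_config()) {
  stopifnot(all(c("time_min", "phase", "glucose_mmol_l", "ttr",
                  "tracer_umol_kg_min", "gir_umol_kg_min") %in% names(series)))
  if (nrow(series) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(series$time_min) <= 0)) {
    stop("time_min must be strictly increasing", call. = FALSE)
  }
  z <- series$ttr
  c_umol <- series$glucose_mmol_l * 1000
  if (isTRUE(cfg$smooth)) {
    z <- moving_average3(z)
    c_umol <- moving_average3(c_umol)
  }
  n <- nrow(series)
  i1 <- seq_len(n - 1)
  i2 <- i1 + 1
  dt <- series$time_min[i2] - series$time_min[i1]
  zbar <- (z[i1] + z[i2]) / 2
  cbar <- (c_umol[i1] + c_umol[i2]) / 2
  fbar <- (series$tracer_umol_kg_min[i1] + series$tracer_umol_kg_min[i2]) / 2

  ra <- (fbar - cfg$pv * cbar * (z[i2] - z[i1]) / dt) / zbar
  rd <- ra - cfg$pv * (c_umol[i2] - c_umol[i1]) / dt
  flag <- zbar <= 0
  ra[flag] <- NA_real_
  rd[flag] <- NA_real_

  tibble::tibble(
    time_mid = (series$time_min[i1] + series$time_min[i2]) / 2,
    phase = ifelse(series$phase[i1] == series$phase[i2],
                   series$phase[i1], NA_character_),
    ra = ra,
    rd = rd,
    gir = (series$gir_umol_kg_min[i1] + series$gir_umol_kg_min[i2]) / 2,
    flag = flag
  )
}

#' Steady-state flux estimate over the final phase window
#'
#' Averages the interval-level Steele fluxes over the last `window_min`
#' minutes of a clamp phase, mirroring the study protocol in which steady
#' state is reached during the last 30 min of the basal, low- and high-insulin
#' phases. The coefficient of variation of plasma glucose within the window is
#' reported as a quality-control field.
#'
#' @inheritParams steele_fluxes
#' @param phase Phase label to evaluate (`"basal"`, `"low"` or `"high"`).
#' @return A one-row tibble: `phase`, `ra`, `rd`, `gir` (window means),
#'   `glucose_cv` and `n_intervals`.
#' @export
steady_state_estimate <- function(series, cfg = kinetics_config(),
                                  phase = c("high", "low", "basal")) {
  phase <- match.arg(phase)
  sub <- series[series$phase == phase, , drop = FALSE]
  if (nrow(sub) < 2) {
    stop(sprintf("phase '%s' absent or has fewer than 2 samples", phase),
         call. = FALSE)
  }
  span <- max(sub$time_min) - min(sub$time_min)
  if (span < cfg$window_min) {
    stop(sprintf(
      "steady-state window (%g min) not covered by phase '%s' (%g min)",
      cfg$window_min, phase, span), call. = FALSE)
  }
  t_from <- max(sub$time_min) - cfg$window_min
  win <- sub[sub$time_min >= t_from, , drop = FALSE]
  fluxes <- steele_fluxes(win, cfg)
  glucose_cv <- stats::sd(win$glucose_mmol_l) / mean(win$glucose_mmol_l)
  tibble::tibble(
    phase = phase,
    ra = mean(fluxes$ra, na.rm = TRUE),
    rd = mean(fluxes$rd, na.rm = TRUE),
    gir = mean(fluxes$gir, na.rm = TRUE),
    glucose_cv = glucose_cv,
    n_intervals = sum(!fluxes$flag)
  )
}

#' Endogenous glucose production
#'
#' EGP is the glucose rate of appearance minus the exogenous glucose infusion
#' rate; in the basal phase (GIR = 0) EGP equals Ra.
#'
#' @param ra Rate of appearance, umol kg-1 min-1.
#' @param gir Exogenous glucose infusion rate, umol kg-1 min-1.
#' @return EGP, umol kg-1 min-1.
#' @export
compute_egp <- function(ra, gir) {
  ra - gir
}

#' Insulin-mediated EGP suppression
#'
#' Percentage suppression of endogenous glucose production during the
#' low-insulin phase relative to basal:
#' `100 * (EGP_basal - EGP_low) / EGP_basal`. Values above basal (negative
#' suppression) are allowed and flagged with a warning; a non-positive basal
#' EGP makes the quantity undefined (NA, with a warning).
#'
#' @param egp_basal,egp_low EGP in the basal and low-insulin phases,
#'   umol kg-1 min-1.
#' @return Suppression in percent.
#' @export
egp_suppression <- function(egp_basal, egp_low) {
  out <- ifelse(egp_basal > 0, 100 * (egp_basal - egp_low) / egp_basal,
                NA_real_)
  if (any(egp_basal <= 0)) {
    warning("EGP suppression undefined for non-positive basal EGP",
            call. = FALSE)
  }
  if (any(!is.na(out) & out < 0)) {
    warning("negative EGP suppression (EGP rose under insulin)",
            call. = FALSE)
  }
  out
}

#' Non-oxidative glucose disposal
#'
#' NOGD is the high-insulin glucose rate of disappearance minus carbohydrate
#' oxidation, both in umol kg-1 min-1; it proxies insulin-stimulated glycogen
#' storage. Negative values are allowed and flagged with a warning.
#'
#' @param rd_high High-insulin Rd, umol kg-1 min-1.
#' @param cho_ox Carbohydrate oxidation, umol kg-1 min-1.
#' @return NOGD, umol kg-1 min-1.
#' @export
compute_nogd <- function(rd_high, cho_ox) {
  out <- rd_high - cho_ox
  if (any(out < 0, na.rm = TRUE)) {
    warning("negative NOGD (carbohydrate oxidation exceeds Rd)",
            call. = FALSE)
  }
  out
}

#' Per-phase flux estimates for one clamp series
#'
#' Convenience wrapper: runs [steady_state_estimate()] for every phase present
#' in the series and derives EGP per phase.
#'
#' @inheritParams steele_fluxes
#' @return A tibble with one row per phase: `phase`, `ra`, `rd`, `gir`,
#'   `egp`, `glucose_cv`, `n_intervals`.
#' @export
clamp_fluxes <- function(series, cfg = kinetics_config()) {
  phases <- intersect(c("basal", "low", "high"), unique(series$phase))
  out <- dplyr::bind_rows(lapply(phases, function(p) {
    steady_state_estimate(series, cfg, phase = p)
  }))
  out$egp <- compute_egp(out$ra, out$gir)
  out
}
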