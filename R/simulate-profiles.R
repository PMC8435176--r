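#' Draw participant profiles and per-regimen physiological truth
#'
#' Samples a synthetic cohort: per-participant body mass and basal gas
#' exchange, and per-(participant, regimen) ground-truth glucose fluxes used
#' to drive the clamp and calorimetry simulators. Within-person structure is
#' explicit: each participant carries a shared insulin-sensitivity offset on
#' top of which regimen effects and within-person residuals act, so crossover
#' contrasts have the within-person precision the study design relies on.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per (participant, regimen): body mass, true
#'   basal EGP, low-dose suppression fraction, low/high-dose Rd, the glucose
#'   infusion rates implied by mass balance, high-dose carbohydrate oxidation
#'   and NOGD truth, and basal gas-exchange parameters.
#' @export
generate_profiles <- function(cfg, seed = 1L) {
  set.seed(seed)
  n <- cfg$n_participants
  regs <- names(cfg$regimens)
  ids <- sprintf("P%02d", seq_len(n))

  body_mass <- pmax(45, stats::rnorm(n, cfg$body_mass_mean, cfg$body_mass_sd))
  rd_offset <- stats::rnorm(n, 0, cfg$rd_between_sd)
  egp_basal_p <- pmax(5, stats::rnorm(n, cfg$egp_basal_mean, cfg$egp_basal_sd))
  vo2_p <- pmax(0.12, stats::rnorm(n, cfg$vo2_baseline_mean, cfg$vo2_baseline_sd))

  cho_mean <- cfg$rd_high_mean[regs] - cfg$nogd_high_mean[regs]

  grid <- tidyr::expand_grid(participant = ids, regimen = regs)
  i <- match(grid$participant, ids)
  true_rd_high <- cfg$rd_high_mean[grid$regimen] + rd_offset[i] +
    stats::rnorm(nrow(grid), 0, cfg$rd_within_sd)
  supp_low <- pmin(0.99, pmax(0.05,
    stats::rnorm(nrow(grid), cfg$suppression_low_mean, cfg$suppression_low_sd)))
  true_cho_high <- pmax(2, cho_mean[grid$regimen] + stats::rnorm(nrow(grid), 0, 0.8))
  rer_basal <- pmin(0.95, pmax(0.70,
    stats::rnorm(nrow(grid), cfg$rer_basal_mean, cfg$rer_basal_sd)))

  egp_basal <- egp_basal_p[i]
  egp_low <- egp_basal * (1 - supp_low)
  egp_high <- egp_basal * (1 - cfg$suppression_high)
  true_rd_low <- cfg$rd_low_factor * egp_basal

  tibble::tibble(
    participant = grid$participant,
    regimen = grid$regimen,
    body_mass = body_mass[i],
    vo2_baseline = vo2_p[i],
    rer_basal = rer_basal,
    true_egp_basal = egp_basal,
    true_suppression_low = supp_low,
    true_egp_low = egp_low,
    true_egp_high = egp_high,
    true_rd_low = true_rd_low,
    true_rd_high = true_rd_high,
    gir_low = pmax(0, true_rd_low - egp_low),
    gir_high = pmax(0, true_rd_high - egp_high),
    true_cho_ox_high = true_cho_high,
    true_nogd_high = true_rd_high - true_cho_high
  )
}
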