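#' Configuration for a synthetic study cohort
#'
#' Collects every parameter the synthetic-data generators need: cohort size,
#' per-regimen physiological truth (means and dispersions for insulin-stimulated
#' glucose disposal Rd, non-oxidative glucose disposal NOGD, basal endogenous
#' glucose production EGP and its insulin-mediated suppression), clamp sampling
#' and noise settings, and the metabolome effect-structure settings.
#'
#' Physiological truth defaults are seeded from the study's measured regimen
#' means: high-insulin Rd 29.4 / 33.1 / 35.2 and NOGD 15.7 / 19.9 / 22.3
#' umol kg-1 min-1 for SIT / SL / EXE. Dispersion is split into a
#' between-participant offset (SD 2.5) and a within-person regimen residual
#' (SD 1.75, i.e. a within-person SD of paired differences of about 2.48),
#' reflecting that crossover inference rests on within-person contrasts.
#'
#' @param n_participants Number of participants (default 12).
#' @param regimens Named list of [regimen_design()]s (default [default_regimens()]).
#' @param body_mass_mean,body_mass_sd Body mass distribution, kg.
#' @param rd_high_mean Named per-regimen means of high-insulin Rd,
#'   umol kg-1 min-1.
#' @param nogd_high_mean Named per-regimen means of high-insulin NOGD,
#'   umol kg-1 min-1; carbohydrate-oxidation truth is `rd - nogd`.
#' @param rd_between_sd Between-participant SD of the shared Rd offset.
#' @param rd_within_sd Within-person regimen-level residual SD of Rd.
#' @param egp_basal_mean,egp_basal_sd Basal EGP distribution, umol kg-1 min-1.
#' @param suppression_low_mean,suppression_low_sd Fractional EGP suppression
#'   during the low-dose insulin phase (truncated to `[0, 1]`).
#' @param suppression_high Fractional EGP suppression during the high-dose
#'   phase (single value; high-dose EGP is nearly fully suppressed).
#' @param rd_low_factor Low-insulin Rd as a multiple of basal EGP.
#' @param vo2_baseline_mean,vo2_baseline_sd Basal oxygen uptake, l/min.
#' @param rer_basal_mean,rer_basal_sd Basal respiratory exchange ratio.
#' @param fat_ox_high_g_min Residual fat oxidation during high insulin, g/min.
#' @param tracer_mg_kg_min Tracer infusion rate, mg kg-1 min-1 (d2-glucose).
#' @param tracer_molar_mass Tracer molar mass, g/mol (d2-glucose, 182.0).
#' @param glucose_basal,glucose_clamp Basal and clamped plasma glucose, mmol/l.
#' @param sample_interval_min Clamp sampling interval, min.
#' @param phase_minutes Named durations of the basal / low / high phases, min.
#' @param glucose_noise_sd Measurement noise SD on plasma glucose, mmol/l.
#' @param ttr_noise_cv Proportional measurement noise on the tracer-to-tracee
#'   ratio.
#' @param gas_noise_sd Measurement noise SD on VO2 and VCO2, l/min.
#' @param n_metabolites Number of metabolites (default 138).
#' @param n_amino_like Number of amino-acid-like metabolites forced to respond
#'   negatively to exercise.
#' @param shared_fraction Fraction of metabolites that respond to the
#'   interventions (the rest have zero effects).
#' @param lambda Effect-sharing coefficient: the SL effect is
#'   `lambda * beta_EXE + eta` for responding metabolites; must lie in `[0, 1]`
#'   (dose-like intermediacy).
#' @param beta_sd SD of the exercise effect size beta_EXE (log2 units).
#' @param eta_sd SD of the SL-specific effect component eta (log2 units).
#' @param metabolome_noise_sd Residual SD of log2 intensities.
#' @param participant_sd SD of per-participant metabolite offsets (log2 units).
#' @param n_internal_standards Number of internal standards.
#' @param dry_weight_mean_mg,dry_weight_sd_mg Per-sample dry tissue weight, mg.
#' @param activity_day_jitter Relative day-level jitter on posture totals.
#' @param activity_cadence_jitter Relative jitter on per-bout cadence.
#' @param days_per_regimen Wear days simulated per regimen.
#'
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_participants = 12,
                          regimens = default_regimens(),
                          body_mass_mean = 79, body_mass_sd = 8,
                          rd_high_mean = c(SIT = 29.4, SL = 33.1, EXE = 35.2),
                          nogd_high_mean = c(SIT = 15.7, SL = 19.9, EXE = 22.3),
                          rd_between_sd = 2.5,
                          rd_within_sd = 1.75,
                          egp_basal_mean = 11, egp_basal_sd = 1,
                          suppression_low_mean = 0.55, suppression_low_sd = 0.08,
                          suppression_high = 0.90,
                          rd_low_factor = 1.2,
                          vo2_baseline_mean = 0.24, vo2_baseline_sd = 0.02,
                          rer_basal_mean = 0.78, rer_basal_sd = 0.015,
                          fat_ox_high_g_min = 0.03,
                          tracer_mg_kg_min = 0.04,
                          tracer_molar_mass = 182.0,
                          glucose_basal = 5.4, glucose_clamp = 5.2,
                          sample_interval_min = 5,
                          phase_minutes = c(basal = 180, low = 180, high = 150),
                          glucose_noise_sd = 0.04,
                          ttr_noise_cv = 0.01,
                          gas_noise_sd = 0.004,
                          n_metabolites = 138,
                          n_amino_like = 12,
                          shared_fraction = 0.3,
                          lambda = 0.3,
                          beta_sd = 0.5,
                          eta_sd = 0.25,
                          metabolome_noise_sd = 0.35,
                          participant_sd = 0.5,
                          n_internal_standards = 30,
                          dry_weight_mean_mg = 5, dry_weight_sd_mg = 0.5,
                          activity_day_jitter = 0.03,
                          activity_cadence_jitter = 0.02,
                          days_per_regimen = 4) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (n_metabolites < 1) stop("n_metabolites must be >= 1", call. = FALSE)
  if (lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1] (dose-like intermediacy)", call. = FALSE)
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  }
  sds <- c(body_mass_sd, rd_between_sd, rd_within_sd, egp_basal_sd,
           suppression_low_sd, glucose_noise_sd, ttr_noise_cv, gas_noise_sd,
           beta_sd, eta_sd, metabolome_noise_sd, participant_sd,
           dry_weight_sd_mg, activity_day_jitter, activity_cadence_jitter)
  if (any(sds < 0)) stop("all SDs / jitters must be >= 0", call. = FALSE)
  regimen_names <- names(regimens)
  stopifnot(all(regimen_names %in% names(rd_high_mean)),
            all(regimen_names %in% names(nogd_high_mean)))
  cfg <- as.list(environment())
  cfg$sds <- NULL
  structure(cfg, class = "cohort_config")
}

#' Tracer infusion rate in micromoles per kg per minute
#'
#' Converts the mass-based tracer infusion rate (mg kg-1 min-1) to molar
#' units using the tracer molar mass.
#'
#' @param cfg A [cohort_config()].
#' @return Tracer infusion rate, umol kg-1 min-1.
#' @export
tracer_umol_kg_min <- function(cfg) {
  cfg$tracer_mg_kg_min / cfg$tracer_molar_mass * 1000
}

# stage seeds derived from one master seed so stages are independently
# rerunnable. A double Lehmer scramble (multiplier 48271, modulus 2^31 - 1,
# exact in double precision) separates nearby master seeds, whose raw values
# would otherwise initialise the generator to correlated early states.
scramble_seed <- function(x) {
  as.integer((48271 * ((48271 * (x %% 2147483647)) %% 2147483647)) %%
               2147483647)
}

derive_seed <- function(seed, stage) {
  offsets <- c(profiles = 11, activity = 23, clamp = 37, gas = 53,
               metabolome = 71, misc = 89)
  scramble_seed(as.numeric(seed) + offsets[[stage]] * 1299709)
}
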