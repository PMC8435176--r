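#' Simulate a muscle-metabolome intensity matrix
#'
#' Generates raw metabolite intensities for a crossover cohort (metabolites x
#' participant-regimen samples) with the block structure the metabolomics
#' analyses assume. On the log2 scale each value is
#' `baseline + participant effect + beta_EXE * 1[EXE] + beta_SL * 1[SL] + noise`,
#' where a configured fraction of metabolites respond to the interventions
#' with `beta_SL = lambda * beta_EXE + eta` (dose-like intermediacy of the
#' sit-less regimen) and the rest are null; an amino-acid-like subset responds
#' negatively to exercise. Raw intensities additionally carry per-sample
#' internal-standard intensities and dry tissue weights, so the normalisation
#' step has real work to undo.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @return An object of class `metabolite_matrix`: a list with `raw`
#'   (metabolite x sample matrix), `samples` (sample sheet tibble with
#'   `sample_id`, `participant`, `regimen`, `dry_weight_mg`), `is_map`
#'   (metabolite -> internal-standard id), `is_intensities` (internal-standard
#'   x sample matrix), and `truth` (per-metabolite `beta_exe`, `beta_sl`,
#'   `amino_like`).
#' @export
generate_metabolome <- function(cfg, seed = 1L) {
  if (cfg$lambda < 0 || cfg$lambda > 1) {
    stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  m <- cfg$n_metabolites
  regs <- names(cfg$regimens)
  n <- cfg$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  samples <- tidyr::expand_grid(participant = ids, regimen = regs)
  samples$sample_id <- paste(samples$participant, samples$regimen, sep = "_")
  s <- nrow(samples)

  met_ids <- sprintf("met_%03d", seq_len(m))
  n_resp <- round(cfg$shared_fraction * m)
  responder <- seq_len(m) <= n_resp
  amino_like <- rep(FALSE, m)
  amino_like[seq_len(min(cfg$n_amino_like, n_resp))] <- TRUE

  beta_exe <- ifelse(responder, stats::rnorm(m, 0, cfg$beta_sd), 0)
  beta_exe[amino_like] <- -abs(beta_exe[amino_like])
  beta_sl <- ifelse(responder,
                    cfg$lambda * beta_exe + stats::rnorm(m, 0, cfg$eta_sd), 0)

  baseline <- stats::runif(m, 12, 20)
  part_eff <- matrix(stats::rnorm(m * n, 0, cfg$participant_sd), m, n,
                     dimnames = list(met_ids, ids))

  log2val <- matrix(baseline, m, s) +
    part_eff[, match(samples$participant, ids)] +
    outer(beta_exe, as.numeric(samples$regimen == "EXE")) +
    outer(beta_sl, as.numeric(samples$regimen == "SL")) +
    matrix(stats::rnorm(m * s, 0, cfg$metabolome_noise_sd), m, s)

  dry_weight <- pmax(1, stats::rnorm(s, cfg$dry_weight_mean_mg,
                                     cfg$dry_weight_sd_mg))
  n_is <- cfg$n_internal_standards
  is_ids <- sprintf("IS_%02d", seq_len(n_is))
  is_int <- matrix(1e5 * exp(stats::rnorm(n_is * s, 0, 0.1)), n_is, s,
                   dimnames = list(is_ids, samples$sample_id))
  is_map <- tibble::tibble(
    metabolite = met_ids,
    is_id = is_ids[(seq_len(m) - 1) %% n_is + 1]
  )

  raw <- 2^log2val *
    is_int[match(is_map$is_id, is_ids), , drop = FALSE] *
    matrix(dry_weight, m, s, byrow = TRUE)
  dimnames(raw) <- list(met_ids, samples$sample_id)

  samples$dry_weight_mg <- dry_weight
  structure(
    list(
      raw = raw,
      samples = samples[, c("sample_id", "participant", "regimen",
                            "dry_weight_mg")],
      is_map = is_map,
      is_intensities = is_int,
      truth = tibble::tibble(metabolite = met_ids, beta_exe = beta_exe,
                             beta_sl = beta_sl, amino_like = amino_like,
                             responder = responder)
    ),
    class = "metabolite_matrix"
  )
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d metabolites x %d samples (%d participants x %d regimens)\n",
              nrow(x$raw), ncol(x$raw),
              length(unique(x$samples$participant)),
              length(unique(x$samples$regimen))))
  invisible(x)
}
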