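#' Generate a full synthetic study cohort
#'
#' Draws participant profiles and, for every participant-regimen combination,
#' an activity event stream, a clamp time series and steady-state gas
#' exchange; one metabolome matrix covers the whole cohort. The generating
#' truth is kept alongside the data so downstream estimates can be checked
#' against it. Stage seeds are derived deterministically from the master
#' seed, so identical `(cfg, seed)` give identical bundles.
#'
#' @param cfg A [cohort_config()].
#' @param seed Master integer seed.
#' @return A list of class `study_cohort`: `config`, `seed`, `truth`
#'   (the [generate_profiles()] table), `activity` (named list of event
#'   tibbles per "participant.regimen"), `clamp` (named list of clamp series),
#'   `gas` (tibble of per-phase gas exchange for all participant-regimens)
#'   and `metabolome` (a `metabolite_matrix`).
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1L) {
  truth <- generate_profiles(cfg, derive_seed(seed, "profiles"))
  keys <- paste(truth$participant, truth$regimen, sep = ".")

  activity <- vector("list", nrow(truth))
  clamp <- vector("list", nrow(truth))
  gas <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    design <- cfg$regimens[[truth$regimen[i]]]
    activity[[i]] <- generate_activity_events(
      design, day_count = cfg$days_per_regimen,
      seed = scramble_seed(derive_seed(seed, "activity") + i),
      day_jitter = cfg$activity_day_jitter,
      cadence_jitter = cfg$activity_cadence_jitter
    )
    clamp[[i]] <- generate_clamp_timeseries(
      truth[i, ], cfg, seed = scramble_seed(derive_seed(seed, "clamp") + i)
    )
    g <- generate_gas_exchange(
      truth[i, ], cfg, seed = scramble_seed(derive_seed(seed, "gas") + i))
    g$participant <- truth$participant[i]
    g$regimen <- truth$regimen[i]
    gas[[i]] <- g
  }
  names(activity) <- keys
  names(clamp) <- keys

  structure(
    list(
      config = cfg,
      seed = as.integer(seed),
      truth = truth,
      activity = activity,
      clamp = clamp,
      gas = dplyr::bind_rows(gas),
      metabolome = generate_metabolome(cfg, derive_seed(seed, "metabolome"))
    ),
    class = "study_cohort"
  )
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("<study_cohort> %d participants x %d regimens (seed %d)\n",
              x$config$n_participants, length(x$config$regimens), x$seed))
  invisible(x)
}
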