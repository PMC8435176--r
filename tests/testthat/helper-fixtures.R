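# shared fixture builders for the test suite

# one tiling day of hand-built events
make_day <- function(postures, hours, steps = NULL,
                     date = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  if (is.null(steps)) steps <- rep(0L, length(postures))
  dur <- hours * 3600
  tibble::tibble(
    event_start = date + c(0, cumsum(dur[-length(dur)])),
    posture = postures,
    duration_s = dur,
    step_count = as.integer(steps)
  )
}

# steady-state clamp series: constant glucose, TTR and infusions
make_steady_series <- function(f = 0.8, z = 0.02, glucose = 5.0, gir = 0,
                               phase = "basal", times = seq(0, 60, by = 5)) {
  tibble::tibble(
    time_min = times,
    phase = phase,
    glucose_mmol_l = glucose,
    ttr = z,
    tracer_umol_kg_min = f,
    gir_umol_kg_min = gir
  )
}

# small metabolome-like object built by hand (no generator involved)
make_tiny_metabolome <- function(log2vals, participants, regimens) {
  s <- length(participants)
  sample_id <- paste(participants, regimens, sep = "_")
  m <- nrow(log2vals)
  met_ids <- sprintf("met_%03d", seq_len(m))
  dimnames(log2vals) <- list(met_ids, sample_id)
  is_int <- matrix(1, 1, s, dimnames = list("IS_01", sample_id))
  list(
    raw = 2^log2vals,
    samples = tibble::tibble(sample_id = sample_id,
                             participant = participants,
                             regimen = regimens,
                             dry_weight_mg = rep(1, s)),
    is_map = tibble::tibble(metabolite = met_ids, is_id = "IS_01"),
    is_intensities = is_int,
    truth = NULL
  )
}

# long outcome table from a participant x regimen matrix
make_outcome_table <- function(m) {
  tibble::tibble(
    participant = rep(rownames(m), ncol(m)),
    regimen = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
}
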