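# split a duration into n bouts with mildly jittered proportions
split_bouts <- function(total_min, approx_bout_min, jitter) {
  if (total_min <= 0) return(numeric(0))
  n <- max(1L, round(total_min / approx_bout_min))
  w <- pmax(0.2, 1 + stats::rnorm(n, 0, jitter))
  total_min * w / sum(w)
}

#' Simulate an activPAL-style posture event stream
#'
#' Generates timestamped posture bouts (sedentary incl. sleep, standing,
#' stepping, cycling) that tile each 24 h day without gaps or overlaps,
#' following a prescribed regimen. Daily posture totals are jittered by a
#' truncated-normal day-level factor and renormalised so every day still sums
#' to exactly 24 h; stepping bouts carry step counts at the regimen cadence
#' with per-bout cadence jitter.
#'
#' @param design A [regimen_design()].
#' @param day_count Number of days to simulate.
#' @param seed Integer seed.
#' @param day_jitter Relative SD of day-level posture-total jitter
#'   (0 reproduces the design hours exactly).
#' @param cadence_jitter Relative SD of per-bout cadence jitter.
#' @param start_date First day (Date).
#' @return A tibble of events with columns `event_start` (POSIXct, UTC),
#'   `posture` (sedentary/standing/stepping/cycling), `duration_s` and
#'   `step_count` (0 unless stepping). Sleep occupies the first block of each
#'   day as sedentary time; diary-style sleep intervals are attached as
#'   attribute `"sleep_intervals"`.
#' @examples
#' ev <- generate_activity_events(default_regimens()$SL, day_count = 1,
#'                                seed = 1, day_jitter = 0)
#' sum(ev$step_count)  # 3 h/day stepping at 94 steps/min -> 16,920 steps
#' @export
generate_activity_events <- function(design, day_count = 4, seed = 1L,
                                     day_jitter = 0.03, cadence_jitter = 0.02,
                                     start_date = as.Date("2024-01-01")) {
  stopifnot(inherits(design, "regimen_design"))
  set.seed(seed)
  days <- vector("list", day_count)
  sleep_iv <- vector("list", day_count)
  for (d in seq_len(day_count)) {
    base <- c(sleep = design$hours_sleep, sit = design$hours_sit,
              stand = design$hours_stand, walk = design$hours_walk,
              cycle = design$hours_exercise)
    jit <- pmin(2, pmax(0.25, 1 + stats::rnorm(5, 0, day_jitter)))
    jit[base == 0] <- 1
    hrs <- base * jit
    hrs <- hrs * 24 / sum(hrs)  # renormalise: the day must still sum to 24 h

    sleep_min <- hrs[["sleep"]] * 60
    sit_bouts <- split_bouts(hrs[["sit"]] * 60, 45, day_jitter)
    stand_bouts <- split_bouts(hrs[["stand"]] * 60, 15, day_jitter)
    walk_bouts <- split_bouts(hrs[["walk"]] * 60, 10, day_jitter)
    cycle_bouts <- split_bouts(hrs[["cycle"]] * 60, 60, day_jitter)

    # interleave waking bouts in a round-robin over the available postures so
    # the day looks like alternating activity, then append in that order
    pool <- list(sedentary = sit_bouts, standing = stand_bouts,
                 stepping = walk_bouts, cycling = cycle_bouts)
    idx <- lapply(pool, seq_along)
    order_post <- character(0)
    order_dur <- numeric(0)
    ptr <- c(sedentary = 1L, standing = 1L, stepping = 1L, cycling = 1L)
    remaining <- vapply(pool, length, integer(1))
    while (any(remaining > 0)) {
      for (p in names(pool)) {
        if (ptr[[p]] <= length(pool[[p]])) {
          order_post <- c(order_post, p)
          order_dur <- c(order_dur, pool[[p]][ptr[[p]]])
          ptr[[p]] <- ptr[[p]] + 1L
          remaining[[p]] <- remaining[[p]] - 1L
        }
      }
    }

    posture <- c("sedentary", order_post)
    dur_min <- c(sleep_min, order_dur)
    day_start <- as.POSIXct(paste(start_date + (d - 1), "00:00:00"), tz = "UTC")
    starts <- day_start + c(0, cumsum(dur_min[-length(dur_min)])) * 60

    cad <- ifelse(posture == "stepping",
                  design$walk_cadence *
                    pmax(0.5, 1 + stats::rnorm(length(posture), 0, cadence_jitter)),
                  0)
    steps <- ifelse(posture == "stepping", round(dur_min * cad), 0)

    days[[d]] <- tibble::tibble(
      event_start = starts,
      posture = posture,
      duration_s = dur_min * 60,
      step_count = as.integer(steps)
    )
    sleep_iv[[d]] <- tibble::tibble(
      sleep_start = day_start,
      sleep_end = day_start + sleep_min * 60
    )
  }
  out <- dplyr::bind_rows(days)
  attr(out, "sleep_intervals") <- dplyr::bind_rows(sleep_iv)
  out
}
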