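#' Define an activity regimen
#'
#' A regimen prescribes how the 24 h day is divided between sleeping,
#' sitting, standing, walking and (for the exercise arm) supervised cycling,
#' together with the walking cadence and the metabolic intensity of the
#' exercise session.
#'
#' @param name Regimen label, one of `"SIT"`, `"SL"`, `"EXE"` (free labels are
#'   allowed for custom designs).
#' @param hours_sleep,hours_sit,hours_stand,hours_walk,hours_exercise Hours per
#'   day spent in each behaviour. Must be non-negative and sum to 24.
#' @param walk_cadence Walking cadence in steps/min while stepping.
#' @param exercise_met Metabolic intensity of the exercise session in METs
#'   (1 MET = resting oxygen uptake of 3.5 ml kg-1 min-1). Ignored when
#'   `hours_exercise` is 0.
#'
#' @return An object of class `regimen_design` (a named list).
#' @examples
#' regimen_design("SIT", 8, 14, 1, 1, 0, walk_cadence = 85)
#' @export
regimen_design <- function(name, hours_sleep, hours_sit, hours_stand,
                           hours_walk, hours_exercise = 0,
                           walk_cadence = 90, exercise_met = 4.60) {
  hours <- c(hours_sleep, hours_sit, hours_stand, hours_walk, hours_exercise)
  if (any(hours < 0)) {
    stop("regimen hours must all be non-negative", call. = FALSE)
  }
  if (abs(sum(hours) - 24) > 1e-8) {
    stop(sprintf("regimen hours must sum to 24 h/day (got %.4f)", sum(hours)),
         call. = FALSE)
  }
  if (walk_cadence <= 0) stop("walk_cadence must be > 0", call. = FALSE)
  structure(
    list(
      name = as.character(name),
      hours_sleep = hours_sleep,
      hours_sit = hours_sit,
      hours_stand = hours_stand,
      hours_walk = hours_walk,
      hours_exercise = hours_exercise,
      walk_cadence = walk_cadence,
      exercise_met = exercise_met
    ),
    class = "regimen_design"
  )
}

#' Default study regimens
#'
#' The three prescribed regimens of the crossover design: sitting (SIT),
#' sitting less (SL) and exercise (EXE). Cadences and the exercise intensity
#' are the measured study means (SIT 85, SL 94, EXE 86 steps/min; cycling at
#' 4.60 MET).
#'
#' @return Named list of [regimen_design()] objects.
#' @export
default_regimens <- function() {
  list(
    SIT = regimen_design("SIT", hours_sleep = 8, hours_sit = 14,
                         hours_stand = 1, hours_walk = 1, hours_exercise = 0,
                         walk_cadence = 85),
    SL  = regimen_design("SL", hours_sleep = 8, hours_sit = 9,
                         hours_stand = 4, hours_walk = 3, hours_exercise = 0,
                         walk_cadence = 94),
    EXE = regimen_design("EXE", hours_sleep = 8, hours_sit = 13,
                         hours_stand = 1, hours_walk = 1, hours_exercise = 1,
                         walk_cadence = 86, exercise_met = 4.60)
  )
}

#' @export
print.regimen_design <- function(x, ...) {
  cat(sprintf(
    "<regimen_design> %s: sleep %.1f h, sit %.1f h, stand %.1f h, walk %.1f h (%.0f steps/min), exercise %.1f h",
    x$name, x$hours_sleep, x$hours_sit, x$hours_stand, x$hours_walk,
    x$walk_cadence, x$hours_exercise))
  if (x$hours_exercise > 0) cat(sprintf(" @ %.2f MET", x$exercise_met))
  cat("\n")
  invisible(x)
}
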