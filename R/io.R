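#' Read and write the package's file dialects
#'
#' Activity events travel as CSV with columns `event_start_iso8601`,
#' `posture`, `duration_s`, `step_count`; clamp series as CSV with
#' `time_min`, `phase`, `glucose_mmol_l`, `ttr`, `tracer_umol_kg_min`,
#' `gir_umol_kg_min`; the metabolome as a TSV intensity matrix (metabolites x
#' samples) plus a sample sheet TSV (`sample_id`, `participant`, `regimen`,
#' `dry_weight_mg`) and an internal-standard map TSV (`metabolite`, `is_id`)
#' with the internal-standard intensity matrix alongside.
#'
#' @param events,series Tibbles in the shapes produced by
#'   [generate_activity_events()] / [generate_clamp_timeseries()].
#' @param path,dir File or directory paths.
#' @param mm A `metabolite_matrix`.
#' @name sitless-io
NULL

#' @rdname sitless-io
#' @export
write_activity_csv <- function(events, path) {
  out <- tibble::tibble(
    event_start_iso8601 = format(events$event_start, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
    posture = events$posture,
    duration_s = events$duration_s,
    step_count = events$step_count
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname sitless-io
#' @export
read_activity_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    event_start = as.POSIXct(raw$event_start_iso8601,
                             format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    posture = raw$posture,
    duration_s = raw$duration_s,
    step_count = as.integer(raw$step_count)
  )
}

#' @rdname sitless-io
#' @export
write_clamp_csv <- function(series, path) {
  readr::write_csv(series[c("time_min", "phase", "glucose_mmol_l", "ttr",
                            "tracer_umol_kg_min", "gir_umol_kg_min")], path)
  invisible(path)
}

#' @rdname sitless-io
#' @export
read_clamp_csv <- function(path) {
  series <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("time_min", "phase", "glucose_mmol_l", "ttr",
              "tracer_umol_kg_min", "gir_umol_kg_min")
  missing <- setdiff(needed, names(series))
  if (length(missing) > 0) {
    stop(sprintf("clamp CSV %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  series
}

#' @rdname sitless-io
#' @export
write_metabolome_tsv <- function(mm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raw <- tibble::as_tibble(mm$raw, rownames = "metabolite")
  readr::write_tsv(raw, file.path(dir, "intensities.tsv"))
  readr::write_tsv(mm$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(mm$is_map, file.path(dir, "is_map.tsv"))
  is_int <- tibble::as_tibble(mm$is_intensities, rownames = "is_id")
  readr::write_tsv(is_int, file.path(dir, "is_intensities.tsv"))
  invisible(dir)
}

#' @rdname sitless-io
#' @export
read_metabolome_tsv <- function(dir) {
  as_mat <- function(df, key) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[key]]
    m
  }
  raw <- readr::read_tsv(file.path(dir, "intensities.tsv"),
                         show_col_types = FALSE)
  is_int <- readr::read_tsv(file.path(dir, "is_intensities.tsv"),
                            show_col_types = FALSE)
  structure(
    list(
      raw = as_mat(raw, "metabolite"),
      samples = readr::read_tsv(file.path(dir, "samples.tsv"),
                                show_col_types = FALSE),
      is_map = readr::read_tsv(file.path(dir, "is_map.tsv"),
                               show_col_types = FALSE),
      is_intensities = as_mat(is_int, "is_id"),
      truth = NULL
    ),
    class = "metabolite_matrix"
  )
}
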