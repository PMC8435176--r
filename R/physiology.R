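#' Indirect-calorimetry substrate oxidation and energy expenditure
#'
#' Converts steady-state gas exchange into whole-body substrate oxidation and
#' energy expenditure, assuming negligible protein oxidation:
#' carbohydrate oxidation `4.55 VCO2 - 3.21 VO2` g/min, fat oxidation
#' `1.67 (VO2 - VCO2)` g/min (Frayn-type stoichiometry), energy expenditure
#' `(3.941 VO2 + 1.106 VCO2) * 4.184` kJ/min (Weir-type), and RER
#' `VCO2 / VO2`. When `body_mass` is supplied, carbohydrate oxidation is also
#' expressed in umol kg-1 min-1 (glucose molar mass 180.16 g/mol) for use in
#' non-oxidative glucose disposal. Negative oxidation rates are reported
#' as-is and flagged.
#'
#' @param vo2,vco2 Oxygen uptake and carbon dioxide production, l/min
#'   (vectors of equal length).
#' @param body_mass Optional body mass, kg.
#' @return A tibble: `rer`, `cho_ox_g_min`, `fat_ox_g_min`, `ee_kj_min`,
#'   `cho_ox_umol_kg_min` (NA without body mass) and `flag` (TRUE when any
#'   oxidation rate is negative).
#' @examples
#' substrate_oxidation(0.25, 0.20, body_mass = 79)
#' @export
substrate_oxidation <- function(vo2, vco2, body_mass = NULL) {
  if (any(vo2 <= 0)) stop("vo2 must be > 0", call. = FALSE)
  if (any(vco2 <= 0)) stop("vco2 must be > 0", call. = FALSE)
  cho_g <- 4.55 * vco2 - 3.21 * vo2
  fat_g <- 1.67 * (vo2 - vco2)
  ee <- (3.941 * vo2 + 1.106 * vco2) * 4.184
  cho_umol <- if (!is.null(body_mass)) {
    cho_g * 1e6 / (180.16 * body_mass)
  } else {
    NA_real_
  }
  flag <- cho_g < 0 | fat_g < 0
  if (any(flag)) {
    warning("negative oxidation rate(s); reported as-is", call. = FALSE)
  }
  tibble::tibble(
    rer = vco2 / vo2,
    cho_ox_g_min = cho_g,
    fat_ox_g_min = fat_g,
    ee_kj_min = ee,
    cho_ox_umol_kg_min = cho_umol,
    flag = flag
  )
}

#' Cytochrome-c quality control for respirometry traces
#'
#' A respiration increase after cytochrome-c addition indicates disrupted
#' integrity of the outer mitochondrial membrane; traces with a cytochrome-c
#' response strictly above the threshold (default 15%) are excluded. The
#' response is `(post - pre) / pre`.
#'
#' @param pre,post State respiration before and after cytochrome-c addition,
#'   pmol mg-1 s-1 (vectors of equal length; one element per trace).
#' @param threshold Exclusion threshold on the fractional response
#'   (default 0.15; a response of exactly 15% is kept).
#' @return A tibble: `response` (fraction) and `keep` (logical).
#' @examples
#' respirometry_qc(pre = c(10, 10), post = c(12, 10))
#' @export
respirometry_qc <- function(pre, post, threshold = 0.15) {
  if (any(pre <= 0)) stop("pre-cytochrome-c respiration must be > 0",
                          call. = FALSE)
  if (any(post < 0)) stop("respiration must be >= 0", call. = FALSE)
  response <- (post - pre) / pre
  tibble::tibble(response = response, keep = response <= threshold)
}

#' Aggregate replicate respirometry traces
#'
#' Applies [respirometry_qc()] to replicate traces (the study protocol runs
#' quadruplicates) and returns the mean respiration over the kept traces.
#'
#' @param traces Tibble with columns `respiration`, `pre_cytc`, `post_cytc`
#'   (one row per replicate trace).
#' @inheritParams respirometry_qc
#' @return A one-row tibble: `respiration` (mean of kept traces, NA when all
#'   are excluded), `n_kept`, `n_total`.
#' @export
aggregate_respirometry <- function(traces, threshold = 0.15) {
  qc <- respirometry_qc(traces$pre_cytc, traces$post_cytc, threshold)
  kept <- traces$respiration[qc$keep]
  tibble::tibble(
    respiration = if (length(kept) > 0) mean(kept) else NA_real_,
    n_kept = length(kept),
    n_total = nrow(traces)
  )
}
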