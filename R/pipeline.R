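with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

mean_se <- function(x) {
  x <- x[is.finite(x)]
  tibble::tibble(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
                 n = length(x))
}

load_config <- function(config) {
  if (is.null(config)) return(cohort_config())
  if (inherits(config, "cohort_config")) return(config)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    lst <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    return(do.call(cohort_config, lst))
  }
  if (is.list(config)) return(do.call(cohort_config, config))
  stop("unsupported config", call. = FALSE)
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> activity -> clamp -> calorimetry -> metabolome ->
#' statistics and assembles a report: per-regimen means +/- SE for Rd, NOGD,
#' EGP suppression, basal RER, steps/day and MET.h/day; omnibus crossover
#' tests; the signature concordance; the top-25 VIP metabolites; and a
#' truth-versus-estimate recovery table. Any stage failure aborts with the
#' stage name.
#'
#' @param config A [cohort_config()], a plain list of its arguments, a path
#'   to a YAML/JSON file of them, or NULL for defaults.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional output directory; when given, report tables, the
#'   metabolome matrices and a JSON run manifest are written there.
#' @return A list of class `study_report`: `manifest`, `regimen_summary`,
#'   `participant_outcomes`, `omnibus`, `effects`, `concordance`,
#'   `top_vip`, `exemplars`, `recovery`, `cohort`.
#' @export
run_study <- function(config = NULL, seed = 1L, out_dir = NULL) {
  cfg <- with_stage("config", load_config(config))
  cohort <- with_stage("simulate", generate_cohort(cfg, seed))
  kcfg <- kinetics_config()

  activity_summary <- with_stage("activity", {
    rows <- lapply(names(cohort$activity), function(key) {
      ev <- cohort$activity[[key]]
      days <- summarize_days(ev, sleep_diary = attr(ev, "sleep_intervals"))
      pr <- strsplit(key, ".", fixed = TRUE)[[1]]
      design <- cfg$regimens[[pr[2]]]
      days$met_hours <- estimate_met_hours(
        days, met_model(exercise_met = design$exercise_met))
      tibble::tibble(
        participant = pr[1], regimen = pr[2],
        steps = mean(days$steps),
        cadence = stats::weighted.mean(days$cadence,
                                       days$hours_stepping, na.rm = TRUE),
        hours_sedentary = mean(days$hours_sedentary),
        hours_standing = mean(days$hours_standing),
        hours_stepping = mean(days$hours_stepping),
        hours_cycling = mean(days$hours_cycling),
        hours_sleep = mean(days$hours_sleep),
        met_hours = mean(days$met_hours)
      )
    })
    dplyr::bind_rows(rows)
  })

  clamp_summary <- with_stage("clamp", {
    rows <- lapply(names(cohort$clamp), function(key) {
      series <- cohort$clamp[[key]]
      pr <- strsplit(key, ".", fixed = TRUE)[[1]]
      fx <- clamp_fluxes(series, kcfg)
      tibble::tibble(
        participant = pr[1], regimen = pr[2],
        egp_basal = fx$egp[fx$phase == "basal"],
        egp_low = fx$egp[fx$phase == "low"],
        rd_high = fx$rd[fx$phase == "high"],
        glucose_cv_high = fx$glucose_cv[fx$phase == "high"]
      )
    })
    out <- dplyr::bind_rows(rows)
    out$suppression_pct <- egp_suppression(out$egp_basal, out$egp_low)
    out
  })

  calorimetry <- with_stage("calorimetry", {
    truth_mass <- cohort$truth[c("participant", "regimen", "body_mass")]
    gas <- dplyr::left_join(cohort$gas, truth_mass,
                            by = c("participant", "regimen"))
    ox <- substrate_oxidation(gas$vo2_l_min, gas$vco2_l_min)
    ox$cho_ox_umol_kg_min <- ox$cho_ox_g_min * 1e6 / (180.16 * gas$body_mass)
    dplyr::bind_cols(gas[c("participant", "regimen", "phase")], ox)
  })

  outcomes <- with_stage("outcomes", {
    cho_high <- calorimetry[calorimetry$phase == "high",
                            c("participant", "regimen", "cho_ox_umol_kg_min")]
    rer_basal <- calorimetry[calorimetry$phase == "basal",
                             c("participant", "regimen", "rer")]
    out <- dplyr::left_join(clamp_summary, cho_high,
                            by = c("participant", "regimen"))
    out <- dplyr::left_join(out, rer_basal, by = c("participant", "regimen"))
    out$nogd_high <- compute_nogd(out$rd_high, out$cho_ox_umol_kg_min)
    dplyr::left_join(out,
                     activity_summary[c("participant", "regimen", "steps",
                                        "met_hours")],
                     by = c("participant", "regimen"))
  })

  metabolome <- with_stage("metabolome", {
    normed <- normalize_metabolome(cohort$metabolome)
    effects <- fit_effects(normed)
    model <- plsda(normed, ncomp = 2)
    conc <- signature_concordance(effects)
    list(normed = normed, effects = effects, model = model,
         concordance = conc,
         top_vip = names(sort(-model$vip)[1:min(25, length(model$vip))]),
         heatmap = rank_heatmap(model, normed,
                                k = min(25, length(model$vip))),
         exemplars = select_exemplars(conc, 10))
  })

  omnibus <- with_stage("stats", {
    one <- function(var) {
      tab <- tibble::tibble(participant = outcomes$participant,
                            regimen = outcomes$regimen,
                            value = outcomes[[var]])
      cbind(outcome = var, rm_anova(tab),
            tibble::tibble(posthoc = list(bonferroni_posthoc(tab))))
    }
    dplyr::bind_rows(lapply(c("rd_high", "nogd_high", "suppression_pct",
                              "steps", "met_hours"), one))
  })

  regimen_summary <- with_stage("report", {
    vars <- c("rd_high", "nogd_high", "suppression_pct", "rer", "steps",
              "met_hours")
    rows <- lapply(vars, function(v) {
      out <- dplyr::group_by(outcomes, .data$regimen)
      out <- dplyr::summarise(out, mean_se(.data[[v]]), .groups = "drop")
      out$outcome <- v
      out
    })
    dplyr::bind_rows(rows)[, c("outcome", "regimen", "mean", "se", "n")]
  })

  recovery <- with_stage("report", {
    truth_means <- dplyr::summarise(
      dplyr::group_by(cohort$truth, .data$regimen),
      true_rd_high = mean(.data$true_rd_high),
      true_nogd_high = mean(.data$true_nogd_high),
      true_egp_basal = mean(.data$true_egp_basal),
      .groups = "drop")
    est_means <- dplyr::summarise(
      dplyr::group_by(outcomes, .data$regimen),
      est_rd_high = mean(.data$rd_high),
      est_nogd_high = mean(.data$nogd_high),
      est_egp_basal = mean(.data$egp_basal),
      .groups = "drop")
    dplyr::left_join(truth_means, est_means, by = "regimen")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("sitless")),
    seed = as.integer(seed),
    config_hash = rlang::hash(cfg),
    n_participants = cfg$n_participants,
    qc = list(
      metabolome_imputed = metabolome$normed$n_imputed,
      metabolome_flagged_samples = metabolome$normed$flagged_samples,
      clamp_max_glucose_cv = max(clamp_summary$glucose_cv_high)
    ),
    outputs = character(0)
  )

  report <- structure(
    list(manifest = manifest,
         regimen_summary = regimen_summary,
         participant_outcomes = outcomes,
         omnibus = omnibus,
         effects = metabolome$effects,
         concordance = metabolome$concordance,
         top_vip = metabolome$top_vip,
         heatmap = metabolome$heatmap,
         exemplars = metabolome$exemplars,
         recovery = recovery,
         cohort = cohort),
    class = "study_report"
  )

  if (!is.null(out_dir)) {
    with_stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- c(
        regimen_summary = "regimen_summary.tsv",
        participant_outcomes = "participant_outcomes.tsv",
        recovery = "recovery.tsv"
      )
      for (nm in names(files)) {
        readr::write_tsv(report[[nm]], file.path(out_dir, files[[nm]]))
      }
      readr::write_tsv(metabolome$effects, file.path(out_dir, "effects.tsv"))
      readr::write_tsv(
        tibble::tibble(metabolite = names(metabolome$model$vip),
                       vip = unname(metabolome$model$vip)),
        file.path(out_dir, "vip.tsv"))
      readr::write_tsv(metabolome$concordance$scores,
                       file.path(out_dir, "concordance.tsv"))
      readr::write_tsv(
        tibble::as_tibble(metabolome$heatmap, rownames = "metabolite"),
        file.path(out_dir, "heatmap_matrix.tsv"))
      write_metabolome_tsv(cohort$metabolome, file.path(out_dir, "metabolome"))
      report$manifest$outputs <- c(unname(files), "effects.tsv", "vip.tsv",
                                   "concordance.tsv", "heatmap_matrix.tsv",
                                   "metabolome/")
      jsonlite::write_json(report$manifest,
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d, %d participants\n",
              x$manifest$seed, x$manifest$n_participants))
  cat("\nRegimen summary (mean +/- SE):\n")
  df <- as.data.frame(x$regimen_summary)
  df$mean <- format(signif(df$mean, 4), scientific = FALSE, trim = TRUE)
  df$se <- format(signif(df$se, 3), scientific = FALSE, trim = TRUE)
  print(df, row.names = FALSE)
  cat(sprintf("\nSignature concordance (EXE-SIT vs SL-SIT): r = %.3f, p = %.2g\n",
              x$concordance$r, x$concordance$p))
  cat(sprintf("Top VIP metabolites: %s ...\n",
              paste(utils::head(x$top_vip, 5), collapse = ", ")))
  invisible(x)
}
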