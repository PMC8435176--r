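# complete-case wide matrix (participants x regimens) from a long outcome table
outcome_matrix <- function(table) {
  stopifnot(all(c("participant", "regimen", "value") %in% names(table)))
  wide <- tidyr::pivot_wider(table[c("participant", "regimen", "value")],
                             names_from = "regimen", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) {
    stop("need >= 3 participants with complete data across regimens",
         call. = FALSE)
  }
  m
}

#' One-way repeated-measures ANOVA for a crossover outcome
#'
#' Within-subject ANOVA with participant as block (listwise deletion of
#' participants with missing regimen values), as used for parametric
#' crossover outcomes. No sphericity correction is applied by default;
#' Greenhouse-Geisser is available behind a flag.
#'
#' @param table Long tibble with columns `participant`, `regimen`, `value`.
#' @param gg Apply the Greenhouse-Geisser epsilon correction to the degrees
#'   of freedom (default FALSE).
#' @return A one-row tibble: `f`, `df1`, `df2`, `p`, `n` (complete
#'   participants), and `epsilon` (1 unless `gg`).
#' @export
rm_anova <- function(table, gg = FALSE) {
  m <- outcome_matrix(table)
  n <- nrow(m); k <- ncol(m)
  # balanced within-subject decomposition (equivalent to aov with
  # participant as block, but robust to the all-tied degenerate case)
  grand <- mean(m)
  ss_reg <- n * sum((colMeans(m) - grand)^2)
  ss_part <- k * sum((rowMeans(m) - grand)^2)
  ss_err <- max(0, sum((m - grand)^2) - ss_reg - ss_part)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- (ss_reg / df1) / (ss_err / df2)
  eps <- 1
  if (gg) {
    # Greenhouse-Geisser epsilon from the double-centred covariance matrix
    s <- stats::cov(m)
    sc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) +
      mean(s)
    eps <- sum(diag(sc))^2 / ((k - 1) * sum(sc^2))
    eps <- min(1, max(1 / (k - 1), eps))
  }
  p <- stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  if (!is.finite(f)) { f <- 0; p <- 1 }  # identical values across regimens
  tibble::tibble(f = f, df1 = df1, df2 = df2, p = p, n = n, epsilon = eps)
}

#' Bonferroni-corrected paired post hoc tests
#'
#' All pairwise paired t tests between regimens, with p values multiplied by
#' the number of comparisons and capped at 1.
#'
#' @inheritParams rm_anova
#' @return A tibble with one row per regimen pair: `contrast`, `mean_diff`,
#'   `t`, `df`, `p_raw`, `p_adj`.
#' @export
bonferroni_posthoc <- function(table) {
  m <- outcome_matrix(table)
  pairs <- utils::combn(colnames(m), 2, simplify = FALSE)
  n_comp <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    tt <- stats::t.test(m[, pr[2]], m[, pr[1]], paired = TRUE)
    tibble::tibble(
      contrast = paste(pr[2], pr[1], sep = "-"),
      mean_diff = unname(tt$estimate),
      t = unname(tt$statistic),
      df = unname(tt$parameter),
      p_raw = tt$p.value,
      p_adj = min(1, tt$p.value * n_comp)
    )
  })
  dplyr::bind_rows(rows)
}

#' Friedman test for a crossover outcome
#'
#' Rank-based omnibus test over regimens with participant as block (the
#' non-parametric counterpart of [rm_anova()]); ties are handled by average
#' ranks with the standard tie correction. Degenerate tables in which every
#' participant's values are identical across regimens are flagged and return
#' a zero statistic.
#'
#' @inheritParams rm_anova
#' @return A one-row tibble: `chisq`, `df`, `p`, `n`, `degenerate`.
#' @export
friedman_crossover <- function(table) {
  m <- outcome_matrix(table)
  degenerate <- all(apply(m, 1, function(r) length(unique(r)) == 1))
  if (degenerate) {
    warning("all within-participant values tied; Friedman statistic is 0",
            call. = FALSE)
    return(tibble::tibble(chisq = 0, df = ncol(m) - 1, p = 1, n = nrow(m),
                          degenerate = TRUE))
  }
  ft <- stats::friedman.test(m)
  tibble::tibble(
    chisq = unname(ft$statistic),
    df = unname(ft$parameter),
    p = ft$p.value,
    n = nrow(m),
    degenerate = FALSE
  )
}

#' Dunn's post hoc tests on Friedman ranks
#'
#' Pairwise z tests on within-participant mean ranks,
#' `z = (Rbar_a - Rbar_b) / sqrt(k (k + 1) / (6 n))`, with the multiplicity
#' adjustment multiplying each p value by the number of comparisons (capped
#' at 1). Ties receive average ranks.
#'
#' @inheritParams rm_anova
#' @return A tibble with one row per regimen pair: `contrast`,
#'   `mean_rank_diff`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_posthoc <- function(table) {
  m <- outcome_matrix(table)
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(colnames(m), 2, simplify = FALSE)
  n_comp <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    z <- (rbar[pr[2]] - rbar[pr[1]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(
      contrast = paste(pr[2], pr[1], sep = "-"),
      mean_rank_diff = unname(rbar[pr[2]] - rbar[pr[1]]),
      z = unname(z),
      p_raw = p,
      p_adj = min(1, p * n_comp)
    )
  })
  dplyr::bind_rows(rows)
}

#' Paired-t sample size with Bonferroni-corrected alpha
#'
#' Smallest n such that a two-sided paired t test at significance level
#' `alpha / n_comparisons` reaches the target power for a true mean
#' difference `delta`, given the within-person SD of paired differences.
#' Power uses the noncentral t distribution with noncentrality
#' `sqrt(n) * delta / sd_diff` and the central-t critical value at n - 1
#' degrees of freedom.
#'
#' @param sd_diff Within-person SD of paired differences.
#' @param delta Detectable mean difference (same units).
#' @param alpha Family-wise two-sided significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 3, the three regimen
#'   pairs).
#' @param power Target power (default 0.8).
#' @param n_max Search cap.
#' @return A one-row tibble: `n`, `power_achieved`, `alpha_adjusted`.
#' @export
paired_t_sample_size <- function(sd_diff, delta, alpha = 0.05,
                                 n_comparisons = 3, power = 0.8,
                                 n_max = 10000) {
  if (sd_diff <= 0 || delta <= 0) {
    stop("sd_diff and delta must be positive", call. = FALSE)
  }
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)", call. = FALSE)
  a <- alpha / n_comparisons
  pow <- function(n) {
    ncp <- sqrt(n) * delta / sd_diff
    tcrit <- stats::qt(1 - a / 2, df = n - 1)
    stats::pt(tcrit, df = n - 1, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df = n - 1, ncp = ncp)
  }
  for (n in 2:n_max) {
    if (pow(n) >= power) {
      return(tibble::tibble(n = n, power_achieved = pow(n),
                            alpha_adjusted = a))
    }
  }
  stop("no n <= n_max reaches the target power", call. = FALSE)
}
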