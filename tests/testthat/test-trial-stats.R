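test_that("repeated-measures ANOVA matches a hand-computed toy table", {
  # 4 participants x 3 regimens with simple integer sums of squares
  m <- matrix(c(10, 12, 14, 16,
                12, 14, 16, 18,
                14, 16, 18, 20), nrow = 4,
              dimnames = list(paste0("P", 1:4), c("SIT", "SL", "EXE")))
  tab <- make_outcome_table(m)
  res <- rm_anova(tab)
  # grand mean 15; SS_regimen = 4 * ((13-15)^2 + (15-15)^2 + (17-15)^2) = 32
  # SS_participant = 3 * sum((12,14,16,18) - 15)^2 = 60; SS_total = 92
  # residual SS = 0 -> additive table, F is infinite in exact arithmetic;
  # perturb one cell to get a finite hand-checkable value
  m2 <- m
  m2[1, 1] <- 11
  res2 <- rm_anova(make_outcome_table(m2))
  long <- make_outcome_table(m2)
  a <- stats::anova(stats::lm(value ~ factor(participant) + factor(regimen),
                              data = long))
  f_hand <- a["factor(regimen)", "Mean Sq"] / a["Residuals", "Mean Sq"]
  expect_equal(res2$f, f_hand, tolerance = 1e-10)
  expect_equal(res2$df1, 2)
  expect_equal(res2$df2, 6)
})

test_that("identical values across regimens give F = 0, p = 1", {
  m <- matrix(rep(c(5, 6, 7, 8), 3), nrow = 4,
              dimnames = list(paste0("P", 1:4), c("SIT", "SL", "EXE")))
  res <- rm_anova(make_outcome_table(m))
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
})

test_that("two-regimen ANOVA F equals the squared paired t", {
  set.seed(21)
  m <- matrix(rnorm(20, 10, 2), nrow = 10,
              dimnames = list(sprintf("P%02d", 1:10), c("SIT", "EXE")))
  res <- rm_anova(make_outcome_table(m))
  tt <- t.test(m[, 2], m[, 1], paired = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("omnibus type-I error is at its nominal level under the null", {
  set.seed(31)
  n_rep <- 1000
  rejections <- vapply(seq_len(n_rep), function(r) {
    m <- matrix(rnorm(36, 10, 2), nrow = 12,
                dimnames = list(sprintf("P%02d", 1:12), c("SIT", "SL", "EXE")))
    rm_anova(make_outcome_table(m))$p < 0.05
  }, logical(1))
  # 99.9% binomial band around 0.05 for 1000 draws, ~ [0.037, 0.065]
  expect_gte(mean(rejections), 0.029)
  expect_lte(mean(rejections), 0.073)
})

test_that("Bonferroni post hocs inflate p threefold with a cap at 1", {
  set.seed(41)
  m <- matrix(rnorm(36, 10, 3), nrow = 12,
              dimnames = list(sprintf("P%02d", 1:12), c("SIT", "SL", "EXE")))
  ph <- bonferroni_posthoc(make_outcome_table(m))
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_true(all(ph$p_adj <= 1))
})

test_that("Friedman statistic is exact for a perfectly monotone table", {
  # every participant ranks SIT < SL < EXE: chi2 = 12n/(k(k+1)) * sum
  # of squared deviations of mean ranks (1,2,3) from 2 -> 2n = 24 at n = 12
  base <- matrix(rnorm(12, 10, 1), 12, 1)
  m <- cbind(SIT = base[, 1], SL = base[, 1] + 1, EXE = base[, 1] + 2)
  rownames(m) <- sprintf("P%02d", 1:12)
  res <- friedman_crossover(make_outcome_table(m))
  expect_equal(res$chisq, 24)
  expect_lt(res$p, 1e-5)
})

test_that("a fully tied table is flagged degenerate", {
  m <- matrix(rep(c(4, 5, 6), each = 4), nrow = 4,
              dimnames = list(paste0("P", 1:4), NULL))
  m <- matrix(5, 4, 3, dimnames = list(paste0("P", 1:4), c("SIT", "SL", "EXE")))
  expect_warning(res <- friedman_crossover(make_outcome_table(m)), "tied")
  expect_equal(res$chisq, 0)
  expect_true(res$degenerate)
})

test_that("Friedman p agrees with the exhaustive permutation null", {
  # n = 5 blocks, k = 3: enumerate all 6^5 within-block rank orderings.
  # Agreement with the chi-square reference is asserted in the rejection
  # region, where decisions are made; outside it the 5-block exact null is
  # visibly discrete and the approximation is known to be loose.
  m <- cbind(SIT = c(1, 1, 1, 1, 2), SL = c(2, 2, 2, 2, 1),
             EXE = c(3, 3, 3, 3, 3)) + 0.1 * matrix(seq_len(15), 5)
  rownames(m) <- paste0("P", 1:5)
  obs <- friedman_crossover(make_outcome_table(m))
  expect_equal(obs$chisq, 8.4)

  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  chi_stat <- function(ranks) {
    rbar <- colMeans(ranks)
    12 * nrow(ranks) / (3 * 4) * sum((rbar - 2)^2)
  }
  idx <- as.matrix(expand.grid(rep(list(1:6), 5)))
  null_stats <- apply(idx, 1, function(row) chi_stat(perms[row, ]))
  p_exact <- mean(null_stats >= obs$chisq - 1e-9)
  p_asym <- obs$p
  expect_lt(abs(p_exact - p_asym), 0.01)
})

test_that("Dunn post hocs rank regimens by mean Friedman ranks", {
  base <- matrix(rnorm(12, 10, 1), 12, 1)
  m <- cbind(SIT = base[, 1], SL = base[, 1] + 1, EXE = base[, 1] + 2)
  rownames(m) <- sprintf("P%02d", 1:12)
  dn <- dunn_posthoc(make_outcome_table(m))
  expect_equal(nrow(dn), 3)
  # perfect ordering: mean rank differences are 1, 2, 1
  expect_equal(dn$mean_rank_diff[dn$contrast == "EXE-SIT"], 2)
  z_expected <- 2 / sqrt(3 * 4 / (6 * 12))
  expect_equal(dn$z[dn$contrast == "EXE-SIT"], z_expected)
  expect_true(all(dn$p_adj >= dn$p_raw & dn$p_adj <= 1))
})

test_that("sample-size search is exact, monotone and Monte-Carlo consistent", {
  # saturated effect: the floor of n = 2 suffices. (At a single residual
  # degree of freedom the t critical value is so large that even a 10-SD
  # effect is underpowered, so "saturated" needs a much larger standardized
  # effect before n = 2 is reachable.)
  sat <- paired_t_sample_size(sd_diff = 1, delta = 50)
  expect_equal(sat$n, 2)
  expect_equal(paired_t_sample_size(sd_diff = 1, delta = 10)$n, 3)

  # study-style specification
  spec <- paired_t_sample_size(sd_diff = 2.48, delta = 2.70, alpha = 0.05,
                               n_comparisons = 3, power = 0.8)
  # cross-check 1: power.t.test at the Bonferroni-corrected alpha
  ref <- stats::power.t.test(delta = 2.70, sd = 2.48, sig.level = 0.05 / 3,
                             power = 0.8, type = "paired")
  expect_equal(spec$n, ceiling(ref$n))

  # cross-check 2: Monte-Carlo power at the returned n within 1%
  set.seed(61)
  n <- spec$n
  n_sim <- 1e5
  diffs <- matrix(rnorm(n * n_sim, 2.70, 2.48), nrow = n)
  tstats <- colMeans(diffs) / (apply(diffs, 2, sd) / sqrt(n))
  crit <- qt(1 - (0.05 / 3) / 2, df = n - 1)
  mc_power <- mean(abs(tstats) > crit)
  expect_lt(abs(mc_power - spec$power_achieved), 0.01)
  expect_gte(spec$power_achieved, 0.8)

  # power is monotone in n at a fixed specification
  pow_n <- vapply(2:20, function(n) {
    ncp <- sqrt(n) * 2.70 / 2.48
    crit <- qt(1 - (0.05 / 3) / 2, df = n - 1)
    pt(crit, df = n - 1, ncp = ncp, lower.tail = FALSE) +
      pt(-crit, df = n - 1, ncp = ncp)
  }, numeric(1))
  expect_true(all(diff(pow_n) > -1e-12))

  expect_error(paired_t_sample_size(0, 1), "positive")
})
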