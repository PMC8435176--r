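test_that("normalisation divides by internal standard and dry weight", {
  mm <- make_tiny_metabolome(matrix(0, 1, 2), c("P01", "P01"), c("SIT", "SL"))
  mm$raw[1, ] <- c(4, 8)
  mm$is_intensities[1, ] <- c(2, 2)
  mm$samples$dry_weight_mg <- c(1, 1)
  nm <- normalize_metabolome(mm)
  expect_equal(unname(nm$log2[1, ]), c(1, 2))  # log2(4/2/1) = 1

  # doubling all dry weights shifts every value by -1
  mm2 <- mm
  mm2$samples$dry_weight_mg <- mm$samples$dry_weight_mg * 2
  nm2 <- normalize_metabolome(mm2)
  expect_equal(nm2$log2, nm$log2 - 1)
})

test_that("zeros are imputed by half-minimum and all-zero rows flagged", {
  mm <- make_tiny_metabolome(matrix(3, 2, 4),
                             rep(c("P01", "P02"), each = 2),
                             rep(c("SIT", "SL"), 2))
  mm$raw[1, 2] <- 0
  mm$raw[2, ] <- 0
  nm <- suppressWarnings(normalize_metabolome(mm))
  expect_equal(nm$n_imputed, 5)
  # imputed cell is half the smallest positive normalised value of its row
  expect_equal(nm$log2[1, 2], log2(8 / 2))
  expect_equal(nm$all_zero_metabolites, "met_002")
  expect_true(all(nm$log2[2, ] == nm$log2[2, 1]))
})

test_that("effect fitting matches a brute-force normal-equations oracle", {
  set.seed(71)
  n_p <- 4
  participants <- rep(sprintf("P%02d", 1:n_p), each = 3)
  regimens <- rep(c("SIT", "SL", "EXE"), n_p)
  y <- matrix(rnorm(5 * n_p * 3, mean = 12), 5, n_p * 3)
  mm <- make_tiny_metabolome(y, participants, regimens)
  nm <- normalize_metabolome(mm)
  ef <- fit_effects(nm, d0_override = 0)  # ordinary least squares

  # oracle: explicit normal equations per metabolite
  part <- factor(participants)
  reg <- factor(regimens, levels = c("SIT", "SL", "EXE"))
  x <- stats::model.matrix(~ part + reg)
  for (g in 1:5) {
    beta <- solve(t(x) %*% x, t(x) %*% nm$log2[g, ])
    fc_exe <- beta[rownames(beta) == "regEXE"]
    fc_sl <- beta[rownames(beta) == "regSL"]
    expect_equal(ef$log2fc[ef$metabolite == sprintf("met_%03d", g) &
                             ef$contrast == "EXE-SIT"],
                 unname(fc_exe), tolerance = 1e-10)
    expect_equal(ef$log2fc[ef$metabolite == sprintf("met_%03d", g) &
                             ef$contrast == "EXE-SL"],
                 unname(fc_exe - fc_sl), tolerance = 1e-10)
  }
})

test_that("variance shrinkage interpolates between s2 and the prior", {
  # heteroscedastic fixture so the prior degrees of freedom stay finite
  set.seed(2)
  n_p <- 8
  participants <- rep(sprintf("P%02d", 1:n_p), each = 3)
  regimens <- rep(c("SIT", "SL", "EXE"), n_p)
  sds <- sqrt(0.1 * rgamma(80, shape = 2, rate = 2))
  y <- 12 + matrix(rnorm(80 * n_p * 3, 0, rep(sds, n_p * 3)), 80, n_p * 3)
  nm <- normalize_metabolome(make_tiny_metabolome(y, participants, regimens))
  ef <- fit_effects(nm)
  d0 <- attr(ef, "df_prior")
  s02 <- attr(ef, "var_prior")
  expect_gt(d0, 0)
  expect_true(is.finite(d0))

  ef_inf <- fit_effects(nm, d0_override = Inf)
  # with infinite prior df every posterior variance equals the prior:
  # all metabolites share one t denominator, so t / log2fc is constant
  one <- ef_inf[ef_inf$contrast == "EXE-SIT", ]
  expect_equal(stats::sd(one$t / one$log2fc) /
                 abs(mean(one$t / one$log2fc)), 0, tolerance = 1e-10)

  # finite d0: the posterior variance lies strictly between s_g^2 and s0^2;
  # recover the variances from the t denominators by dividing out the
  # contrast factor c' (X'X)^-1 c computed directly from the design
  ef_ols <- fit_effects(nm, d0_override = 0)
  x <- stats::model.matrix(
    ~ factor(nm$samples$participant) +
      factor(nm$samples$regimen, levels = c("SIT", "SL", "EXE")))
  v_c <- solve(crossprod(x))[ncol(x), ncol(x)]
  exe <- ef$contrast == "EXE-SIT"
  s2_post <- (ef$log2fc[exe] / ef$t[exe])^2 / v_c
  s2_raw <- (ef_ols$log2fc[exe] / ef_ols$t[exe])^2 / v_c
  differ <- abs(s2_raw - s02) > 1e-10
  expect_true(all(s2_post[differ] > pmin(s2_raw, s02)[differ]))
  expect_true(all(s2_post[differ] < pmax(s2_raw, s02)[differ]))
})

test_that("moderated t holds its size under a null simulation", {
  # 1000 null metabolites with a common true variance
  set.seed(99)
  n_p <- 12
  participants <- rep(sprintf("P%02d", 1:n_p), each = 3)
  regimens <- rep(c("SIT", "SL", "EXE"), n_p)
  y <- matrix(rnorm(1000 * n_p * 3, 12, 0.4), 1000, n_p * 3)
  mm <- make_tiny_metabolome(y, participants, regimens)
  nm <- normalize_metabolome(mm)
  ef <- fit_effects(nm)
  rej <- mean(ef$p[ef$contrast == "EXE-SIT"] < 0.05)
  ci <- stats::qbinom(c(0.0005, 0.9995), 1000, 0.05) / 1000
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("a spiked metabolite dominates the exercise contrast", {
  cfg <- cohort_config(n_metabolites = 50, shared_fraction = 0)
  mm <- generate_metabolome(cfg, seed = 3)
  spike <- mm$samples$regimen == "EXE"
  mm$raw["met_025", spike] <- mm$raw["met_025", spike] * 2^3
  ef <- fit_effects(normalize_metabolome(mm))
  exe <- ef[ef$contrast == "EXE-SIT", ]
  expect_equal(exe$metabolite[which.max(abs(exe$t))], "met_025")
  expect_equal(sign(exe$t), sign(exe$log2fc))
})

test_that("effect fitting agrees with limma's moderated statistics", {
  cfg <- cohort_config(n_metabolites = 80)
  nm <- normalize_metabolome(generate_metabolome(cfg, seed = 12))
  ef <- fit_effects(nm)

  design <- stats::model.matrix(
    ~ factor(nm$samples$participant) +
      factor(nm$samples$regimen, levels = c("SIT", "SL", "EXE")))
  fit <- limma::eBayes(limma::lmFit(nm$log2, design))
  i_exe <- ncol(design)
  expect_equal(ef$log2fc[ef$contrast == "EXE-SIT"],
               unname(fit$coefficients[, i_exe]), tolerance = 1e-8)
  expect_equal(ef$t[ef$contrast == "EXE-SIT"],
               unname(fit$t[, i_exe]), tolerance = 1e-6)
  expect_equal(attr(ef, "df_prior"), unname(fit$df.prior), tolerance = 1e-4)
})

test_that("PLS-DA satisfies the VIP identity and score orthogonality", {
  cfg <- cohort_config(n_metabolites = 40)
  nm <- normalize_metabolome(generate_metabolome(cfg, seed = 5))
  m <- plsda(nm, ncomp = 2)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  gram <- crossprod(m$t)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)
  # one-component VIP is exposed via the ncomp flag
  v1 <- vip(m, ncomp = 1)
  expect_equal(mean(v1^2), 1, tolerance = 1e-8)
})

test_that("a perfectly separating metabolite earns the top VIP score", {
  set.seed(8)
  n_p <- 8
  participants <- rep(sprintf("P%02d", 1:n_p), each = 2)
  regimens <- rep(c("SIT", "EXE"), n_p)
  y <- matrix(rnorm(20 * n_p * 2, 12, 1), 20, n_p * 2)
  y[7, ] <- 12 + 3 * (regimens == "EXE") + rnorm(n_p * 2, 0, 0.01)
  mm <- make_tiny_metabolome(y, participants, regimens)
  m <- plsda(normalize_metabolome(mm), ncomp = 2)
  expect_equal(names(which.max(m$vip)), "met_007")
})

test_that("sample order does not affect scores or VIP", {
  cfg <- cohort_config(n_metabolites = 30)
  nm <- normalize_metabolome(generate_metabolome(cfg, seed = 9))
  m1 <- plsda(nm, ncomp = 2)
  perm <- sample(ncol(nm$log2))
  nm2 <- nm
  nm2$log2 <- nm$log2[, perm]
  nm2$samples <- nm$samples[perm, ]
  m2 <- plsda(nm2, ncomp = 2)
  expect_equal(m2$vip, m1$vip, tolerance = 1e-8)
  expect_equal(abs(m2$t[order(perm), 1]), abs(m1$t[, 1]), tolerance = 1e-6)
})

test_that("VIP ranking agrees with mixOmics on the same data", {
  skip_if_not_installed("mixOmics")
  cfg <- cohort_config(n_metabolites = 40)
  nm <- normalize_metabolome(generate_metabolome(cfg, seed = 14))
  ours <- plsda(nm, ncomp = 2)
  ref <- mixOmics::plsda(t(nm$log2), factor(nm$samples$regimen), ncomp = 2)
  ref_vip <- mixOmics::vip(ref)[, 2]
  # rankings from the independent implementation agree closely
  expect_gt(stats::cor(ours$vip[names(ref_vip)], ref_vip,
                       method = "spearman"), 0.95)
})

test_that("heatmap matrix is VIP-ordered and row-standardised", {
  cfg <- cohort_config()
  nm <- normalize_metabolome(generate_metabolome(cfg, seed = 4))
  m <- plsda(nm, ncomp = 2)
  hm <- rank_heatmap(m, nm, k = 25)
  expect_equal(dim(hm), c(25, 36))
  expect_equal(unname(rowMeans(hm)), rep(0, 25), tolerance = 1e-12)
  expect_equal(unname(apply(hm, 1, sd)), rep(1, 25), tolerance = 1e-12)
  ord <- order(-m$vip, names(m$vip))
  expect_equal(rownames(hm), names(m$vip)[ord][1:25])
  expect_error(rank_heatmap(m, nm, k = 1000), "exceeds")
})

test_that("signature concordance is 1 against itself and behaves at nulls", {
  cfg <- cohort_config(n_metabolites = 60)
  ef <- fit_effects(normalize_metabolome(generate_metabolome(cfg, seed = 6)))
  self <- signature_concordance(ef, "EXE-SIT", "EXE-SIT")
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_named(self$volcano, c("EXE-SIT", "SL-SIT", "EXE-SL"))
  expect_error(signature_concordance(ef, "EXE-SIT", "nope"), "not present")
})

test_that("exemplar selection keeps sign-consistent metabolites in rank order", {
  conc <- list(scores = tibble::tibble(
    metabolite = c("a", "b", "c", "d"),
    s_a = c(3, 2, -4, 1.5),
    s_b = c(2.5, -1, -3, 1.0)
  ))
  # b is discordant and never selected
  picks <- select_exemplars(conc, 10)
  expect_false("b" %in% picks)
  # ranked by min(|s_a|, |s_b|): c (3) > a (2.5) > d (1.0)
  expect_equal(picks, c("c", "a", "d"))
  expect_equal(select_exemplars(conc, 2), c("c", "a"))
})
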