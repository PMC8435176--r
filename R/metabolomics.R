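#' Normalize a metabolite intensity matrix
#'
#' Divides each raw intensity by its mapped internal-standard intensity and
#' by the sample's dry tissue weight, then takes log2. Zero or missing raw
#' intensities are imputed per metabolite by half the minimum positive value
#' before the log; the imputation count is reported. Samples whose
#' internal-standard intensity is non-positive are flagged.
#'
#' @param mm A `metabolite_matrix` (see [generate_metabolome()]) or a list
#'   with elements `raw`, `samples`, `is_map`, `is_intensities`.
#' @return A list of class `normalized_metabolome`: `log2` (metabolite x
#'   sample matrix), `samples` (the sample sheet), `n_imputed`,
#'   `flagged_samples`, `all_zero_metabolites`.
#' @export
normalize_metabolome <- function(mm) {
  raw <- mm$raw
  is_int <- mm$is_intensities[match(mm$is_map$is_id,
                                    rownames(mm$is_intensities)), ,
                              drop = FALSE]
  dw <- mm$samples$dry_weight_mg[match(colnames(raw), mm$samples$sample_id)]
  if (any(dw <= 0)) stop("dry weights must be positive", call. = FALSE)
  flagged <- colnames(raw)[apply(is_int <= 0, 2, any)]
  if (length(flagged) > 0) {
    warning(sprintf("non-positive internal-standard intensity in sample(s): %s",
                    paste(flagged, collapse = ", ")), call. = FALSE)
  }

  ratio <- raw / is_int / matrix(dw, nrow(raw), ncol(raw), byrow = TRUE)
  bad <- !is.finite(ratio) | ratio <= 0
  n_imputed <- sum(bad)
  all_zero <- character(0)
  if (n_imputed > 0) {
    for (i in which(rowSums(bad) > 0)) {
      pos <- ratio[i, !bad[i, ]]
      if (length(pos) == 0) {
        # degenerate all-zero metabolite: constant imputed column, flagged
        ratio[i, ] <- 1
        all_zero <- c(all_zero, rownames(ratio)[i])
      } else {
        ratio[i, bad[i, ]] <- min(pos) / 2
      }
    }
  }
  if (length(all_zero) > 0) {
    warning(sprintf("all-zero metabolite(s) imputed to a constant: %s",
                    paste(all_zero, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(log2 = log2(ratio), samples = mm$samples, n_imputed = n_imputed,
         flagged_samples = flagged, all_zero_metabolites = all_zero),
    class = "normalized_metabolome"
  )
}

trigamma_inverse <- function(y) {
  # Newton solve of trigamma(x) = y, x > 0
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (k in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (x <= 0) x <- 1e-8
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

squeeze_variances <- function(s2, df) {
  # empirical-Bayes moment matching of log s^2 against a scaled log-F
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    # no excess dispersion beyond chi-squared sampling noise: variances are
    # exchangeable and the pooled mean is the natural prior
    d0 <- Inf
    s02 <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  list(df_prior = d0, var_prior = s02, var_post = post)
}

#' Participant-blocked moderated-t effect table
#'
#' Fits, per metabolite, the least-squares linear model
#' `log2 intensity ~ participant + regimen` (participants as blocks), forms
#' the regimen contrasts EXE-SIT, SL-SIT and EXE-SL, and moderates the
#' residual variances with an empirical-Bayes shrinkage: the prior degrees of
#' freedom d0 and prior variance s0^2 are estimated by moment-matching the
#' distribution of log residual variances to a scaled log-F, the posterior
#' variance is `(d0 s0^2 + d s^2) / (d0 + d)`, and the moderated t carries
#' `d0 + d` degrees of freedom. p values are reported raw and
#' Benjamini-Hochberg adjusted within each contrast.
#'
#' @param normed A `normalized_metabolome` from [normalize_metabolome()], or a
#'   list with `log2` matrix and `samples` sheet.
#' @param d0_override Optional forced prior degrees of freedom (e.g. `Inf`
#'   makes every posterior variance equal the prior variance; `0` recovers
#'   ordinary t statistics).
#' @return A tibble of class `effect_table` with one row per metabolite x
#'   contrast: `metabolite`, `contrast`, `log2fc`, `t`, `p`, `p_adj`,
#'   `df_residual`; prior parameters are attached as attributes `df_prior`
#'   and `var_prior`.
#' @export
fit_effects <- function(normed, d0_override = NULL) {
  y <- normed$log2
  samples <- normed$samples
  stopifnot(identical(colnames(y), samples$sample_id))
  regimen <- factor(samples$regimen, levels = c("SIT", "SL", "EXE"))
  participant <- factor(samples$participant)
  if (any(table(participant, regimen) > 1)) {
    stop("duplicate (participant, regimen) samples", call. = FALSE)
  }
  complete <- rowSums(table(participant, regimen) > 0) == nlevels(regimen)
  if (sum(complete) < 2) {
    stop("need >= 2 participants with all regimens", call. = FALSE)
  }

  x <- stats::model.matrix(~ participant + regimen)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) stop("singular design", call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  df_resid <- n - p

  coefs <- t(qr.coef(qr_x, t(y)))            # metabolites x p
  fitted <- t(qr.fitted(qr_x, t(y)))
  s2 <- unname(rowSums((y - fitted)^2) / df_resid)

  xtx_inv <- chol2inv(qr.R(qr_x))
  cn <- colnames(x)
  i_sl <- which(cn == "regimenSL")
  i_exe <- which(cn == "regimenEXE")
  contrasts <- list(
    "EXE-SIT" = {v <- rep(0, p); v[i_exe] <- 1; v},
    "SL-SIT"  = {v <- rep(0, p); v[i_sl] <- 1; v},
    "EXE-SL"  = {v <- rep(0, p); v[i_exe] <- 1; v[i_sl] <- -1; v}
  )

  if (is.null(d0_override)) {
    sq <- squeeze_variances(s2, df_resid)
  } else if (is.infinite(d0_override)) {
    sq <- list(df_prior = Inf, var_prior = mean(s2),
               var_post = rep(mean(s2), length(s2)))
  } else if (d0_override == 0) {
    sq <- list(df_prior = 0, var_prior = NA_real_, var_post = s2)
  } else {
    s02 <- squeeze_variances(s2, df_resid)$var_prior
    sq <- list(df_prior = d0_override, var_prior = s02,
               var_post = (d0_override * s02 + df_resid * s2) /
                 (d0_override + df_resid))
  }
  df_total <- sq$df_prior + df_resid
  if (is.infinite(df_total)) df_total <- 1e6

  rows <- lapply(names(contrasts), function(cname) {
    v <- contrasts[[cname]]
    fc <- as.numeric(coefs %*% v)
    vc <- as.numeric(t(v) %*% xtx_inv %*% v)
    tstat <- fc / sqrt(sq$var_post * vc)
    pval <- 2 * stats::pt(-abs(tstat), df = df_total)
    tibble::tibble(
      metabolite = rownames(y),
      contrast = cname,
      log2fc = fc,
      t = tstat,
      p = pval,
      p_adj = stats::p.adjust(pval, method = "BH"),
      df_residual = df_resid
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  class(out) <- c("effect_table", class(out))
  out
}

#' Partial least-squares discriminant analysis (NIPALS PLS2)
#'
#' Fits a PLS-DA model on the autoscaled metabolite matrix against a centred
#' one-hot class-membership response using the iterative bilinear (NIPALS)
#' PLS2 algorithm. Constant metabolite columns are dropped with a warning.
#'
#' @param normed A `normalized_metabolome`, or a plain metabolite x sample
#'   log2 matrix.
#' @param classes Class label per sample (default: the regimen column of the
#'   sample sheet).
#' @param ncomp Number of latent components (default 2).
#' @param scale Autoscale metabolites to unit variance (default TRUE).
#' @return An object of class `plsda_model`: weights `w`, X-loadings `p`,
#'   scores `t`, Y-loadings `q`, per-component explained response variance
#'   `ssy`, `vip` scores, and bookkeeping fields.
#' @export
plsda <- function(normed, classes = NULL, ncomp = 2, scale = TRUE) {
  if (inherits(normed, "normalized_metabolome")) {
    x <- t(normed$log2)
    if (is.null(classes)) classes <- normed$samples$regimen
  } else {
    x <- t(as.matrix(normed))
  }
  if (is.null(classes)) stop("classes required", call. = FALSE)
  classes <- factor(classes)
  if (nlevels(classes) < 2) stop("need >= 2 classes", call. = FALSE)

  keep <- apply(x, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant metabolite column(s)",
                    sum(!keep)), call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  x <- base::scale(x, center = TRUE, scale = scale)
  y <- stats::model.matrix(~ classes - 1)
  colnames(y) <- levels(classes)
  y <- base::scale(y, center = TRUE, scale = FALSE)

  n <- nrow(x); pn <- ncol(x)
  if (ncomp > min(n - 1, pn)) stop("ncomp exceeds rank", call. = FALSE)
  w_mat <- matrix(0, pn, ncomp, dimnames = list(colnames(x), NULL))
  p_mat <- matrix(0, pn, ncomp, dimnames = list(colnames(x), NULL))
  t_mat <- matrix(0, n, ncomp, dimnames = list(rownames(x), NULL))
  q_mat <- matrix(0, ncol(y), ncomp, dimnames = list(colnames(y), NULL))
  ssy <- numeric(ncomp)
  xa <- x; ya <- y
  for (a in seq_len(ncomp)) {
    u <- ya[, which.max(apply(ya, 2, stats::var))]
    w <- rep(0, pn)
    for (it in 1:500) {
      w_new <- crossprod(xa, u) / sum(u^2)
      w_new <- w_new / sqrt(sum(w_new^2))
      tt <- xa %*% w_new
      q <- crossprod(ya, tt) / sum(tt^2)
      u_new <- ya %*% q / sum(q^2)
      if (sqrt(sum((w_new - w)^2)) < 1e-10) { w <- w_new; u <- u_new; break }
      w <- w_new; u <- u_new
    }
    tt <- xa %*% w
    pp <- crossprod(xa, tt) / sum(tt^2)
    q <- crossprod(ya, tt) / sum(tt^2)
    w_mat[, a] <- w
    p_mat[, a] <- pp
    t_mat[, a] <- tt
    q_mat[, a] <- q
    ssy[a] <- sum(tt^2) * sum(q^2)   # SS of Y explained by component a
    xa <- xa - tcrossprod(tt, pp)
    ya <- ya - tcrossprod(tt, q)
  }

  model <- structure(
    list(w = w_mat, p = p_mat, t = t_mat, q = q_mat, ssy = ssy,
         ncomp = ncomp, classes = classes, dropped = names(keep)[!keep],
         metabolites = colnames(x)),
    class = "plsda_model"
  )
  model$vip <- vip(model)
  model
}

#' Variable importance in projection (VIP) scores
#'
#' \deqn{VIP_j = \sqrt{P \sum_a SSY_a (w_{ja}/\lVert w_a \rVert)^2 / \sum_a SSY_a}}
#' over the first `ncomp` components; the mean squared VIP over metabolites is
#' identically 1.
#'
#' @param model A [plsda()] model.
#' @param ncomp Number of components to use (default: all fitted).
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model, ncomp = model$ncomp) {
  w <- model$w[, seq_len(ncomp), drop = FALSE]
  ssy <- model$ssy[seq_len(ncomp)]
  w2 <- sweep(w, 2, sqrt(colSums(w^2)), "/")^2
  pn <- nrow(w)
  scores <- sqrt(pn * as.numeric(w2 %*% ssy) / sum(ssy))
  names(scores) <- rownames(w)
  scores
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components, %d metabolites, classes: %s\n",
              x$ncomp, length(x$metabolites),
              paste(levels(x$classes), collapse = "/")))
  invisible(x)
}

#' Top-k VIP heatmap matrix
#'
#' Selects the `k` metabolites with the highest VIP scores (ties broken by
#' metabolite id), orders rows by descending VIP and z-scales each row across
#' samples (mean 0, SD 1), producing the matrix behind a top-metabolite
#' heatmap.
#'
#' @param model A [plsda()] model.
#' @param normed The `normalized_metabolome` the model was fitted on.
#' @param k Number of top metabolites (default 25).
#' @return A k x sample matrix with row order by descending VIP.
#' @export
rank_heatmap <- function(model, normed, k = 25) {
  v <- model$vip
  if (k > length(v)) stop("k exceeds number of metabolites", call. = FALSE)
  ord <- order(-v, names(v))
  top <- names(v)[ord][seq_len(k)]
  mat <- normed$log2[top, , drop = FALSE]
  sds <- apply(mat, 1, stats::sd)
  sds[sds == 0] <- 1
  sweep(sweep(mat, 1, rowMeans(mat)), 1, sds, "/")
}

#' Concordance of two regimen effect signatures
#'
#' For each metabolite and contrast, forms the signed significance score
#' `s = sign(log2fc) * (-log10 p)` and correlates the two contrasts' scores
#' across metabolites (Pearson), quantifying how closely one intervention's
#' molecular signature tracks another's. Volcano tables per contrast are
#' included in the result.
#'
#' @param effects An `effect_table` from [fit_effects()].
#' @param contrast_a,contrast_b The two contrasts to compare (defaults:
#'   EXE-SIT vs SL-SIT).
#' @return A list of class `concordance_result`: `scores` (per-metabolite
#'   tibble with `s_a`, `s_b`), `r`, `p`, `volcano` (per-contrast tibbles of
#'   `log2fc` and `-log10 p`).
#' @export
signature_concordance <- function(effects, contrast_a = "EXE-SIT",
                                  contrast_b = "SL-SIT") {
  ea <- effects[effects$contrast == contrast_a, ]
  eb <- effects[effects$contrast == contrast_b, ]
  if (nrow(ea) == 0 || nrow(eb) == 0) {
    stop("requested contrasts not present in effect table", call. = FALSE)
  }
  eb <- eb[match(ea$metabolite, eb$metabolite), ]
  if (nrow(ea) < 3) stop("need >= 3 metabolites", call. = FALSE)
  # guard against p underflow at extreme t statistics
  s_a <- sign(ea$log2fc) * (-log10(pmax(ea$p, 1e-300)))
  s_b <- sign(eb$log2fc) * (-log10(pmax(eb$p, 1e-300)))
  ct <- stats::cor.test(s_a, s_b, method = "pearson")
  volcano <- list()
  for (cn in unique(effects$contrast)) {
    ec <- effects[effects$contrast == cn, ]
    volcano[[cn]] <- tibble::tibble(metabolite = ec$metabolite,
                                    log2fc = ec$log2fc,
                                    neg_log10_p = -log10(ec$p))
  }
  structure(
    list(
      scores = tibble::tibble(metabolite = ea$metabolite, s_a = s_a, s_b = s_b),
      contrast_a = contrast_a, contrast_b = contrast_b,
      r = unname(ct$estimate), p = ct$p.value, volcano = volcano
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %s vs %s: Pearson r = %.3f, p = %.3g (%d metabolites)\n",
              x$contrast_a, x$contrast_b, x$r, x$p, nrow(x$scores)))
  invisible(x)
}

#' Select metabolites exemplary of a signature concordance
#'
#' Keeps metabolites whose signed significance scores agree in sign (and are
#' nonzero) in both contrasts, ranked by the smaller of the two absolute
#' scores, descending (a metabolite must be clearly moved in *both* regimens
#' to rank highly); ties are broken by metabolite id.
#'
#' @param concordance A [signature_concordance()] result.
#' @param n Number of exemplars to return; if fewer qualify, all qualifying
#'   metabolites are returned.
#' @return Character vector of metabolite ids, best exemplars first.
#' @export
select_exemplars <- function(concordance, n = 10) {
  sc <- concordance$scores
  qual <- sc[sign(sc$s_a) == sign(sc$s_b) & sc$s_a != 0 & sc$s_b != 0, ]
  key <- pmin(abs(qual$s_a), abs(qual$s_b))
  qual$metabolite[order(-key, qual$metabolite)][seq_len(min(n, nrow(qual)))]
}
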