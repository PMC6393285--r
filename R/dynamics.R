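#' Fit the per-locus one-way linear model across time points
#'
#' A general linear model with one level per time point (TP0, TP36, TP48,
#' TP60 in the default design) and replicate samples per level. With this
#' saturated one-way design the OLS level estimates are the replicate
#' means and the residual variance is the pooled within-level variance
#' with n - k degrees of freedom.
#'
#' @param scores numeric matrix, loci x samples.
#' @param timepoints character/factor of length ncol(scores) assigning
#'   each sample to a level.
#' @return List: `means` (loci x levels), `s2` (residual variance per
#'   locus), `df_residual`, `n_per_level`, `levels`.
#' @export
fit_linear_model <- function(scores, timepoints) {
  timepoints <- as.factor(timepoints)
  stopifnot(ncol(scores) == length(timepoints))
  k <- nlevels(timepoints)
  n <- ncol(scores)
  if (n - k < 1) stop("no residual degrees of freedom (need n_samples > n_levels)")
  lev <- levels(timepoints)
  means <- sapply(lev, function(l)
    rowMeans(scores[, timepoints == l, drop = FALSE]))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(scores), lev))
  resid <- scores - means[, as.character(timepoints), drop = FALSE]
  s2 <- rowSums(resid^2) / (n - k)
  list(means = means, s2 = s2, df_residual = n - k,
       n_per_level = table(timepoints), levels = lev)
}

#' Invert the trigamma function (Newton iteration)
#' @keywords internal
trigamma_inverse <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v) || v <= 0) return(Inf)
    if (v > 1e7) return(1 / sqrt(v))
    if (v < 1e-6) return(1 / v)
    y <- 0.5 + 1 / v
    for (it in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / v) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes prior on residual variances
#'
#' Fits a scaled inverse chi-square prior (d0, s0^2) to the observed
#' residual variances by the method of moments on log s^2: under the
#' hierarchical model, log s2_g has variance trigamma(d_g/2) +
#' trigamma(d0/2) and mean log s0^2 + digamma(d_g/2) - log(d_g/2) -
#' digamma(d0/2) + log(d0/2). If the observed spread of log s^2 does not
#' exceed the sampling floor trigamma(d_g/2), d0 = Inf and every
#' moderated variance equals s0^2. Zero or non-finite variances are
#' excluded from the fit.
#'
#' @param s2 residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return List: `s2_0` (prior variance), `df_0` (prior df, possibly
#'   Inf), `s2_post` (moderated variances for the input s2).
#' @export
ebayes_moderate <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("no positive finite residual variances to moderate")
  z <- log(s2[ok])
  e_z <- mean(z)
  v_z <- var(z)
  floor_v <- trigamma(df / 2)
  if (!is.finite(v_z) || v_z <= floor_v) {
    df0 <- Inf
    s20 <- exp(e_z - digamma(df / 2) + log(df / 2))
  } else {
    df0 <- 2 * trigamma_inverse(v_z - floor_v)
    s20 <- exp(e_z - digamma(df / 2) + log(df / 2) +
                 digamma(df0 / 2) - log(df0 / 2))
  }
  s2_post <- if (is.infinite(df0)) rep(s20, length(s2)) else
    (df0 * s20 + df * s2) / (df0 + df)
  ## loci with s2 = 0 still get prior information
  s2_post[!is.finite(s2) | s2 < 0] <- NA_real_
  list(s2_0 = s20, df_0 = df0, s2_post = s2_post)
}

#' Moderated-t contrast test
#'
#' estimate = c' mu_hat; its unscaled variance is sum(c_l^2 / n_l) for
#' the one-way design; the moderated t divides by the posterior standard
#' deviation and is referred to a t distribution on df0 + df_residual
#' degrees of freedom. A positive t indicates a score increase in the
#' contrast's positive level.
#'
#' @param fit from [fit_linear_model()].
#' @param prior from [ebayes_moderate()] (pass df_0 = 0 to recover the
#'   ordinary t test).
#' @param contrast named numeric vector over the design levels (e.g.
#'   c(TP0 = -1, TP36 = 1)); missing levels count as 0.
#' @return data.frame: locus_id, estimate, t, p_value.
#' @export
contrast_test <- function(fit, prior, contrast) {
  cv <- setNames(numeric(length(fit$levels)), fit$levels)
  bad <- setdiff(names(contrast), fit$levels)
  if (length(bad)) stop("contrast names not in design: ",
                        paste(bad, collapse = ", "))
  cv[names(contrast)] <- contrast
  est <- as.numeric(fit$means %*% cv)
  if (length(prior$s2_post) != length(est))
    stop("prior has ", length(prior$s2_post),
         " moderated variances for ", length(est), " loci")
  v_c <- sum(cv^2 / as.numeric(fit$n_per_level[fit$levels]))
  df_total <- prior$df_0 + fit$df_residual
  se <- sqrt(prior$s2_post * v_c)
  t <- est / se
  t[se == 0] <- 0
  p <- 2 * pt(-abs(t), df = df_total)
  p[se == 0] <- 1
  data.frame(locus_id = rownames(fit$means) %||% seq_along(est),
             estimate = est, t = t, p_value = p,
             stringsAsFactors = FALSE)
}

#' Storey q-values with smoothing-spline pi0
#'
#' pi0_hat(lambda) = #{p > lambda} / (m (1 - lambda)) on the grid
#' lambda = 0, 0.05, ..., 0.95; a cubic smoothing spline (df = 3) is
#' evaluated at lambda = 0.95 and clamped to (0, 1] to give pi0. Then
#' q_i = pi0 * min_{p_j >= p_i} (m p_j / rank_j), monotone in p.
#'
#' @param p p-values in [0, 1].
#' @param lambda grid for pi0 estimation.
#' @param spline_df smoothing-spline degrees of freedom.
#' @return List: `q` (same order as p), `pi0`.
#' @export
qvalues <- function(p, lambda = seq(0, 0.95, by = 0.05), spline_df = 3) {
  m <- length(p)
  if (!m) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1))
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fitted <- suppressWarnings(
    predict(smooth.spline(lambda, pi0_l, df = spline_df),
            x = max(lambda))$y)
  pi0 <- min(max(fitted, .Machine$double.eps), 1)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(m * p[o] / rank(p, ties.method = "max")[o]))[ro]
  list(q = q, pi0 = pi0)
}

#' Differential occupancy between time points
#'
#' Runs the full differential pipeline on a score table: one-way model
#' fit across time points, empirical-Bayes variance moderation, moderated
#' t for the requested contrast, smoothing-spline pi0 q-values, and
#' significance calls at the FDR threshold. Loci below the peak cutoff in
#' every sample of both contrasted time points are recorded as
#' `below_cutoff` and excluded from the significance calls (but not from
#' the model or prior fit).
#'
#' @param st a [score_table()] (RPC4 samples are selected by `factor_`).
#' @param contrast string "TPb-TPa" (estimate = mean(TPb) - mean(TPa)).
#' @param fdr q-value threshold for significance (default 0.05).
#' @param factor_ ChIP factor whose samples enter the model.
#' @return data.frame of class `diff_result`: locus_id, estimate, t,
#'   p_value, q_value, significant, direction, status, plus attributes
#'   pi0, df_0, s2_0.
#' @export
diff_occupancy <- function(st, contrast = "TP36-TP0", fdr = 0.05,
                           factor_ = "RPC4") {
  sel <- st$samples$factor == factor_
  if (!any(sel)) stop("no samples for factor ", factor_)
  sc <- st$scores[, st$samples$sample_id[sel], drop = FALSE]
  tp <- st$samples$timepoint[sel]
  fit <- fit_linear_model(sc, tp)
  prior <- ebayes_moderate(fit$s2, fit$df_residual)
  parts <- strsplit(contrast, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("contrast must be of the form 'TPb-TPa'")
  cvec <- setNames(c(1, -1), parts)
  res <- contrast_test(fit, prior, cvec)
  qq <- qvalues(res$p_value)
  res$q_value <- qq$q

  ## cutoff status at the two contrasted time points
  thr <- st$thresholds[st$samples$sample_id[sel]]
  above <- sweep(sc, 2, thr, ">")
  above_tp <- sapply(parts, function(l)
    rowSums(above[, tp == l, drop = FALSE]) > 0)
  res$status <- ifelse(above_tp[, 1] | above_tp[, 2], "testable",
                       "below_cutoff")
  res$significant <- res$q_value < fdr & res$status == "testable"
  res$direction <- sign(res$estimate)
  res$below_cutoff_at_baseline <- !above_tp[, 2]  # the subtracted level
  res$status[res$significant] <- "significant"
  attr(res, "pi0") <- qq$pi0
  attr(res, "df_0") <- prior$df_0
  attr(res, "s2_0") <- prior$s2_0
  class(res) <- c("diff_result", class(res))
  res
}

#' Flag significant calls at an FDR threshold
#'
#' Convenience wrapper: marks q < fdr among testable loci and carries the
#' stratification used in the T-versus-baseline-score plots (significant
#' loci whose baseline score was below the peak cutoff form their own
#' stratum).
#'
#' @param res a [diff_occupancy()] result.
#' @param fdr threshold.
#' @return `res` with updated `significant` and `stratum` columns.
#' @export
call_significant <- function(res, fdr = 0.05) {
  res$significant <- res$q_value < fdr & res$status != "below_cutoff"
  res$stratum <- ifelse(res$status == "below_cutoff", "below_cutoff",
                 ifelse(!res$significant, "not_significant",
                 ifelse(res$below_cutoff_at_baseline,
                        "significant_from_below_cutoff", "significant")))
  res
}
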