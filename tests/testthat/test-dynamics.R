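test_that("one-way fit returns level means and pooled residual variance", {
  tp <- rep(c("TP0", "TP36", "TP48", "TP60"), each = 2)
  sc <- rbind(L1 = c(0, 2, 3, 5, 0, 0, 0, 0))
  fit <- fit_linear_model(sc, tp)
  expect_equal(unname(fit$means["L1", ]), c(1, 4, 0, 0))
  expect_equal(unname(fit$s2), (2 + 2 + 0 + 0) / 4)  # hand OLS
  expect_equal(fit$df_residual, 4)

  # replicates identical within level -> zero residual variance
  sc2 <- rbind(L1 = rep(c(1, 5, 2, 2), each = 2))
  expect_equal(unname(fit_linear_model(sc2, tp)$s2), 0)

  # invariant to sample ordering
  set.seed(12)
  sc3 <- matrix(rnorm(40), 5, 8)
  perm <- sample(8)
  f1 <- fit_linear_model(sc3, tp)
  f2 <- fit_linear_model(sc3[, perm], tp[perm])
  expect_equal(f1$means, f2$means)
  expect_equal(f1$s2, f2$s2)

  expect_error(fit_linear_model(sc[, 1:4, drop = FALSE], tp[c(1, 3, 5, 7)]),
               "degrees of freedom")
})

test_that("empirical-Bayes prior recovers scaled inverse chi-square truth", {
  set.seed(101)
  d0 <- 4; s0 <- 1; dg <- 4; m <- 1e4
  sigma2 <- d0 * s0 / rchisq(m, d0)
  s2 <- sigma2 * rchisq(m, dg) / dg
  pr <- ebayes_moderate(s2, dg)
  expect_lt(abs(pr$df_0 - d0) / d0, 0.2)
  expect_lt(abs(pr$s2_0 - s0) / s0, 0.1)

  # no spread beyond the sampling floor -> infinite prior df,
  # all moderated variances collapse to s2_0
  pr2 <- ebayes_moderate(rep(2.5, 50), dg)
  expect_equal(pr2$df_0, Inf)
  expect_equal(unique(pr2$s2_post), pr2$s2_0)

  expect_error(ebayes_moderate(rep(0, 20), dg), "variance")
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(55)
  tp <- rep(c("TP0", "TP36", "TP48", "TP60"), each = 2)
  m <- 500
  sigma <- sqrt(0.04 * 4 / rchisq(m, 4))
  y <- matrix(rnorm(m * 8, sd = rep(sigma, 8)), m, 8)
  y[1:50, tp == "TP36"] <- y[1:50, tp == "TP36"] + 1
  rownames(y) <- sprintf("L%03d", 1:m)

  fit <- fit_linear_model(y, tp)
  pr <- ebayes_moderate(fit$s2, fit$df_residual)
  res <- contrast_test(fit, pr, c(TP36 = 1, TP0 = -1))

  design <- stats::model.matrix(~ 0 + factor(tp))
  colnames(design) <- levels(factor(tp))
  lf <- limma::lmFit(y, design)
  lf <- limma::contrasts.fit(lf, limma::makeContrasts(TP36 - TP0,
                                                      levels = design))
  lf <- limma::eBayes(lf)
  expect_equal(pr$df_0, lf$df.prior, tolerance = 0.15)
  expect_equal(pr$s2_0, lf$s2.prior, tolerance = 0.05)
  expect_equal(res$t, as.numeric(lf$t), tolerance = 0.02)
  expect_equal(res$p_value, as.numeric(lf$p.value), tolerance = 0.02)
})

test_that("contrast p-values are calibrated under the null", {
  set.seed(66)
  tp <- rep(c("TP0", "TP36", "TP48", "TP60"), each = 2)
  m <- 1e4
  sigma <- sqrt(0.05 * 6 / rchisq(m, 6))
  y <- matrix(rnorm(m * 8, sd = rep(sigma, 8)), m, 8)
  fit <- fit_linear_model(y, tp)
  pr <- ebayes_moderate(fit$s2, fit$df_residual)
  res <- contrast_test(fit, pr, c(TP36 = 1, TP0 = -1))
  ks <- ks.test(res$p_value, "punif")
  expect_gt(ks$p.value, 0.01)

  # zero estimate -> t = 0, p = 1
  cz <- contrast_test(list(means = matrix(0, 1, 4,
                                          dimnames = list("L1",
                                                          unique(tp))),
                           s2 = 0.1, df_residual = 4,
                           n_per_level = table(tp), levels = unique(tp)),
                      list(df_0 = 0, s2_post = 0.1),
                      c(TP36 = 1, TP0 = -1))
  expect_equal(cz$t, 0)
  expect_equal(cz$p_value, 1)

  # adding a constant to all samples of a locus leaves the estimate unchanged
  y2 <- y[1:100, ] + 5
  pr100 <- list(df_0 = pr$df_0, s2_post = pr$s2_post[1:100])
  res2 <- contrast_test(fit_linear_model(y2, tp), pr100,
                        c(TP36 = 1, TP0 = -1))
  expect_equal(res2$estimate, res$estimate[1:100], tolerance = 1e-9)
  expect_equal(res2$t, res$t[1:100], tolerance = 1e-9)

  # with prior df 0 the moderated t reduces to the ordinary t
  ord <- contrast_test(fit, list(df_0 = 0, s2_post = fit$s2),
                       c(TP36 = 1, TP0 = -1))
  tt <- (fit$means[, "TP36"] - fit$means[, "TP0"]) / sqrt(fit$s2)
  expect_equal(ord$t, unname(tt), tolerance = 1e-9)
})

test_that("pi0 and q-values behave across null and mixed p-value sets", {
  all1 <- qvalues(rep(1, 200))
  expect_equal(all1$pi0, 1)
  expect_true(all(all1$q == 1))

  set.seed(88)
  u <- runif(1e4)
  expect_gte(qvalues(u)$pi0, 0.9)
  expect_lte(qvalues(u)$pi0, 1.0)

  # 30% of p-values near zero
  p_mix <- c(rbeta(3000, 0.1, 12), runif(7000))
  expect_equal(qvalues(p_mix)$pi0, 0.7, tolerance = 0.05)

  # q monotone non-decreasing in p
  qq <- qvalues(u[1:500])
  o <- order(u[1:500])
  expect_true(all(diff(qq$q[o]) >= -1e-12))
  expect_error(qvalues(numeric()), "empty")
})

test_that("significance calls respect FDR bounds and cutoff strata", {
  set.seed(99)
  sc <- matrix(rnorm(50 * 8, mean = 2, sd = 0.2), 50, 8,
               dimnames = list(sprintf("L%03d", 1:50), NULL))
  sc[1:10, 3:4] <- sc[1:10, 3:4] + 2     # induced at TP36
  sc[40:50, ] <- rnorm(11 * 8, 0, 0.2)   # below cutoff everywhere
  colnames(sc) <- sprintf("RPC4_%s_r%d",
                          rep(c("TP0", "TP36", "TP48", "TP60"), each = 2),
                          rep(1:2, 4))
  st <- make_score_table(sc, thresholds = 1,
                         factors = rep("RPC4", 8),
                         timepoints = rep(c("TP0", "TP36", "TP48", "TP60"),
                                          each = 2),
                         replicates = rep(1:2, 4))
  res <- call_significant(diff_occupancy(st, "TP36-TP0", fdr = 0.05), 0.05)
  expect_true(all(res$significant[1:10]))
  expect_true(all(res$direction[1:10] == 1))
  expect_true(all(res$status[40:50] == "below_cutoff"))
  expect_false(any(res$significant[40:50]))

  # fdr = 0 silences everything
  none <- call_significant(res, fdr = 0)
  expect_false(any(none$significant))
})
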