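test_that("the fitting scale is the closed-form least-squares solution", {
  expect_equal(fit_scale(c(0.21, 0.42, 0.63), c(1, 2, 3)), 0.21)
  expect_equal(fit_scale(c(0, 0, 0), c(1, 2, 3)), 0)
  expect_error(fit_scale(c(1, 2, 3), c(0, 0, 0)), "degenerate")
  set.seed(100)
  for (i in 1:20) {
    y <- rnorm(3)
    x <- sample(-3:5, 3)
    if (all(x == 0)) next
    s <- fit_scale(y, x)
    expect_lt(abs(s - oracle_grid_scale(y, x)), 1e-4)
    # any perturbation increases the residual sum of squares
    for (delta in c(-0.05, 0.01, 0.2)) {
      expect_gt(sum((y - (s + delta) * x)^2), sum((y - s * x)^2))
    }
  }
})

test_that("the no-intercept r-squared follows its definition", {
  expect_equal(r_squared_no_intercept(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared_no_intercept(c(1, 2, 3), c(0, 0, 0)), 0)
  expect_equal(r_squared_no_intercept(c(1, 2, 3), c(1, 2, 2)), 1 - 1 / 14)
  expect_error(r_squared_no_intercept(c(0, 0, 0), c(1, 2, 3)), "undefined")
  # r^2 = 1 exactly when y is proportional to x
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(3)
    s <- runif(1, -2, 2)
    expect_equal(r_squared_no_intercept(s * x, fit_scale(s * x, x) * x), 1)
  }
  # negative for models worse than predicting zero
  expect_lt(r_squared_no_intercept(c(1, 1, 1), c(-3, -3, -3)), 0)
})

test_that("deviation tests are calibrated under the null and powered", {
  set.seed(77)
  xv <- c(1, 2, 3)
  ps <- replicate(400, {
    act <- simulate_activations("dom_hier", scale = 0.2,
                                participant_sd = 0, noise_sd = 0.05,
                                n = 10, seed = sample.int(1e6, 1),
                                regions = "L_IFG")
    deviation_tests(act, setNames(0.2 * xv, PSC_CONTRASTS), "L_IFG")$p[1]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 1e-3)  # p-values uniform
  act <- simulate_activations("dom_hier", scale = 0.2, participant_sd = 0,
                              noise_sd = 0.05, n = 20, seed = 3,
                              regions = "L_IFG")
  dev <- deviation_tests(act, setNames(0.2 * xv + 1, PSC_CONTRASTS),
                         "L_IFG")  # large offset
  expect_true(all(dev$p < 1e-6) && all(dev$deviant))
  expect_equal(unique(dev$df), 19)  # n = 20 gives t(19)
})

test_that("the mixed model agrees with nlme under both criteria", {
  xv <- c(1, 2, 3)
  set.seed(11)
  for (i in 1:5) {
    act <- simulate_activations("dom_hier", scale = runif(1, 0.1, 0.3),
                                participant_sd = runif(1, 0.02, 0.1),
                                noise_sd = runif(1, 0.02, 0.1),
                                n = 12, seed = sample.int(1e6, 1),
                                regions = "L_SMG")
    d <- transform(act, x = xv[match(contrast, PSC_CONTRASTS)])
    for (meth in c("ML", "REML")) {
      own <- fit_mixed_model(d$psc, d$x, d$participant, meth)
      ref <- nlme::lme(psc ~ 0 + x, random = ~ 1 | participant, data = d,
                       method = meth)
      expect_equal(own$loglik, as.numeric(stats::logLik(ref)),
                   tolerance = 1e-6)
      expect_equal(own$scale, unname(nlme::fixef(ref)), tolerance = 1e-5)
      expect_equal(sqrt(own$sigma2_b),
                   as.numeric(nlme::VarCorr(ref)[1, 2]), tolerance = 1e-4)
    }
  }
})

test_that("mixed-model likelihood properties hold", {
  xv <- c(1, 2, 3)
  act <- simulate_activations(n = 15, seed = 21, regions = "L_IPS")
  d <- transform(act, x = xv[match(contrast, PSC_CONTRASTS)])
  # forced zero variance ratio reproduces the closed-form OLS likelihood
  at0 <- fit_mixed_model(d$psc, d$x, d$participant, "ML", var_ratio = 0)
  expect_equal(at0$loglik, ols_loglik(d$psc, d$x), tolerance = 1e-10)
  expect_true(at0$boundary)
  # the profiled ML likelihood can only improve on the OLS likelihood
  ml <- fit_mixed_model(d$psc, d$x, d$participant, "ML")
  expect_gte(ml$loglik, at0$loglik)
  # balanced noise-free data: mixed scale equals the least-squares scale
  act0 <- simulate_activations(scale = 0.21, participant_sd = 0,
                               noise_sd = 0, n = 10, seed = 2,
                               regions = "L_IFG")
  d0 <- transform(act0, x = xv[match(contrast, PSC_CONTRASTS)])
  ybar <- as.numeric(tapply(d0$psc, d0$contrast, mean)[PSC_CONTRASTS])
  mm <- fit_mixed_model(d0$psc, d0$x, d0$participant, "ML")
  expect_equal(mm$scale, fit_scale(ybar, xv), tolerance = 1e-10)
  expect_error(fit_mixed_model(d$psc, 0 * d$x, d$participant), "degenerate")
})

test_that("the participant variance component is recoverable", {
  set.seed(33)
  xv <- c(1, 2, 3)
  est <- replicate(100, {
    act <- simulate_activations("dom_hier", scale = 0.21,
                                participant_sd = 0.1, noise_sd = 0.05,
                                n = 20, seed = sample.int(1e6, 1),
                                regions = "L_IFG")
    d <- transform(act, x = xv[match(contrast, PSC_CONTRASTS)])
    fit_mixed_model(d$psc, d$x, d$participant, "ML")$sigma2_b
  })
  expect_lt(abs(mean(est) - 0.01) / 0.01, 0.5)  # within 50% on average
})

test_that("model comparison recovers the generating factor and is invariant", {
  act <- simulate_activations("dom_hier", n = 20, seed = 41)
  cmp <- compare_factor_models(act, "L_SMG")
  expect_equal(cmp$factor[1], "dom_hier")
  expect_equal(cmp$lik_ratio[1], 1)
  ok <- !is.na(cmp$lik_ratio)
  expect_true(all(cmp$lik_ratio[ok] > 0 & cmp$lik_ratio[ok] <= 1))
  # invariant to participant relabeling
  set.seed(8)
  perm <- act
  relab <- sample(20)
  perm$participant <- relab[perm$participant]
  cmp2 <- compare_factor_models(perm, "L_SMG")
  expect_equal(cmp2$loglik, cmp$loglik, tolerance = 1e-9)
  # region missing from the dataset
  expect_error(compare_factor_models(act, "Cerebellum"), "no data")
})

test_that("duplicate and degenerate factor rows are handled", {
  est <- estimates_table()
  est2 <- rbind(est, dom_copy = est["dom_hier", ],
                flat_const = c(4L, 4L, 4L, 4L))
  class(est2) <- c("factor_estimates", "data.frame")
  act <- simulate_activations("dom_hier", n = 10, seed = 51)
  cmp <- compare_factor_models(act, "L_IFG", table = est2)
  # identical rows get identical likelihoods: ratio 1 between them
  expect_equal(cmp$loglik[cmp$factor == "dom_copy"],
               cmp$loglik[cmp$factor == "dom_hier"])
  expect_equal(cmp$lik_ratio[cmp$factor %in% c("dom_hier", "dom_copy")],
               c(1, 1))
  # a factor constant across conditions has null subtracted estimates
  expect_true(cmp$degenerate[cmp$factor == "flat_const"])
  expect_true(is.na(cmp$loglik[cmp$factor == "flat_const"]))
})

test_that("nuisance residualization removes a planted covariate effect", {
  act <- simulate_activations("dom_hier", n = 12, seed = 61,
                              regions = "L_IFG", participant_sd = 0,
                              noise_sd = 0.02)
  set.seed(14)
  err <- setNames(runif(12, 0, 10), 1:12)
  contaminated <- act
  contaminated$psc <- act$psc + 0.05 * (err[as.character(act$participant)] -
                                          mean(err))
  dirty <- compare_factor_models(contaminated, "L_IFG")
  clean <- compare_factor_models(contaminated, "L_IFG", nuisance = err)
  # the covariate inflates apparent between-participant variance; removing
  # it restores the likelihood of the generating model
  expect_gt(clean$loglik[clean$factor == "dom_hier"],
            dirty$loglik[dirty$factor == "dom_hier"])
  # residualization leaves the contrast group means (and hence RSS) intact
  expect_equal(clean$rss[clean$factor == "dom_hier"],
               dirty$rss[dirty$factor == "dom_hier"], tolerance = 1e-12)
})
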