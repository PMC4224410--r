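# shared small design: one session with the study's per-session structure
local_design <- local({
  sch <- build_sessions(generate_stimulus_set(6, 9, seed = 77), seed = 77,
                        n_sessions = 1)
  build_design_regressors(sch)
})

test_that("the model space enumerates 18 structurally distinct models", {
  models <- enumerate_models()
  expect_length(models, 18)
  key <- vapply(models, function(m) paste(m$input_region, m$modulation),
                character(1))
  expect_equal(anyDuplicated(key), 0L)
  # six models per input region
  expect_true(all(table(vapply(models, `[[`, character(1),
                               "input_region")) == 6))
  # model 1: modulation on L_IPS -> L_IFG, driving input into L_IFG
  expect_equal(models[[1]]$input_region, "L_IFG")
  expect_equal(models[[1]]$modulation, "L_IPS->L_IFG")
  # no model touches a direct L_IFG <-> R_IPS connection
  for (m in models) {
    expect_equal(m$a_mask[1, 3], 0L)
    expect_equal(m$a_mask[3, 1], 0L)
    expect_equal(m$b_mask[1, 3], 0L)
    expect_equal(m$b_mask[3, 1], 0L)
    expect_true(all(m$b_mask[m$a_mask == 0 & diag(3) == 0] == 0))
  }
})

test_that("parameter matrices respect the masks and fixed self-decay", {
  m1 <- enumerate_models()[[1]]
  p <- dcm_params(m1, c(1.02, -0.82, 0.62, -0.55), 1.03, 0.71)
  expect_equal(unname(diag(p$A)), rep(-1, 3))
  expect_equal(p$A[1, 3], 0)
  expect_equal(p$A[3, 1], 0)
  expect_equal(p$A[2, 1], 1.02)   # L_IFG -> L_IPS
  expect_equal(p$A[1, 2], -0.82)  # L_IPS -> L_IFG
  expect_equal(p$B[1, 2], 1.03)
  expect_equal(sum(p$B != 0), 1)
  expect_equal(p$C, c(0.71, 0, 0))
})

test_that("neural dynamics match the first-order analytic response", {
  m1 <- enumerate_models()[[1]]
  # decoupled: only self-decay, unit step input into L_IFG
  p <- dcm_params(m1, c(0, 0, 0, 0), 0, 1)
  nT <- 200
  u <- rep(1, nT)
  z <- neural_dynamics(p, u, 0 * u, dt = 0.05)
  t <- (seq_len(nT) - 1) * 0.05
  expect_equal(z[, "L_IFG"], 1 - exp(-t), tolerance = 1e-6)
  expect_true(all(z[, c("L_IPS", "R_IPS")] == 0))
  # zero input from rest stays at rest
  z0 <- neural_dynamics(p, 0 * u, 0 * u, dt = 0.05)
  expect_true(all(z0 == 0))
  # halving the step barely changes the trajectory (4th-order scheme)
  ptrue <- dcm_params(m1, TRUE_DCM_PARAMS$a, TRUE_DCM_PARAMS$b,
                      TRUE_DCM_PARAMS$c_input)
  u1 <- local_design$sessions[[1]]$u_d
  m1u <- local_design$sessions[[1]]$u_m
  za <- neural_dynamics(ptrue, u1, m1u, dt = 0.1)
  zb <- neural_dynamics(ptrue, rep(u1, each = 2), rep(m1u, each = 2),
                        dt = 0.05)
  zb_on_grid <- zb[seq(1, nrow(zb), by = 2), ]
  rel <- sqrt(sum((za - zb_on_grid)^2)) / sqrt(sum(zb_on_grid^2))
  expect_lt(rel, 1e-3)
  expect_error(neural_dynamics(dcm_params(m1, c(5, 5, 5, 5), 0, 1), u1, m1u),
               "unstable")
})

test_that("fitting recovers self-generated data and is near-optimal", {
  m1 <- enumerate_models()[[1]]
  truth <- c(TRUE_DCM_PARAMS$a, TRUE_DCM_PARAMS$b, TRUE_DCM_PARAMS$c_input)
  pars <- dcm_params(m1, truth[1:4], truth[5], truth[6])
  bold <- simulate_bold(pars, local_design, noise_sd = 0, seed = 1)
  fit <- fit_dcm(m1, bold, local_design)
  expect_lt(max(abs(fit$theta - truth)), 1e-2)
  expect_lt(fit$rss, 1e-6)
  # with noise, the fitted likelihood is at least the truth's likelihood
  boldn <- simulate_bold(pars, local_design, noise_sd = 0.05, seed = 2)
  fitn <- fit_dcm(m1, boldn, local_design)
  rss_truth <- sum((boldn$y - bold$y)^2)
  expect_lte(fitn$rss, rss_truth + 1e-8)
})

test_that("random-effects model selection behaves on the simplex", {
  # identical evidences: expected probabilities uniform at 1/18
  b <- bms_rfx(matrix(0, 6, 18), n_draws = 2e5, seed = 1)
  expect_equal(b$expected_prob, rep(1 / 18, 18), tolerance = 1e-9)
  expect_equal(sum(b$exceedance_prob), 1, tolerance = 1e-6)
  expect_true(all(b$exceedance_prob >= 0 & b$expected_prob >= 0))
  # a dominant model takes essentially all exceedance mass
  le <- matrix(0, 20, 18)
  le[, 5] <- 20
  bd <- bms_rfx(le, n_draws = 2e5, seed = 2)
  expect_gt(bd$exceedance_prob[5], 0.999)
  expect_equal(which.max(bd$expected_prob), 5L)
  expect_error(bms_rfx(matrix(c(0, NA), 1, 2)), "non-finite")
})

test_that("exceedance probabilities match an independent sampler", {
  alpha <- c(9, 4, 2.5, 1.5, 1, 1, 1, 1)
  ours <- domarith:::dirichlet_exceedance(alpha, n_draws = 2e5, seed = 3)
  ref <- oracle_exceedance(alpha, n_draws = 2e5, seed = 1234)
  expect_lt(max(abs(ours - ref)), 0.005)
})

test_that("group parameter tests are calibrated and handle degeneracy", {
  set.seed(9)
  # null calibration: false-positive rate near the corrected level
  hits <- replicate(300, {
    th <- matrix(rnorm(10 * 4), 10, 4,
                 dimnames = list(NULL, paste0("a:", INTRINSIC_NAMES)))
    sum(parameter_group_tests(th)$significant)
  })
  rate <- mean(hits) / 4
  expect_lt(abs(rate - 0.0125), 3 * sqrt(0.0125 * 0.9875 / (300 * 4)) + 0.004)
  # constant nonzero estimates: degenerate t reported as a rejection
  thc <- matrix(1, 5, 1, dimnames = list(NULL, "b:L_IPS->L_IFG"))
  expect_warning(res <- parameter_group_tests(thc), "degenerate")
  expect_true(res$significant)
  # n = 20 gives t-tests on 19 degrees of freedom
  th20 <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(NULL, c(paste0("a:", INTRINSIC_NAMES),
                                         "b:x", "c:L_IFG")))
  res20 <- parameter_group_tests(th20)
  expect_true(all(res20$df == 19))
  expect_equal(res20$alpha_corrected,
               c(rep(0.0125, 4), 0.05, 0.05))
  expect_error(parameter_group_tests(th20[1, , drop = FALSE]), "two")
})

test_that("without modulation, Linear and Quad responses are alike", {
  m1 <- enumerate_models()[[1]]
  p0 <- dcm_params(m1, TRUE_DCM_PARAMS$a, 0, TRUE_DCM_PARAMS$c_input)
  sch <- build_sessions(generate_stimulus_set(12, 18, seed = 55), seed = 55,
                        n_sessions = 2)
  reg <- build_design_regressors(sch)
  bold <- simulate_bold(p0, reg, noise_sd = 0.05, seed = 5)
  # mean L_IFG response over the two volumes spanning each trial
  resp <- function(cond) {
    rows <- sch[sch$condition == cond, ]
    vapply(seq_len(nrow(rows)), function(i) {
      v0 <- (rows$session[i] - 1) * 72 + (rows$trial[i] - 1) * 2 + 1
      mean(bold$y[c(v0 + 1, min(v0 + 2, nrow(bold$y))), "L_IFG"])
    }, numeric(1))
  }
  tt <- t.test(resp("Quad"), resp("Linear"))
  expect_gt(tt$p.value, 0.01)
})

test_that("a scaled-down recovery study is deterministic and coherent", {
  rec1 <- run_recovery_study(n = 2, seed = 12, n_sessions = 1,
                             models = c(1, 4), n_draws = 1e4)
  rec2 <- run_recovery_study(n = 2, seed = 12, n_sessions = 1,
                             models = c(1, 4), n_draws = 1e4)
  expect_identical(rec1$log_evidence, rec2$log_evidence)
  expect_identical(rec1$bms$exceedance_prob, rec2$bms$exceedance_prob)
  expect_equal(dim(rec1$theta_hat), c(2, 6))
  expect_equal(sum(rec1$bms$expected_prob), 1, tolerance = 1e-9)
})
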