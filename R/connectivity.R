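# Effective connectivity at desk scale: the 18-model bilinear space over
# L_IFG, L_IPS and R_IPS, maximum-likelihood inversion through the
# canonical-HRF forward model, random-effects Bayesian model selection,
# and the parameter-recovery study.

SELF_DECAY <- -1  # fixed self-connection (s^-1), not a free parameter

# the four allowed directed intrinsic connections; no direct IFG<->RIPS.
# A[target, source] convention: entry (i, j) couples region j into region i.
INTRINSIC_EDGES <- rbind(
  c(2L, 1L),  # L_IFG -> L_IPS
  c(1L, 2L),  # L_IPS -> L_IFG
  c(3L, 2L),  # L_IPS -> R_IPS
  c(2L, 3L))  # R_IPS -> L_IPS
INTRINSIC_NAMES <- c("L_IFG->L_IPS", "L_IPS->L_IFG",
                     "L_IPS->R_IPS", "R_IPS->L_IPS")

# six modulation configurations: each single directed connection, then the
# two bidirectional pairs
MODULATION_CONFIGS <- list(
  "L_IPS->L_IFG" = rbind(c(1L, 2L)),
  "L_IFG->L_IPS" = rbind(c(2L, 1L)),
  "L_IPS->R_IPS" = rbind(c(3L, 2L)),
  "R_IPS->L_IPS" = rbind(c(2L, 3L)),
  "L_IFG<->L_IPS" = rbind(c(1L, 2L), c(2L, 1L)),
  "L_IPS<->R_IPS" = rbind(c(3L, 2L), c(2L, 3L)))

#' Enumerate the 18-model connectivity space
#'
#' Three driving-input regions crossed with six modulation configurations
#' (each of the four directed connections, or either bidirectional pair),
#' on a fixed intrinsic skeleton of bidirectional L_IFG-L_IPS and
#' L_IPS-R_IPS connections. Model 1 has the modulatory effect on the
#' L_IPS to L_IFG connection and driving inputs into the L_IFG.
#'
#' @return List of 18 `dcm_model` objects with fields `id`, `input_region`,
#'   `modulation` (name and edge index matrix), and mask matrices.
#' @export
enumerate_models <- function() {
  models <- list()
  a_mask <- matrix(0L, 3, 3, dimnames = list(DCM_REGIONS, DCM_REGIONS))
  a_mask[INTRINSIC_EDGES] <- 1L
  for (inp in seq_along(DCM_REGIONS)) {
    for (mod in seq_along(MODULATION_CONFIGS)) {
      b_mask <- matrix(0L, 3, 3, dimnames = dimnames(a_mask))
      b_mask[MODULATION_CONFIGS[[mod]]] <- 1L
      c_mask <- integer(3)
      c_mask[inp] <- 1L
      models[[length(models) + 1L]] <- structure(
        list(id = length(models) + 1L,
             regions = DCM_REGIONS,
             input_region = DCM_REGIONS[inp],
             modulation = names(MODULATION_CONFIGS)[mod],
             modulation_edges = MODULATION_CONFIGS[[mod]],
             a_mask = a_mask, b_mask = b_mask, c_mask = c_mask),
        class = "dcm_model")
    }
  }
  models
}

#' @export
print.dcm_model <- function(x, ...) {
  cat(sprintf("<dcm_model %d> input: %s, modulation: %s\n",
              x$id, x$input_region, x$modulation))
  invisible(x)
}

#' Assemble connectivity parameter matrices
#'
#' @param model A `dcm_model`.
#' @param a Intrinsic connection strengths in the order L_IFG->L_IPS,
#'   L_IPS->L_IFG, L_IPS->R_IPS, R_IPS->L_IPS.
#' @param b Modulatory strengths, one per modulated edge of the model.
#' @param c_input Driving-input weight into the model's input region.
#' @return A `dcm_params` list with matrices `A` (self-decay on the
#'   diagonal), `B`, and vector `C`.
#' @export
dcm_params <- function(model, a, b, c_input) {
  stopifnot(inherits(model, "dcm_model"),
            length(a) == nrow(INTRINSIC_EDGES),
            length(b) == nrow(model$modulation_edges),
            length(c_input) == 1L)
  A <- diag(SELF_DECAY, 3)
  dimnames(A) <- list(DCM_REGIONS, DCM_REGIONS)
  A[INTRINSIC_EDGES] <- a
  B <- matrix(0, 3, 3, dimnames = dimnames(A))
  B[model$modulation_edges] <- b
  C <- numeric(3)
  C[match(model$input_region, DCM_REGIONS)] <- c_input
  structure(list(A = A, B = B, C = C, model_id = model$id),
            class = "dcm_params")
}

# free-parameter vector of a fitted/true parameter set, in reporting order
params_to_theta <- function(model, params) {
  c(params$A[INTRINSIC_EDGES], params$B[model$modulation_edges],
    params$C[match(model$input_region, DCM_REGIONS)])
}

theta_names <- function(model) {
  c(paste0("a:", INTRINSIC_NAMES),
    paste0("b:", apply(model$modulation_edges, 1, function(e)
      paste0(DCM_REGIONS[e[2]], "->", DCM_REGIONS[e[1]]))),
    paste0("c:", model$input_region))
}

#' Integrate the bilinear neural dynamics
#'
#' `zdot = (A + u_m(t) B) z + C u_d(t)` by fixed-step fourth-order
#' Runge-Kutta with inputs frozen over each step.
#'
#' @param params A `dcm_params`.
#' @param u_d,u_m Driving and modulatory input vectors on the time grid.
#' @param z0 Initial state (default rest).
#' @param dt Grid step, seconds.
#' @return Matrix of state trajectories, time points x regions.
#' @export
neural_dynamics <- function(params, u_d, u_m, z0 = numeric(3), dt = 0.1) {
  stopifnot(inherits(params, "dcm_params"), dt > 0,
            length(u_d) == length(u_m))
  if (max(Re(eigen(params$A, only.values = TRUE)$values)) >= 0)
    stop("unstable intrinsic matrix: eigenvalue with non-negative real part",
         call. = FALSE)
  z <- dcm_integrate_cpp(params$A, params$B, params$C, u_d, u_m, z0, dt)
  if (any(!is.finite(z)))
    stop("integration diverged: non-finite states", call. = FALSE)
  colnames(z) <- DCM_REGIONS
  z
}


#' Fit a connectivity model to one participant's time series
#'
#' Maximum-likelihood (nonlinear least-squares) inversion through the full
#' forward model: bilinear dynamics, canonical-HRF convolution, sampling
#' at the scan times. The driving weight enters the prediction linearly
#' and is profiled out; the intrinsic and modulatory parameters are found
#' by Nelder-Mead with a restart. Model evidence is summarized by BIC.
#'
#' @param model A `dcm_model`.
#' @param bold A `bold_timeseries` for one participant.
#' @param regressors The `dcm_regressors` used for the session design.
#' @param start Optional start for the nonlinear parameters.
#' @param maxit Iteration cap per Nelder-Mead stage.
#' @return A `dcm_fit` list: `params`, `theta` (named free parameters),
#'   `loglik`, `bic`, `rss`, `sigma2`, `n_free`, `convergence`.
#' @export
fit_dcm <- function(model, bold, regressors, start = NULL, maxit = 400L) {
  stopifnot(inherits(model, "dcm_model"), inherits(bold, "bold_timeseries"))
  hrf <- canonical_hrf(regressors$dt)
  idx <- volume_grid_idx(regressors)
  Y <- unname(bold$y)
  n_mod <- nrow(model$modulation_edges)
  n_nl <- nrow(INTRINSIC_EDGES) + n_mod
  udc <- unlist(lapply(regressors$sessions, `[[`, "u_d"), use.names = FALSE)
  umc <- unlist(lapply(regressors$sessions, `[[`, "u_m"), use.names = FALSE)
  n_sessions <- length(regressors$sessions)
  input_idx <- match(model$input_region, DCM_REGIONS)
  C_unit <- numeric(3)
  C_unit[input_idx] <- 1
  css <- function(th) {  # RSS with the driving weight profiled out
    A <- diag(SELF_DECAY, 3)
    A[INTRINSIC_EDGES] <- th[seq_len(4)]
    if (max(Re(eigen(A, only.values = TRUE)$values)) >= -1e-9)
      return(list(rss = 1e10, c = 0))
    B <- matrix(0, 3, 3)
    B[model$modulation_edges] <- th[4 + seq_len(n_mod)]
    v <- dcm_profiled_rss_cpp(A, B, C_unit, udc, umc, n_sessions,
                              regressors$dt, hrf, idx, Y)
    list(rss = v[1], c = v[2])
  }
  obj <- function(th) css(th)$rss
  if (is.null(start)) start <- rep(0, n_nl)
  o1 <- optim(start, obj, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-10))
  o2 <- optim(o1$par, obj, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-10))
  best <- css(o2$par)
  n_obs <- length(Y)
  sigma2 <- best$rss / n_obs
  loglik <- -n_obs / 2 * (log(2 * pi * sigma2) + 1)
  n_free <- n_nl + 1L            # + driving weight; sigma counted below
  bic <- -2 * loglik + (n_free + 1L) * log(n_obs)
  params <- dcm_params(model, o2$par[seq_len(4)],
                       o2$par[4 + seq_len(n_mod)], best$c)
  theta <- setNames(c(o2$par, best$c), theta_names(model))
  structure(list(model = model, params = params, theta = theta,
                 loglik = loglik, bic = bic, rss = best$rss,
                 sigma2 = sigma2, n_free = n_free,
                 convergence = o2$convergence),
            class = "dcm_fit")
}

#' Random-effects Bayesian model selection
#'
#' Variational update of a Dirichlet posterior over model frequencies
#' (uniform prior concentration `alpha0 = 1`): iterate posterior model
#' assignments and concentration parameters to convergence. Expected
#' probabilities are the normalized concentrations; exceedance
#' probabilities (the probability a model is the most frequent in the
#' population) are estimated by seeded Monte-Carlo sampling of the
#' Dirichlet posterior.
#'
#' @param log_evidence Participants x models matrix of log model evidences
#'   (here, -BIC/2).
#' @param alpha0 Prior concentration (default 1, uniform).
#' @param n_draws Dirichlet Monte-Carlo draws for the exceedance
#'   probabilities.
#' @param seed Integer seed for the Monte-Carlo step.
#' @param tol,max_iter Convergence controls for the variational update.
#' @return A `bms_result` list: `alpha`, `expected_prob`,
#'   `exceedance_prob`, `assignments` (participants x models).
#' @export
bms_rfx <- function(log_evidence, alpha0 = 1, n_draws = 1e6L, seed = 1L,
                    tol = 1e-8, max_iter = 500L) {
  log_evidence <- as.matrix(log_evidence)
  if (any(!is.finite(log_evidence)))
    stop("non-finite log evidence", call. = FALSE)
  n <- nrow(log_evidence); m <- ncol(log_evidence)
  alpha <- rep(alpha0, m)
  g <- matrix(0, n, m)
  for (it in seq_len(max_iter)) {
    logu <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- exp(logu - apply(logu, 1, max))
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  expected <- alpha / sum(alpha)
  xp <- dirichlet_exceedance(alpha, n_draws, seed)
  structure(list(alpha = alpha, expected_prob = expected,
                 exceedance_prob = xp, assignments = g),
            class = "bms_result")
}

# Monte-Carlo exceedance probabilities of a Dirichlet distribution,
# chunked to bound memory
dirichlet_exceedance <- function(alpha, n_draws = 1e6L, seed = 1L,
                                 chunk = 1e5L) {
  m <- length(alpha)
  with_seed(seed, {
    wins <- numeric(m)
    left <- as.integer(n_draws)
    while (left > 0L) {
      k <- min(chunk, left)
      gm <- matrix(rgamma(k * m, shape = rep(alpha, each = k)), k, m)
      mx <- max.col(gm, ties.method = "first")
      wins <- wins + tabulate(mx, m)
      left <- left - k
    }
    wins / n_draws
  })
}

#' One-sample t-tests on group parameter estimates
#'
#' Tests each free parameter's per-participant estimates against zero,
#' Bonferroni-corrected within its parameter class (intrinsic,
#' modulatory, driving): with four intrinsic connections the intrinsic
#' class level is 0.05 / 4 = 0.0125.
#'
#' @param theta_matrix Participants x parameters matrix (columns named as
#'   in a `dcm_fit`'s `theta`).
#' @param alpha Family significance level (default 0.05).
#' @return Data.frame `parameter`, `class`, `mean`, `t`, `df`, `p`,
#'   `alpha_corrected`, `significant`.
#' @export
parameter_group_tests <- function(theta_matrix, alpha = 0.05) {
  theta_matrix <- as.matrix(theta_matrix)
  if (nrow(theta_matrix) < 2L)
    stop("group tests need at least two participants", call. = FALSE)
  cls <- substr(colnames(theta_matrix), 1, 1)
  cls <- c(a = "intrinsic", b = "modulatory", c = "driving")[cls]
  rows <- lapply(seq_len(ncol(theta_matrix)), function(j) {
    v <- theta_matrix[, j]
    lvl <- alpha / sum(cls == cls[j])
    if (sd(v) == 0) {
      warning("zero-variance parameter estimates: degenerate t-test",
              call. = FALSE)
      p <- if (mean(v) == 0) 1 else 0
      tstat <- if (mean(v) == 0) 0 else Inf
    } else {
      tt <- t.test(v)
      p <- tt$p.value
      tstat <- unname(tt$statistic)
    }
    data.frame(parameter = colnames(theta_matrix)[j], class = cls[j],
               mean = mean(v), t = tstat, df = length(v) - 1L, p = p,
               alpha_corrected = lvl, significant = p < lvl)
  })
  do.call(rbind, rows)
}

# group-mean truth of the study's best model, used as generative defaults
TRUE_DCM_PARAMS <- list(
  a = c(1.02, -0.82, 0.62, -0.55),  # order of INTRINSIC_NAMES
  b = 1.03,                          # modulation on L_IPS -> L_IFG
  c_input = 0.71)                    # driving input into L_IFG

#' Parameter-recovery study for the connectivity analysis
#'
#' Simulates `n` participants from model 1 (modulation on L_IPS to L_IFG,
#' driving inputs into L_IFG) with the study's group-mean parameter
#' estimates as ground truth plus Gaussian between-participant variation,
#' fits the requested model subset per participant, runs random-effects
#' Bayesian model selection on the BIC evidences, and tests the winning
#' model's group parameters against zero.
#'
#' @param n Number of participants.
#' @param seed Integer seed driving every random step.
#' @param true_params List with `a`, `b`, `c_input` group-mean truths.
#' @param subject_sd Between-participant parameter standard deviation.
#' @param noise_sd Observation noise standard deviation.
#' @param n_sessions Sessions per participant (study design: 8).
#' @param models Model ids to fit (default all 18).
#' @param n_draws Dirichlet draws for exceedance probabilities.
#' @param progress Print per-participant progress.
#' @return A `dcm_recovery` list: `bms`, `theta_true`, `theta_hat` (both
#'   participants x parameters, for model 1), `group_tests`,
#'   `winning_model`, `log_evidence`, `models`.
#' @export
run_recovery_study <- function(n = 20L, seed = 1L,
                               true_params = TRUE_DCM_PARAMS,
                               subject_sd = 0.1, noise_sd = 0.05,
                               n_sessions = 8L, models = 1:18,
                               n_draws = 1e6L, progress = FALSE) {
  space <- enumerate_models()
  fit_models <- space[models]
  gen_model <- space[[1L]]
  # keep the study's per-session structure (6/6/6/18 trials) at any scale
  schedule <- build_sessions(generate_stimulus_set(6L * n_sessions,
                                                   9L * n_sessions,
                                                   seed = seed),
                             seed = seed, n_sessions = n_sessions)
  regressors <- build_design_regressors(schedule)
  truth <- c(true_params$a, true_params$b, true_params$c_input)
  n_par <- length(truth)
  theta_true <- matrix(NA_real_, n, n_par)
  theta_hat <- matrix(NA_real_, n, n_par + 0)
  log_ev <- matrix(NA_real_, n, length(fit_models))
  m1_pos <- match(1L, vapply(fit_models, `[[`, integer(1), "id"))
  with_seed(seed, {
    for (p in seq_len(n)) {
      repeat {  # redraw until the participant's intrinsic matrix is stable
        th <- truth + rnorm(n_par, 0, subject_sd)
        pars <- dcm_params(gen_model, th[1:4], th[5], th[6])
        if (max(Re(eigen(pars$A, only.values = TRUE)$values)) < -1e-3) break
      }
      theta_true[p, ] <- th
      bold <- simulate_bold(pars, regressors, noise_sd = noise_sd,
                            seed = sample.int(.Machine$integer.max, 1L))
      for (k in seq_along(fit_models)) {
        fit <- fit_dcm(fit_models[[k]], bold, regressors)
        log_ev[p, k] <- -fit$bic / 2
        if (fit_models[[k]]$id == 1L) theta_hat[p, ] <- fit$theta
      }
      if (progress)
        message(sprintf("participant %d/%d done", p, n))
    }
  })
  colnames(theta_true) <- colnames(theta_hat) <- theta_names(gen_model)
  colnames(log_ev) <- paste0("model_", vapply(fit_models, `[[`,
                                              integer(1), "id"))
  bms <- bms_rfx(log_ev, n_draws = n_draws, seed = seed + 1L)
  winning <- fit_models[[which.max(bms$exceedance_prob)]]$id
  gt <- if (!is.na(m1_pos) && all(is.finite(theta_hat)))
    parameter_group_tests(theta_hat) else NULL
  structure(list(bms = bms, theta_true = theta_true, theta_hat = theta_hat,
                 group_tests = gt, winning_model = winning,
                 log_evidence = log_ev,
                 models = vapply(fit_models, `[[`, integer(1), "id"),
                 n = n, seed = seed, noise_sd = noise_sd,
                 subject_sd = subject_sd, n_sessions = n_sessions),
            class = "dcm_recovery")
}

#' @export
print.dcm_recovery <- function(x, ...) {
  cat(sprintf("<dcm_recovery> %d participants, %d models fitted\n",
              x$n, length(x$models)))
  cat(sprintf("  winning model: %d (exceedance %.3f)\n", x$winning_model,
              max(x$bms$exceedance_prob)))
  cat("  group-mean recovered parameters (model 1):\n")
  print(round(colMeans(x$theta_hat), 3))
  invisible(x)
}

#' Export a model space as JSON
#'
#' Masks written as 0/1 matrices.
#'
#' @param models Output of [enumerate_models()].
#' @param path File path.
#' @export
write_model_space_json <- function(models, path) {
  payload <- lapply(models, function(m)
    list(id = m$id, input_region = m$input_region,
         modulation = m$modulation, a_mask = m$a_mask, b_mask = m$b_mask,
         c_mask = m$c_mask))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
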