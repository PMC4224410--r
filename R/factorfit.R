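# No-intercept parametric factor-model fitting: least-squares scale,
# no-intercept r^2, deviation t-tests, random-intercept mixed models, and
# likelihood-ratio ranking of the eight complexity factors.

#' Least-squares fitting scale of a no-intercept model
#'
#' The single scale parameter minimizing the residual sum of squares of
#' `scale * x` against `y`: `sum(x * y) / sum(x^2)`.
#'
#' @param y Observed contrast values (typically group means).
#' @param x Subtracted factor estimates.
#' @return The fitted scale.
#' @export
fit_scale <- function(y, x) {
  stopifnot(length(y) == length(x))
  if (all(x == 0))
    stop("degenerate model: all subtracted estimates are zero", call. = FALSE)
  sum(x * y) / sum(x^2)
}

#' Coefficient of determination for a no-intercept model
#'
#' `r^2 = 1 - sum((y - yhat)^2) / sum(y^2)`, the appropriate definition
#' when the model has no intercept (total variation is measured about
#' zero, not about the mean). Can be negative for a bad model.
#'
#' @param y Observed values (not all zero).
#' @param yhat Fitted values.
#' @return The no-intercept coefficient of determination.
#' @export
r_squared_no_intercept <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (all(y == 0))
    stop("r^2 undefined: observed values are all zero", call. = FALSE)
  1 - sum((y - yhat)^2) / sum(y^2)
}

#' Deviation t-tests between fitted values and individual activations
#'
#' For each contrast, a two-sided one-sample t-test of the individual
#' participants' activations against the model's fitted value. A model
#' fits well when no contrast deviates at the Bonferroni-corrected level.
#'
#' @param data An `activation_dataset`.
#' @param fitted_values Named (by contrast) or ordered vector of fitted
#'   values, one per contrast.
#' @param region Region to test.
#' @param alpha Per-comparison significance level (default 0.05 / 3,
#'   Bonferroni over the three contrasts).
#' @return Data.frame `contrast`, `fitted`, `t`, `df`, `p`, `deviant`.
#' @export
deviation_tests <- function(data, fitted_values, region,
                            alpha = 0.05 / 3) {
  d <- data[data$region == region, , drop = FALSE]
  contrasts <- unique(d$contrast)
  stopifnot(length(fitted_values) == length(contrasts))
  if (is.null(names(fitted_values))) names(fitted_values) <- contrasts
  rows <- lapply(contrasts, function(ct) {
    v <- d$psc[d$contrast == ct]
    if (length(v) < 2L)
      stop("deviation test needs at least two participants", call. = FALSE)
    if (sd(v) == 0) {  # degenerate: all participants identical
      dev0 <- mean(v) - fitted_values[[ct]]
      tstat <- if (dev0 == 0) 0 else Inf * sign(dev0)
      p <- if (dev0 == 0) 1 else 0
      return(data.frame(contrast = ct, fitted = fitted_values[[ct]],
                        t = tstat, df = length(v) - 1L, p = p))
    }
    tt <- t.test(v, mu = fitted_values[[ct]])
    data.frame(contrast = ct, fitted = fitted_values[[ct]],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$deviant <- out$p < alpha
  out
}

#' Closed-form Gaussian log-likelihood of the no-intercept OLS fit
#'
#' Maximum-likelihood profile: `sigma^2 = RSS / N`, giving
#' `ll = -N/2 * (log(2 pi sigma^2) + 1)`. Equals the mixed-model ML
#' log-likelihood when the random-intercept variance is zero.
#'
#' @param y Observations.
#' @param x Regressor (same length).
#' @return Log-likelihood at the OLS maximum.
#' @export
ols_loglik <- function(y, x) {
  s <- fit_scale(y, x)
  rss <- sum((y - s * x)^2)
  n <- length(y)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

# Profiled deviance machinery for the single-regressor random-intercept
# model y_pj = s * x_pj + b_p + e_pj. For a fixed variance ratio
# rho = sigma_b^2 / sigma_e^2 everything else has a closed form.
mixed_profile <- function(y, x, participant, rho, reml = FALSE) {
  sp <- split(seq_along(y), participant)
  xVx <- xVy <- yVy <- logdet <- 0
  for (idx in sp) {
    m <- length(idx)
    w <- rho / (1 + m * rho)
    xs <- sum(x[idx]); ys <- sum(y[idx])
    xVx <- xVx + sum(x[idx]^2) - w * xs^2
    xVy <- xVy + sum(x[idx] * y[idx]) - w * xs * ys
    yVy <- yVy + sum(y[idx]^2) - w * ys^2
    logdet <- logdet + log1p(m * rho)
  }
  scale <- xVy / xVx
  q <- max(yVy - xVy^2 / xVx, 0)  # GLS residual quadratic form
  n <- length(y)
  if (q < 1e-300) {  # perfect fit: likelihood unbounded, use a sentinel
    return(list(scale = scale, sigma2 = 0, sigma2_b = 0, loglik = 1e300,
                rho = rho))
  }
  if (reml) {
    sigma2 <- q / (n - 1)
    ll <- -0.5 * ((n - 1) * (log(2 * pi * sigma2) + 1) + logdet + log(xVx))
  } else {
    sigma2 <- q / n
    ll <- -0.5 * (n * (log(2 * pi * sigma2) + 1) + logdet)
  }
  list(scale = scale, sigma2 = sigma2, sigma2_b = rho * sigma2,
       loglik = ll, rho = rho)
}

#' Fit the no-intercept random-intercept mixed model
#'
#' Fits `y = scale * x + b_participant + e` with a participant random
#' intercept, by profiling the likelihood over the variance ratio
#' `rho = sigma_b^2 / sigma_e^2` (scale and residual variance have closed
#' forms given rho). A boundary solution at zero random variance is
#' reported, not raised.
#'
#' @param y Individual activation values.
#' @param x Regressor (subtracted factor estimates expanded to the long
#'   format), not all zero.
#' @param participant Participant identifier, same length as `y`.
#' @param method `"ML"` (default, comparable across factor models) or
#'   `"REML"`.
#' @param var_ratio Optional fixed variance ratio; `0` forces the
#'   zero-random-variance (OLS) solution.
#' @return List: `scale`, `sigma2`, `sigma2_b`, `loglik`, `method`,
#'   `boundary` (TRUE when the variance estimate hit zero).
#' @export
fit_mixed_model <- function(y, x, participant, method = c("ML", "REML"),
                            var_ratio = NULL) {
  method <- match.arg(method)
  stopifnot(length(y) == length(x), length(y) == length(participant))
  if (all(x == 0))
    stop("degenerate model: all subtracted estimates are zero", call. = FALSE)
  reml <- method == "REML"
  if (!is.null(var_ratio)) {
    fit <- mixed_profile(y, x, participant, var_ratio, reml)
    fit$method <- method
    fit$boundary <- var_ratio == 0
    return(fit)
  }
  obj <- function(u) mixed_profile(y, x, participant, exp(u), reml)$loglik
  opt <- optimize(obj, interval = c(-12, 12), maximum = TRUE)
  at0 <- mixed_profile(y, x, participant, 0, reml)
  if (at0$loglik >= opt$objective) {
    fit <- at0
    fit$boundary <- TRUE
  } else {
    fit <- mixed_profile(y, x, participant, exp(opt$maximum), reml)
    fit$boundary <- FALSE
  }
  fit$method <- method
  fit
}

#' Fit and rank all complexity-factor models for one region
#'
#' For each factor: the no-intercept least-squares fit to the
#' participant-averaged contrast values (scale, fitted values, RSS,
#' no-intercept r^2), deviation t-tests against individual activations,
#' and the random-intercept mixed-model log-likelihood on the individual
#' values. Factors are ranked by log-likelihood; each model's likelihood
#' ratio is its likelihood relative to the best model's. Degenerate
#' factors (all-zero subtracted estimates) are reported as not calculable.
#'
#' @param data An `activation_dataset`.
#' @param region Region label present in `data`.
#' @param table Factor estimate table.
#' @param criterion `"ML"` (default) or `"REML"` likelihoods for the
#'   ranking.
#' @param alpha Deviation-test significance level (default 0.05 / 3).
#' @param nuisance Optional named per-participant covariate (e.g. error
#'   rates) residualized out of the activations before fitting.
#' @return A `factor_comparison` data.frame sorted by rank, with columns
#'   `factor`, `scale`, `rss`, `r2`, `p1`-`p3` (deviation p-values in
#'   ascending order), `loglik`, `lik_ratio`, `boundary`, `degenerate`.
#' @export
compare_factor_models <- function(data, region, table = default_estimates(),
                                  criterion = c("ML", "REML"),
                                  alpha = 0.05 / 3, nuisance = NULL) {
  criterion <- match.arg(criterion)
  d <- data[data$region == region, , drop = FALSE]
  if (nrow(d) == 0L) stop("no data for region ", region, call. = FALSE)
  if (!is.null(nuisance)) d$psc <- residualize_nuisance(d, nuisance)
  contrasts <- intersect(PSC_CONTRASTS, unique(d$contrast))
  ybar <- vapply(contrasts, function(ct) mean(d$psc[d$contrast == ct]),
                 numeric(1))
  rows <- lapply(rownames(table), function(fac) {
    xv <- factor_contrast_vector(fac, table, contrasts)
    if (all(xv == 0)) {
      return(data.frame(factor = fac, scale = NA_real_, rss = NA_real_,
                        r2 = NA_real_, p1 = NA_real_, p2 = NA_real_,
                        p3 = NA_real_, loglik = NA_real_,
                        boundary = NA, degenerate = TRUE))
    }
    s <- fit_scale(ybar, xv)
    fitted <- s * xv
    rss <- sum((ybar - fitted)^2)
    r2 <- r_squared_no_intercept(ybar, fitted)
    dev <- deviation_tests(d, setNames(fitted, contrasts), region, alpha)
    p_sorted <- sort(dev$p)
    mm <- fit_mixed_model(d$psc, xv[d$contrast], d$participant, criterion)
    data.frame(factor = fac, scale = s, rss = rss, r2 = r2,
               p1 = p_sorted[1], p2 = p_sorted[2], p3 = p_sorted[3],
               loglik = mm$loglik, boundary = mm$boundary,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  best <- max(out$loglik, na.rm = TRUE)
  # the best model's ratio is 1 by definition (robust to perfect fits,
  # where the profiled log-likelihood is unbounded)
  out$lik_ratio <- ifelse(out$loglik == best, 1, exp(out$loglik - best))
  out <- out[order(-out$lik_ratio, na.last = TRUE), ]
  out$rank <- ifelse(out$degenerate, NA_integer_, seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "region") <- region
  attr(out, "criterion") <- criterion
  class(out) <- c("factor_comparison", "data.frame")
  out
}

# regress a centered per-participant covariate out of the activations,
# preserving the contrast means
residualize_nuisance <- function(d, nuisance) {
  cov <- nuisance[as.character(d$participant)]
  if (any(is.na(cov)))
    stop("nuisance covariate missing for some participants", call. = FALSE)
  out <- d$psc
  for (ct in unique(d$contrast)) {
    i <- d$contrast == ct
    cc <- cov[i] - mean(cov[i])
    if (sum(cc^2) > 0)
      out[i] <- d$psc[i] - sum(cc * d$psc[i]) / sum(cc^2) * cc
  }
  out
}

#' Write a factor-comparison table as CSV
#'
#' @param comparison A `factor_comparison`.
#' @param path File path.
#' @export
write_comparison_csv <- function(comparison, path) {
  write.csv(as.data.frame(comparison), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
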