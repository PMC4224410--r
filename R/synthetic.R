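# Synthetic data: region-level percent-signal-change datasets with the
# statistical structure the factor-model analysis assumes, and BOLD-like
# three-region time series from the bilinear connectivity model.

PSC_REGIONS <- c("L_IFG", "L_SMG", "L_IPS", "R_IPS", "Precuneus")
# fitted scales of the winning factor model, used as per-region defaults
REGION_SCALES <- c(L_IFG = 0.21, L_SMG = 0.21, L_IPS = 0.17,
                   R_IPS = 0.13, Precuneus = 0.22)

DCM_REGIONS <- c("L_IFG", "L_IPS", "R_IPS")
TR_DEFAULT <- 4.1          # scan repetition time, seconds
VOLUMES_PER_SESSION <- 72L
TRIAL_DUR <- 2 * TR_DEFAULT  # one trial spans two scans: 5 s + 3 s + 0.2 s
BOXCAR_WINDOW <- c(1, 3)   # seconds after main-stimulus onset

#' Simulate a percent-signal-change activation dataset
#'
#' Each cell value is `region_scale * contrast_estimate(factor) + b_p + e`,
#' with a participant random intercept `b_p ~ N(0, participant_sd^2)`
#' (drawn per participant and region, matching the region-wise mixed-model
#' analysis) and observation noise `e ~ N(0, noise_sd^2)`.
#'
#' @param factor Name of the generating complexity factor.
#' @param scale Scalar or per-region named vector of fitting scales
#'   (defaults: the winning model's per-region fitted scales).
#' @param participant_sd,noise_sd Random-intercept and residual standard
#'   deviations (percent signal change units).
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param regions Region labels.
#' @param table Factor estimate table.
#' @return An `activation_dataset` data.frame with columns `participant`,
#'   `region`, `contrast`, `psc`.
#' @export
simulate_activations <- function(factor = "dom_hier", scale = REGION_SCALES,
                                 participant_sd = 0.05, noise_sd = 0.05,
                                 n = 20L, seed = 1L, regions = PSC_REGIONS,
                                 table = default_estimates()) {
  stopifnot(participant_sd >= 0, noise_sd >= 0, n >= 1)
  xv <- factor_contrast_vector(factor, table)
  if (length(scale) == 1L) scale <- setNames(rep(scale, length(regions)), regions)
  if (!all(regions %in% names(scale)))
    stop("scale must be scalar or named for every region", call. = FALSE)
  with_seed(seed, {
    grid <- expand.grid(participant = seq_len(n), region = regions,
                        contrast = PSC_CONTRASTS, stringsAsFactors = FALSE)
    b <- matrix(rnorm(n * length(regions), 0, participant_sd), n,
                length(regions), dimnames = list(NULL, regions))
    grid$psc <- scale[grid$region] * xv[grid$contrast] +
      b[cbind(grid$participant, match(grid$region, regions))] +
      rnorm(nrow(grid), 0, noise_sd)
    grid <- grid[order(grid$participant, grid$region, grid$contrast), ]
    rownames(grid) <- NULL
    attr(grid, "out.attrs") <- NULL
    class(grid) <- c("activation_dataset", "data.frame")
    grid
  })
}

#' Write / read an activation dataset as CSV
#'
#' @param data An `activation_dataset`.
#' @param path File path.
#' @return `read_activations_csv` returns an `activation_dataset`.
#' @export
write_activations_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activations_csv
#' @export
read_activations_csv <- function(path) {
  out <- read.csv(path, check.names = FALSE)
  class(out) <- c("activation_dataset", "data.frame")
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, undershoot ratio 1/6; normalized to a
#' unit peak.
#'
#' @param dt Sampling interval in seconds.
#' @param duration Kernel length in seconds.
#' @return Numeric vector of kernel weights.
#' @export
canonical_hrf <- function(dt = 0.1, duration = 32) {
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build driving and modulatory input regressors from a schedule
#'
#' Unit-height boxcars over the 1-3 s window after each main-stimulus
#' onset: the driving regressor covers every Quad and Linear trial, the
#' modulatory regressor the Quad trials only (so its support is a subset
#' of the driving support). Sampled on a fine time grid per session.
#'
#' @param schedule A `session_schedule`.
#' @param dt Grid step in seconds.
#' @param tr Scan repetition time in seconds.
#' @return A `dcm_regressors` list: `dt`, `tr`, `n_volumes`, and per-session
#'   lists with `u_d` and `u_m` vectors.
#' @export
build_design_regressors <- function(schedule, dt = 0.1, tr = TR_DEFAULT) {
  n_sessions <- attr(schedule, "n_sessions")
  if (is.null(n_sessions)) n_sessions <- max(schedule$session)
  trials_per_session <- if (nrow(schedule)) max(schedule$trial) else 0L
  session_secs <- trials_per_session * TRIAL_DUR
  n_steps <- round(session_secs / dt)
  sessions <- lapply(seq_len(n_sessions), function(s) {
    u_d <- numeric(max(n_steps, 1L))
    u_m <- numeric(max(n_steps, 1L))
    rows <- schedule[schedule$session == s, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      cond <- rows$condition[i]
      if (!cond %in% c("Linear", "Quad")) next
      onset <- (rows$trial[i] - 1) * TRIAL_DUR
      idx <- seq(round((onset + BOXCAR_WINDOW[1]) / dt) + 1L,
                 round((onset + BOXCAR_WINDOW[2]) / dt))
      u_d[idx] <- 1
      if (cond == "Quad") u_m[idx] <- 1
    }
    list(u_d = u_d, u_m = u_m)
  })
  structure(list(dt = dt, tr = tr,
                 n_volumes = as.integer(round(session_secs / tr)),
                 sessions = sessions),
            class = "dcm_regressors")
}

# 1-based grid indices of the scan volumes within one session
volume_grid_idx <- function(regressors) {
  round((seq_len(regressors$n_volumes) - 1L) * regressors$tr /
          regressors$dt) + 1L
}

#' Simulate a BOLD-like time series from a connectivity model
#'
#' Integrates the bilinear neural dynamics per session (states restart at
#' rest at each session boundary), convolves each region's neural state
#' with the canonical HRF, samples at the scan times, and adds iid
#' Gaussian observation noise.
#'
#' @param params A `dcm_params` object (see [dcm_params()]).
#' @param regressors A `dcm_regressors` object.
#' @param noise_sd Observation noise standard deviation.
#' @param seed Integer seed (only the noise is random).
#' @return A `bold_timeseries`: list with `y` (volumes x regions matrix),
#'   `session` index vector, `regions`, `tr`.
#' @export
simulate_bold <- function(params, regressors, noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(params, "dcm_params"),
            inherits(regressors, "dcm_regressors"))
  if (max(Re(eigen(params$A, only.values = TRUE)$values)) >= 0)
    stop("unstable intrinsic matrix: eigenvalue with non-negative real part",
         call. = FALSE)
  hrf <- canonical_hrf(regressors$dt)
  idx <- volume_grid_idx(regressors)
  ylist <- lapply(regressors$sessions, function(s) {
    dcm_forward_session_cpp(params$A, params$B, params$C, s$u_d, s$u_m,
                            regressors$dt, hrf, idx)
  })
  y <- do.call(rbind, ylist)
  if (any(!is.finite(y)))
    stop("integration diverged: non-finite states", call. = FALSE)
  colnames(y) <- DCM_REGIONS[seq_len(ncol(y))]
  with_seed(seed, y <- y + matrix(rnorm(length(y), 0, noise_sd), nrow(y)))
  structure(list(y = y,
                 session = rep(seq_along(regressors$sessions),
                               each = regressors$n_volumes),
                 regions = colnames(y), tr = regressors$tr),
            class = "bold_timeseries")
}

#' Write / read a BOLD time-series dataset as long CSV
#'
#' Columns `session`, `volume`, `region`, `bold`; the repetition time is
#' carried in a JSON sidecar written next to the CSV.
#'
#' @param ts A `bold_timeseries`.
#' @param path CSV file path (the sidecar gets extension `.json`).
#' @return `read_bold_csv` returns a `bold_timeseries`.
#' @export
write_bold_csv <- function(ts, path) {
  long <- do.call(rbind, lapply(ts$regions, function(r) {
    data.frame(session = ts$session,
               volume = ave(ts$session, ts$session, FUN = seq_along),
               region = r, bold = ts$y[, r])
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(tr = ts$tr, regions = ts$regions), side,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bold_csv
#' @export
read_bold_csv <- function(path) {
  long <- read.csv(path, check.names = FALSE)
  side <- jsonlite::fromJSON(sub("\\.csv$", ".json", path))
  regions <- side$regions
  nvol <- nrow(long) / length(regions)
  y <- sapply(regions, function(r) long$bold[long$region == r])
  structure(list(y = y, session = long$session[long$region == regions[1]],
                 regions = regions, tr = side$tr),
            class = "bold_timeseries")
}

# behavioral summary statistics used as simulator defaults: per-condition
# mean and sd of accuracy (%) and reaction time (ms)
BEHAVIOR_DEFAULTS <- list(
  accuracy = list(mean = c(Simple = 97.6, Linear = 98.5, Quad = 92.6,
                           Match = 98.8),
                  sd = c(Simple = 2.7, Linear = 2.9, Quad = 5.0,
                         Match = 1.4)),
  rt = list(mean = c(Simple = 838, Linear = 850, Quad = 895, Match = 931),
            sd = c(Simple = 151, Linear = 150, Quad = 174, Match = 172)))

#' Simulate per-participant behavioral data
#'
#' Accuracy (%) and reaction times (ms) drawn per condition from truncated
#' Normal distributions (accuracy clamped to 0-100, reaction times floored
#' at 200 ms) with the group-level means and standard deviations of the
#' study as defaults.
#'
#' @param n Number of participants (>= 2).
#' @param seed Integer seed.
#' @param defaults List with `accuracy` and `rt` mean/sd vectors.
#' @return Data.frame `participant`, `condition`, `accuracy`, `rt`.
#' @export
simulate_behavior <- function(n = 20L, seed = 1L,
                              defaults = BEHAVIOR_DEFAULTS) {
  stopifnot(n >= 2)
  with_seed(seed, {
    grid <- expand.grid(participant = seq_len(n), condition = CONDITIONS,
                        stringsAsFactors = FALSE)
    acc <- rnorm(nrow(grid), defaults$accuracy$mean[grid$condition],
                 defaults$accuracy$sd[grid$condition])
    rt <- rnorm(nrow(grid), defaults$rt$mean[grid$condition],
                defaults$rt$sd[grid$condition])
    grid$accuracy <- pmin(pmax(acc, 0), 100)
    grid$rt <- pmax(rt, 200)
    grid
  })
}
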