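# End-to-end pipeline: stimuli -> trees and factors -> synthetic
# activations -> factor-model comparison -> connectivity recovery, with a
# machine-readable summary.

#' Default pipeline configuration
#'
#' A flat list of every tunable of the pipeline, at the study's design
#' values: 48 arithmetic / 72 Match arrangements, 8 sessions of 36 trials,
#' 20 participants, the winning factor (`dom_hier`) with its per-region
#' fitted scales as generator truth, ML ranking, and the full 18-model
#' connectivity space.
#'
#' @param seed Global seed; every random stage derives its seed from it.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       n_arith = 48L, n_match = 72L, n_sessions = 8L,
       n_participants = 20L,
       factor = "dom_hier",
       participant_sd = 0.05, noise_sd = 0.05,
       criterion = "ML", deviation_alpha = 0.05 / 3,
       regions = PSC_REGIONS,
       dcm_noise_sd = 0.05, dcm_subject_sd = 0.1,
       dcm_models = 1:18, dcm_n_draws = 1e6L, dcm_dt = 0.1)
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- base
  out[names(config)] <- config
  out
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic data and writes all tables (CSV),
#' the connectivity report, and a machine-readable `summary.json`
#' (containing the seed, package version, and full configuration) to
#' `out_dir`. Deterministic: the same configuration yields byte-identical
#' outputs.
#'
#' @param config Configuration list (see [default_config()]); partial
#'   lists are completed with defaults, unknown keys are rejected.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  # stage 1: stimuli and schedule
  stimset <- generate_stimulus_set(cfg$n_arith, cfg$n_match,
                                   seed = cfg$seed)
  schedule <- build_sessions(stimset, seed = cfg$seed + 1L,
                             n_sessions = cfg$n_sessions)
  write_schedule_csv(schedule, path("schedule.csv"))

  # stage 2: trees and the factor estimate table
  est <- estimates_table()
  write_estimates_csv(est, path("estimates.csv"))
  ct_rows <- sapply(c(PSC_CONTRASTS, "Linear - Simple"),
                    function(ct) contrast_estimates(est, ct))
  write.csv(cbind(factor = rownames(est), as.data.frame(ct_rows)),
            path("contrast_estimates.csv"), row.names = FALSE, quote = FALSE)

  # stage 3: synthetic activations
  act <- simulate_activations(cfg$factor, participant_sd = cfg$participant_sd,
                              noise_sd = cfg$noise_sd,
                              n = cfg$n_participants, seed = cfg$seed + 2L,
                              regions = cfg$regions, table = est)
  write_activations_csv(act, path("activations.csv"))

  # stage 4: factor-model comparison per region
  best_factor <- list()
  for (region in cfg$regions) {
    cmp <- compare_factor_models(act, region, table = est,
                                 criterion = cfg$criterion,
                                 alpha = cfg$deviation_alpha)
    write_comparison_csv(cmp, path(paste0("comparison_",
                                          gsub("[^A-Za-z]", "_", region),
                                          ".csv")))
    best_factor[[region]] <- cmp$factor[1]
  }

  # stage 5: connectivity recovery
  rec <- run_recovery_study(n = cfg$n_participants, seed = cfg$seed + 3L,
                            subject_sd = cfg$dcm_subject_sd,
                            noise_sd = cfg$dcm_noise_sd,
                            n_sessions = cfg$n_sessions,
                            models = cfg$dcm_models,
                            n_draws = cfg$dcm_n_draws)
  jsonlite::write_json(
    list(models = rec$models, alpha = rec$bms$alpha,
         expected_prob = rec$bms$expected_prob,
         exceedance_prob = rec$bms$exceedance_prob,
         winning_model = rec$winning_model,
         group_mean = as.list(colMeans(rec$theta_hat))),
    path("recovery.json"), auto_unbox = TRUE, digits = NA)

  summary <- list(
    package_version = as.character(utils::packageVersion("domarith")),
    config = cfg,
    n_valid_stimuli = length(all_valid_stimuli()),
    estimates = as.list(est),
    best_factor_by_region = best_factor,
    recovery = list(winning_model = rec$winning_model,
                    exceedance = max(rec$bms$exceedance_prob),
                    group_mean = as.list(colMeans(rec$theta_hat))))
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Small in-memory fixture bundle for fast examples and tests
#'
#' The worked five-digit stimulus (3, 7 upper, 2, 4, 9 lower) under all
#' four conditions, a small synthetic activation dataset, and a
#' two-participant single-session connectivity dataset.
#'
#' @param seed Integer seed.
#' @return List with `worked_trials`, `activations`, and `dcm`
#'   (`schedule`, `regressors`, `bold` list, `params` list).
#' @export
make_fixtures <- function(seed = 1L) {
  digits <- c(3L, 7L, 2L, 4L, 9L)
  worked <- lapply(setNames(CONDITIONS, CONDITIONS),
                   function(cond) build_trial_forest(cond, digits))
  act <- simulate_activations(n = 4L, seed = seed,
                              regions = c("L_IFG", "L_SMG"))
  stimset <- generate_stimulus_set(6L, 9L, seed = seed)
  schedule <- build_sessions(stimset, seed = seed, n_sessions = 1L)
  regressors <- build_design_regressors(schedule)
  model1 <- enumerate_models()[[1]]
  bold <- list()
  params <- list()
  for (p in 1:2) {
    params[[p]] <- dcm_params(model1, TRUE_DCM_PARAMS$a, TRUE_DCM_PARAMS$b,
                              TRUE_DCM_PARAMS$c_input)
    bold[[p]] <- simulate_bold(params[[p]], regressors, noise_sd = 0.05,
                               seed = seed + p)
  }
  list(worked_trials = worked, activations = act,
       dcm = list(schedule = schedule, regressors = regressors,
                  bold = bold, params = params, model = model1))
}
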