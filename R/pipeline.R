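# End-to-end pipeline: simulate -> synthesize gaze -> detect -> classify ->
# measure -> fit -> (optionally) bootstrap, with per-experiment default
# model specifications mirroring the analysis plan.

#' Pipeline configuration
#'
#' @param experiment 1, 2 or 3.
#' @param n_participants Cohort size.
#' @param seed Master seed (all randomness derives from it).
#' @param n_boot Parametric-bootstrap replications for the fitted models
#'   (0 skips the bootstrap; final inference uses 10,000).
#' @param gaze_params,joc_params,policy Overrides of the cohort defaults.
#' @param cluster_b K-quantiles initializations.
#' @param prop_distant Also fit the proportion-of-Distant-fixations model.
#' @param out_dir Output directory for artifacts (`NULL`: in memory only).
#' @param max_trials_per_session Smoke-testing cap (default: full session).
#' @return A `dodge_pipelineconfig` list.
#' @export
pipeline_config <- function(experiment, n_participants = 25L, seed = 1L,
                            n_boot = 0L,
                            gaze_params = dodgegaze::gaze_params(experiment),
                            joc_params = dodgegaze::joc_params(experiment),
                            policy = greedy_gap_policy(),
                            cluster_b = 50L, prop_distant = FALSE,
                            out_dir = NULL, max_trials_per_session = Inf) {
  structure(list(experiment = as.integer(experiment),
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed), n_boot = as.integer(n_boot),
                 gaze_params = gaze_params, joc_params = joc_params,
                 policy = policy, cluster_b = as.integer(cluster_b),
                 prop_distant = isTRUE(prop_distant), out_dir = out_dir,
                 max_trials_per_session = max_trials_per_session),
            class = "dodge_pipelineconfig")
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; failures are reported, not thrown.
#'
#' @param config A `dodge_pipelineconfig`.
#' @return A data.frame (`check`, `ok`, `note`) with attribute `"valid"`.
#' @export
validate_config <- function(config) {
  checks <- list()
  add <- function(check, ok, note = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, ok = ok, note = note)
  }
  add("class", inherits(config, "dodge_pipelineconfig"),
      "config must come from pipeline_config()")
  add("experiment", isTRUE(config$experiment %in% 1:3), "experiment must be 1, 2 or 3")
  add("seed", is.numeric(config$seed) && length(config$seed) == 1L &&
        is.finite(config$seed), "an explicit integer seed is required")
  add("n_participants", isTRUE(config$n_participants >= 2),
      "at least two participants")
  gp <- config$gaze_params
  add("gaze_params", inherits(gp, "dodge_gazeparams"), "use gaze_params()")
  if (inherits(gp, "dodge_gazeparams")) {
    add("mixture_order", gp$distant_mean > gp$close_mean,
        "Distant component must lie beyond the Close component")
    add("jitter", gp$intra_fixation_jitter_px < 1.25 / 3,
        "intra-fixation jitter must stay well below the 1.25-px threshold")
  }
  if (isTRUE(config$experiment == 2L)) {
    specs <- enumerate_configurations(2, seed = config$seed)
    add("exp2_no_drift", !any(vapply(specs, `[[`, NA, "drift_enabled")),
        "Experiment 2 forbids drift")
  }
  out <- do.call(rbind, checks)
  attr(out, "valid") <- all(out$ok)
  out
}

# Per-experiment model specifications. Distance responses use Box-Cox
# transform selection; input noise enters as a factor with
# successive-difference contrasts in distance/JoC models; completion is a
# Bernoulli-link model of the raw attempts (treatment contrasts in
# Experiment 1, successive differences in Experiment 2, matching how each
# comparison is reported).
default_model_specs <- function(experiment) {
  noise_sdif <- list(noise_f = "successive_difference")
  if (experiment == 1L) {
    list(
      close = model_spec("dist_to_ship_deg",
        "n_obstacles_on_screen + n_drift_sections_on_screen + noise_f",
        transform = "auto", contrasts = noise_sdif),
      distant = model_spec("dist_to_ship_deg",
        "n_obstacles_on_screen + n_drift_sections_on_screen + noise_f",
        transform = "auto", contrasts = noise_sdif),
      joc = model_spec("joc",
        "completed + difficulty * drift_enabled + noise_f + n_fixations + consecutive_crash_completions",
        contrasts = list(noise_f = "treatment")),
      completion = model_spec("completed", "difficulty + noise_f + drift_enabled",
        family = "bernoulli", contrasts = list(noise_f = "treatment"))
    )
  } else if (experiment == 2L) {
    list(
      close = model_spec("dist_to_ship_deg", "n_obstacles_on_screen + noise_f",
        transform = "auto", contrasts = noise_sdif),
      distant = model_spec("dist_to_ship_deg", "n_obstacles_on_screen + noise_f",
        transform = "auto", contrasts = noise_sdif),
      joc = model_spec("joc",
        "completed + difficulty + noise_f + n_fixations + consecutive_crash_completions",
        contrasts = noise_sdif),
      completion = model_spec("completed", "difficulty + noise_f",
        family = "bernoulli", contrasts = noise_sdif)
    )
  } else {
    list(
      close = model_spec("dist_to_ship_deg",
        "n_obstacles_on_screen + n_drift_sections_on_screen + block",
        transform = "auto"),
      distant = model_spec("dist_to_ship_deg",
        "n_obstacles_on_screen + n_drift_sections_on_screen + block",
        transform = "auto"),
      joc = model_spec("joc",
        "completed + difficulty + block + n_fixations + consecutive_crash_completions"),
      completion = model_spec("completed", "difficulty + block",
        family = "bernoulli")
    )
  }
}

# Factor preparation shared by the model stages.
prepare_factors <- function(df, experiment) {
  lev <- sort(unique(df$noise_sd))
  df$noise_f <- factor(as.character(df$noise_sd), levels = as.character(lev))
  df$difficulty <- factor(df$difficulty,
                          levels = intersect(c("easy", "medium", "hard"),
                                             unique(df$difficulty)))
  if (experiment == 3L) {
    df$block <- factor(df$block, levels = c("normal", "invisible", "fake"))
  }
  df$participant <- factor(df$participant)
  df
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort, splits fixations into Close and Distant by
#' k-quantiles clustering of the distance to the ship, and fits the four
#' model families: Close distance, Distant distance, judgment of control,
#' and completion probability (plus, optionally, the proportion of Distant
#' fixations). With `n_boot > 0` each model's coefficients get parametric
#' bootstrap HDIs. With `out_dir` set, tables, the split summary and
#' coefficient tables are written as CSV/JSON, stamped with the config
#' hash.
#'
#' @param config A `dodge_pipelineconfig`.
#' @return A `dodge_pipelineresult`: list with `tables` (fixations, trials),
#'   `split`, `models`, `config`.
#' @export
run_pipeline <- function(config) {
  report <- validate_config(config)
  if (!isTRUE(attr(report, "valid"))) {
    bad <- report[!report$ok, ]
    stop("invalid pipeline config: ",
         paste(sprintf("%s (%s)", bad$check, bad$note), collapse = "; "))
  }
  cspec <- cohort_spec(config$n_participants, config$experiment, config$seed,
                       gaze_params = config$gaze_params,
                       joc_params = config$joc_params, policy = config$policy,
                       max_trials_per_session = config$max_trials_per_session)
  cohort <- make_cohort(cspec)
  fixations <- prepare_factors(cohort$fixations, config$experiment)
  trials <- prepare_factors(cohort$trials, config$experiment)

  split <- kquantiles_fit(fixations$dist_to_ship_deg, b = config$cluster_b,
                          seed = derive_seed(config$seed, "kq"))
  fixations <- apply_split(fixations, split)
  n_distant <- tapply(fixations$class == "distant",
                      paste(fixations$participant, fixations$trial), sum)
  key <- paste(trials$participant, trials$trial)
  trials$n_distant <- as.integer(n_distant[key])
  trials$n_distant[is.na(trials$n_distant)] <- 0L

  specs <- default_model_specs(config$experiment)
  models <- list(
    close = fit_mixed(fixations[fixations$class == "close", ], specs$close),
    distant = fit_mixed(fixations[fixations$class == "distant", ], specs$distant),
    joc = fit_mixed(trials, specs$joc),
    completion = fit_mixed(trials, specs$completion)
  )
  if (config$prop_distant) {
    models$prop_distant <- proportion_distant_model(
      trials,
      fixed = if (config$experiment == 1L) "difficulty * drift_enabled"
              else if (config$experiment == 2L) "difficulty + noise_f"
              else "difficulty + block")
  }
  if (config$n_boot > 0L) {
    for (nm in names(models)) {
      models[[nm]] <- parametric_bootstrap(models[[nm]], config$n_boot,
                                           seed = derive_seed(config$seed, "boot", nm))
    }
  }
  result <- structure(list(tables = list(fixations = fixations, trials = trials),
                           split = split, models = models, config = config),
                      class = "dodge_pipelineresult")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  result
}

#' @export
print.dodge_pipelineresult <- function(x, ...) {
  cat(sprintf("<dodge_pipelineresult> exp %d, %d participants: %d fixations (%d close / %d distant), %d trials\n",
              x$config$experiment, x$config$n_participants,
              nrow(x$tables$fixations), sum(x$tables$fixations$class == "close"),
              sum(x$tables$fixations$class == "distant"), nrow(x$tables$trials)))
  cat(sprintf("  split threshold: %.2f deg\n", x$split$threshold_deg))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    sig <- m$coefficients$term[m$coefficients$significant &
                                 m$coefficients$term != "(Intercept)"]
    cat(sprintf("  %s [%s, %s]: significant: %s\n", nm, m$family, m$transform,
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}

write_pipeline_artifacts <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = content_hash(result$config[
    setdiff(names(result$config), "out_dir")]),
    package_version = as.character(utils::packageVersion("dodgegaze")))
  utils::write.csv(result$tables$fixations,
                   file.path(dir, "fixation_table.csv"), row.names = FALSE)
  utils::write.csv(result$tables$trials,
                   file.path(dir, "trial_table.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(stamp, list(threshold_deg = result$split$threshold_deg,
                  class_counts = as.list(result$split$n),
                  objective = result$split$objective)),
    file.path(dir, "split_summary.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(result$models)) {
    utils::write.csv(result$models[[nm]]$coefficients,
                     file.path(dir, sprintf("model_%s.csv", nm)),
                     row.names = FALSE)
  }
  jsonlite::write_json(stamp, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Sign-recovery report against planted generator effects
#'
#' For a fitted pipeline result, extracts the coefficients that correspond
#' to the planted generator effects of its experiment and reports, per
#' target, the fitted sign, z-score, and whether the planted sign is
#' recovered at |z| >= 2.
#'
#' @param result A `dodge_pipelineresult`.
#' @return A data.frame (`target`, `model`, `term`, `planted_sign`, `beta`,
#'   `z`, `recovered`).
#' @export
sign_recovery_report <- function(result) {
  exp <- result$config$experiment
  targets <- if (exp == 1L) {
    data.frame(
      target = c("obstacles_up_close", "obstacles_up_distant",
                 "strong_noise_down_close", "noise_down_completion"),
      model = c("close", "distant", "close", "completion"),
      term = c("n_obstacles_on_screen", "n_obstacles_on_screen",
               "noise_f6-3", "noise_f6"),
      planted_sign = c(1, 1, -1, -1)
    )
  } else if (exp == 2L) {
    data.frame(
      target = c("obstacles_up_close", "obstacles_up_distant",
                 "noise3_up_close", "noise6_down_close",
                 "noise_down_completion"),
      model = c("close", "distant", "close", "close", "completion"),
      # sum: the total effect across all successive noise differences,
      # i.e. the highest noise level's log-odds against the baseline
      term = c("n_obstacles_on_screen", "n_obstacles_on_screen",
               "noise_f3-0", "noise_f6-3", "sum:noise_f"),
      planted_sign = c(1, 1, 1, -1, -1)
    )
  } else {
    data.frame(
      target = c("obstacles_up_close", "drift_sections_up_distant",
                 "invisible_block_down_joc"),
      model = c("close", "distant", "joc"),
      term = c("n_obstacles_on_screen", "n_drift_sections_on_screen",
               "blockinvisible"),
      planted_sign = c(1, 1, -1)
    )
  }
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    m <- result$models[[targets$model[i]]]
    co <- m$coefficients
    if (startsWith(targets$term[i], "sum:")) {
      # linear contrast: sum of all coefficients with the given prefix
      # (for successive differences, the last level against the first)
      pre <- sub("^sum:", "", targets$term[i])
      j <- grep(paste0("^", pre), co$term)
      beta <- sum(co$beta[j])
      se <- if (is.null(m$vcov)) NA_real_ else sqrt(sum(m$vcov[j, j]))
      z <- beta / se
    } else {
      j <- match(targets$term[i], co$term)
      beta <- co$beta[j]; z <- co$z[j]
    }
    # on a reciprocal-type fitted scale the response ordering flips
    flip <- if (m$transform %in% c("reciprocal", "reciprocal_of_log")) -1 else 1
    data.frame(targets[i, ], beta = beta, z = z,
               recovered = !is.na(z) &&
                 sign(beta) * flip == targets$planted_sign[i] &&
                 abs(z) >= 2)
  })
  do.call(rbind, rows)
}
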