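# Synthetic cohorts: sessions, gaze, detection and measures for a set of
# simulated participants, streamed trial by trial so only the analysis
# tables are kept in memory.

#' Cohort specification
#'
#' @param n_participants Number of synthetic participants (>= 2).
#' @param experiment 1, 2 or 3.
#' @param seed Master seed; every participant, trial and fixation stream
#'   derives its own seed from it.
#' @param gaze_params A `dodge_gazeparams` (defaults for the experiment).
#' @param joc_params A `dodge_jocparams` (defaults for the experiment).
#' @param policy Base `dodge_policy`; each participant plays with a skill
#'   drawn around the base skill (SD 0.04), which is what gives the
#'   completion model its per-participant random intercept.
#' @param max_trials_per_session Cap on logged attempts per session
#'   (smoke-testing knob; the study conditions use the full queue).
#' @return A `dodge_cohortspec` list.
#' @export
cohort_spec <- function(n_participants, experiment, seed = 1L,
                        gaze_params = dodgegaze::gaze_params(experiment),
                        joc_params = dodgegaze::joc_params(experiment),
                        policy = greedy_gap_policy(),
                        max_trials_per_session = Inf) {
  stopifnot(n_participants >= 2)
  structure(list(n_participants = as.integer(n_participants),
                 experiment = as.integer(experiment), seed = as.integer(seed),
                 gaze_params = gaze_params, joc_params = joc_params,
                 policy = policy,
                 max_trials_per_session = max_trials_per_session),
            class = "dodge_cohortspec")
}

# One participant: session, per-trial gaze synthesis + event detection,
# measures, and judgments. Gaze streams are discarded after detection
# unless a sink function is given (used by make_cohort to write CSVs).
simulate_participant <- function(spec, pid, layouts, gaze_sink = NULL) {
  pseed <- derive_seed(spec$seed, "participant", pid)
  intercept <- with_seed(derive_seed(pseed, "icpt"),
                         stats::rnorm(1L, 0, spec$gaze_params$participant_sd))
  pol <- spec$policy
  if (pol$name == "greedy_gap") {
    pol$params$skill <- with_seed(derive_seed(pseed, "skill"),
                                  min(max(stats::rnorm(1L, pol$params$skill, 0.04),
                                          0.5), 1))
  }
  session <- run_session(spec$experiment, pol, seed = pseed, layouts = layouts,
                         counterbalance = pid %% 2L == 0L)
  if (is.finite(spec$max_trials_per_session)) {
    keep <- seq_len(min(length(session$logs), spec$max_trials_per_session))
    session$logs <- session$logs[keep]
  }
  events <- list()
  for (i in seq_along(session$logs)) {
    log <- session$logs[[i]]
    if (isTRUE(log$training)) next
    gaze <- synth_trial_gaze(log, spec$gaze_params, intercept,
                             seed = derive_seed(pseed, "gaze", i))
    if (!is.null(gaze_sink)) gaze_sink(pid, i, gaze)
    events[[as.character(i)]] <- detect_fixations(gaze)
  }
  pname <- sprintf("p%02d", pid)
  tabs <- build_tables(events, session, participant = pname)
  if (!is.null(tabs$trials)) {
    tabs$trials$joc <- synth_joc(tabs$trials, spec$joc_params, intercept,
                                 seed = derive_seed(pseed, "joc"))
  }
  tabs$session <- session
  tabs$intercept <- intercept
  tabs
}

#' Generate a synthetic cohort
#'
#' Runs every participant's session, synthesizes and detects gaze trial by
#' trial, and assembles the pooled fixation and trial tables. With `dir`
#' set, the bundle is written to disk: layouts as JSON, both tables as CSV,
#' a manifest JSON with seeds and content hashes, and (optionally) the raw
#' gaze streams as CSV.
#'
#' @param spec A `dodge_cohortspec`.
#' @param dir Output directory (`NULL` keeps everything in memory).
#' @param write_gaze Also write per-trial gaze CSVs (large).
#' @return A list with `fixations`, `trials`, `manifest`.
#' @export
make_cohort <- function(spec, dir = NULL, write_gaze = FALSE) {
  stopifnot(inherits(spec, "dodge_cohortspec"))
  layouts <- make_experiment_layouts(spec$experiment, spec$seed)
  sink_fn <- NULL
  if (!is.null(dir)) {
    dir.create(file.path(dir, "gaze"), recursive = TRUE, showWarnings = FALSE)
    for (lay in layouts) {
      write_layout_json(lay, file.path(dir, paste0("layout_", lay$id, ".json")))
    }
    if (write_gaze) {
      sink_fn <- function(pid, trial, gaze) {
        utils::write.csv(gaze, file.path(dir, "gaze",
                                         sprintf("p%02d_t%03d.csv", pid, trial)),
                         row.names = FALSE)
      }
    }
  }
  fx <- list(); tr <- list()
  for (pid in seq_len(spec$n_participants)) {
    part <- simulate_participant(spec, pid, layouts, gaze_sink = sink_fn)
    fx[[pid]] <- part$fixations
    tr[[pid]] <- part$trials
  }
  fixations <- do.call(rbind, fx[!vapply(fx, is.null, NA)])
  trials <- do.call(rbind, tr[!vapply(tr, is.null, NA)])
  manifest <- list(
    experiment = spec$experiment, n_participants = spec$n_participants,
    seed = spec$seed, layout_ids = names(layouts),
    n_fixations = nrow(fixations), n_trials = nrow(trials),
    fixation_hash = content_hash(fixations), trial_hash = content_hash(trials)
  )
  if (!is.null(dir)) {
    utils::write.csv(fixations, file.path(dir, "fixations.csv"), row.names = FALSE)
    utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fixations = fixations, trials = trials, manifest = manifest)
}
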