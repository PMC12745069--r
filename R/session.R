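# One synthetic participant's session: randomized configuration queue with
# crash requeue (max three attempts per configuration), training before the
# main part, and the Experiment-3 block order (normal first, invisible/fake
# counterbalanced), with a baseline training configuration between blocks.

#' Run a full session for one (synthetic) participant
#'
#' Draws configurations in randomized order; a completed configuration is
#' removed, a crashed one is mixed back into the queue, and after three
#' crashed attempts a configuration is dropped. Training trials (initial
#' training, and in Experiment 3 the baseline configurations between
#' blocks) are logged with `training = TRUE` and are excluded from analysis
#' tables downstream.
#'
#' @param experiment 1, 2 or 3.
#' @param policy A `dodge_policy`.
#' @param seed Integer seed.
#' @param layouts Optional layout list (generated from `seed` if missing).
#' @param counterbalance Logical; Experiment-3 only: `FALSE` plays the
#'   invisible block before the fake block, `TRUE` the reverse.
#' @param include_training Include training configurations.
#' @return A `dodge_session`: list with `logs` (list of `dodge_triallog`),
#'   `layouts`, `specs`, `experiment`, `seed`.
#' @export
run_session <- function(experiment, policy = greedy_gap_policy(), seed = 1L,
                        layouts = NULL, counterbalance = FALSE,
                        include_training = TRUE) {
  experiment <- as.integer(experiment)
  if (is.null(layouts)) layouts <- make_experiment_layouts(experiment, seed)
  specs <- enumerate_configurations(experiment, layouts, seed)
  logs <- list()
  trial_counter <- 0L

  play_queue <- function(queue, lays) {
    attempts <- stats::setNames(integer(length(queue)),
                                vapply(queue, `[[`, "", "spec_id"))
    active <- seq_along(queue)
    while (length(active) > 0L) {
      trial_counter <<- trial_counter + 1L
      pick <- if (length(active) == 1L) active else
        with_seed(derive_seed(seed, "order", trial_counter),
                  sample(active, 1L))
      sp <- queue[[pick]]
      attempts[sp$spec_id] <- attempts[sp$spec_id] + 1L
      log <- run_trial(sp, lays[[sp$layout_id]], policy,
                       seed = derive_seed(seed, "trial", trial_counter))
      log$attempt_index <- unname(attempts[sp$spec_id])
      logs[[length(logs) + 1L]] <<- log
      if (log$outcome == "completed" || attempts[sp$spec_id] >= 3L) {
        active <- setdiff(active, pick)
      }
    }
  }

  play_training <- function() {
    tr <- training_config(experiment, seed)
    for (a in 1:3) {
      trial_counter <<- trial_counter + 1L
      log <- run_trial(tr$spec, tr$layout, policy,
                       seed = derive_seed(seed, "trial", trial_counter))
      log$attempt_index <- a
      logs[[length(logs) + 1L]] <<- log
      if (log$outcome == "completed") break
    }
  }

  if (include_training) play_training()
  if (experiment == 3L) {
    blocks <- c("normal", if (counterbalance) c("fake", "invisible")
                          else c("invisible", "fake"))
    for (b in seq_along(blocks)) {
      if (b > 1L && include_training) play_training()
      play_queue(Filter(function(s) s$block == blocks[b], specs), layouts)
    }
  } else {
    play_queue(specs, layouts)
  }

  structure(list(logs = logs, layouts = layouts, specs = specs,
                 experiment = experiment, seed = seed,
                 counterbalance = counterbalance),
            class = "dodge_session")
}

#' @export
print.dodge_session <- function(x, ...) {
  outc <- vapply(x$logs, `[[`, "", "outcome")
  tr <- vapply(x$logs, function(l) isTRUE(l$training), NA)
  cat(sprintf("<dodge_session> exp %d: %d trials (%d training), %d completed, %d crashed\n",
              x$experiment, length(x$logs), sum(tr),
              sum(outc == "completed" & !tr), sum(outc == "crashed" & !tr)))
  invisible(x)
}

#' Per-attempt summary table of a session
#'
#' One row per logged attempt, in chronological order; training attempts are
#' flagged. This is the trial-level backbone that measures and the judgment
#' generator build on.
#'
#' @param session A `dodge_session`.
#' @return A data.frame with columns `trial`, `spec_id`, `layout_id`,
#'   `difficulty`, `noise_sd`, `drift_enabled`, `block`, `attempt`,
#'   `outcome`, `completed`, `n_frames`, `training`.
#' @export
session_table <- function(session) {
  logs <- session$logs
  data.frame(
    trial = seq_along(logs),
    spec_id = vapply(logs, function(l) l$spec$spec_id, ""),
    layout_id = vapply(logs, `[[`, "", "layout_id"),
    difficulty = vapply(logs, function(l) {
      lay <- session$layouts[[l$layout_id]]
      if (is.null(lay)) "easy" else lay$difficulty  # training layout
    }, ""),
    noise_sd = vapply(logs, function(l) l$spec$input_noise_sd, 0),
    drift_enabled = vapply(logs, function(l) isTRUE(l$spec$drift_enabled), NA),
    block = vapply(logs, function(l) l$spec$block, ""),
    attempt = vapply(logs, `[[`, 0L, "attempt_index"),
    outcome = vapply(logs, `[[`, "", "outcome"),
    completed = vapply(logs, `[[`, "", "outcome") == "completed",
    n_frames = vapply(logs, `[[`, 0L, "n_frames"),
    training = vapply(logs, function(l) isTRUE(l$training), NA),
    stringsAsFactors = FALSE
  )
}
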