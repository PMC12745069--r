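# Experiment designs: layout sets and trial configurations.

#' Generate the six layouts of an experiment
#'
#' Experiment 1 uses three 9000-px and three 18,000-px layouts, one of each
#' difficulty per length. Experiments 2 and 3 use six 13,500-px layouts,
#' three medium and three hard; Experiment 3 layouts carry eight drift
#' sections at positions fixed per layout, Experiment 2 layouts none.
#'
#' @param experiment 1, 2 or 3.
#' @param seed Integer master seed.
#' @return A named list of six `dodge_layout` objects.
#' @export
make_experiment_layouts <- function(experiment, seed = 1L) {
  experiment <- as.integer(experiment)
  stopifnot(experiment %in% 1:3)
  layouts <- list()
  if (experiment == 1L) {
    i <- 0L
    for (len in c(9000L, 18000L)) for (d in c("easy", "medium", "hard")) {
      i <- i + 1L
      layouts[[i]] <- generate_layout(len, d, seed = derive_seed(seed, "lay", 1, i))
    }
  } else {
    nd <- if (experiment == 3L) 8L else 0L
    i <- 0L
    for (d in c("medium", "hard")) for (k in 1:3) {
      i <- i + 1L
      layouts[[i]] <- generate_layout(
        13500L, d, n_drift_sections = nd,
        seed = derive_seed(seed, "lay", experiment, i),
        id = sprintf("E%d_%s_%d", experiment, d, k)
      )
    }
  }
  names(layouts) <- vapply(layouts, `[[`, "", "id")
  layouts
}

#' Enumerate the trial configurations of an experiment
#'
#' Experiment 1 crosses 6 layouts with input-noise SD in \{0, 3, 6\} px and
#' drift on/off (36 configurations). Experiment 2 crosses 6 layouts with
#' noise SD in \{0, 3, 6, 9, 12\} px, no drift (30). Experiment 3 crosses 6
#' layouts with three blocks (normal, invisible, fake) and, per layout and
#' block, the two complementary assignments of the block's special drift
#' type to half of the eight sections (36).
#'
#' @param experiment 1, 2 or 3.
#' @param layouts Layout list from [make_experiment_layouts()].
#' @param seed Seed used only to fix each Experiment-3 layout's half-set of
#'   special sections.
#' @return A list of `dodge_trialspec` objects, each with fields
#'   `spec_id`, `layout_id`, `experiment`, `input_noise_sd`, `drift_enabled`,
#'   `block`, `section_types` (character per drift section: `"normal"`,
#'   `"invisible"`, `"fake"` or `"off"`).
#' @export
enumerate_configurations <- function(experiment, layouts = NULL, seed = 1L) {
  experiment <- as.integer(experiment)
  stopifnot(experiment %in% 1:3)
  if (is.null(layouts)) layouts <- make_experiment_layouts(experiment, seed)
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  if (experiment == 1L) {
    for (lid in names(layouts)) for (sd in c(0, 3, 6)) for (drift in c(TRUE, FALSE)) {
      n_sec <- nrow(layouts[[lid]]$drift_sections)
      add(new_trialspec(
        layout_id = lid, experiment = 1L, input_noise_sd = sd,
        drift_enabled = drift, block = "none",
        section_types = rep(if (drift) "normal" else "off", n_sec)
      ))
    }
  } else if (experiment == 2L) {
    for (lid in names(layouts)) for (sd in c(0, 3, 6, 9, 12)) {
      add(new_trialspec(
        layout_id = lid, experiment = 2L, input_noise_sd = sd,
        drift_enabled = FALSE, block = "none", section_types = character(0)
      ))
    }
  } else {
    for (lid in names(layouts)) {
      n_sec <- nrow(layouts[[lid]]$drift_sections)
      half <- with_seed(derive_seed(seed, "half", lid),
                        sort(sample(n_sec, n_sec %/% 2L)))
      for (block in c("normal", "invisible", "fake")) {
        special <- switch(block, normal = "off", invisible = "invisible", fake = "fake")
        for (assignment in 1:2) {
          types <- rep("normal", n_sec)
          idx <- if (assignment == 1L) half else setdiff(seq_len(n_sec), half)
          types[idx] <- special
          add(new_trialspec(
            layout_id = lid, experiment = 3L, input_noise_sd = 0,
            drift_enabled = TRUE, block = block, section_types = types
          ))
        }
      }
    }
  }
  for (i in seq_along(specs)) specs[[i]]$spec_id <- sprintf("cfg%02d", i)
  specs
}

new_trialspec <- function(layout_id, experiment, input_noise_sd, drift_enabled,
                          block, section_types, training = FALSE,
                          manipulation_from_y = 0) {
  structure(list(
    spec_id = NA_character_, layout_id = layout_id, experiment = experiment,
    input_noise_sd = input_noise_sd, drift_enabled = drift_enabled,
    block = block, section_types = section_types,
    training = training, manipulation_from_y = manipulation_from_y
  ), class = "dodge_trialspec")
}

#' @export
print.dodge_trialspec <- function(x, ...) {
  cat(sprintf("<dodge_trialspec %s> layout=%s exp=%d noise_sd=%g drift=%s block=%s%s\n",
              x$spec_id, x$layout_id, x$experiment, x$input_noise_sd,
              if (x$drift_enabled) "on" else "off", x$block,
              if (isTRUE(x$training)) " [training]" else ""))
  invisible(x)
}

#' Difficulty label of the layout a spec points to
#' @param spec A `dodge_trialspec`.
#' @param layouts Layout list.
#' @return Character difficulty.
#' @export
spec_difficulty <- function(spec, layouts) layouts[[spec$layout_id]]$difficulty

# Training configuration per procedure: an 18,000-px layout with easy
# statistics; the manipulation (noise sd 3 in Exp 1/2, drift in Exp 1/3)
# kicks in from halfway through the layout.
training_config <- function(experiment, seed) {
  lay <- generate_layout(18000L, "easy", seed = derive_seed(seed, "training"),
                         id = sprintf("training_E%d", experiment), training = TRUE)
  n_sec <- nrow(lay$drift_sections)
  spec <- new_trialspec(
    layout_id = lay$id, experiment = as.integer(experiment),
    input_noise_sd = if (experiment %in% c(1L, 2L)) 3 else 0,
    drift_enabled = experiment %in% c(1L, 3L),
    block = "none",
    section_types = rep(if (experiment %in% c(1L, 3L)) "normal" else "off", n_sec),
    training = TRUE, manipulation_from_y = 9000
  )
  spec$spec_id <- "training"
  list(layout = lay, spec = spec)
}
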