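#' Experimental design for a bucket-vs-arithmetic choice experiment
#'
#' Describes the fully crossed within-participant design: bucket weight x
#' cognitive-task difficulty x imposed cognitive-task duration x bucket side,
#' with a fixed number of trials per combination. The default instantiation is
#' the 2 x 2 x 3 x 2 design with one trial per combination (24 trials per
#' participant): weights 0.0 and 3.2 kg, two difficulty levels, durations 9,
#' 18 and 27 s anchored at the ~18 s walk time, bucket on the left or right.
#'
#' Difficulty levels are ordered from easiest to hardest; their rank is their
#' position in `difficulties`.
#'
#' @param weights numeric bucket masses in kg (unique).
#' @param difficulties character difficulty labels, easiest first.
#' @param durations numeric imposed durations of the cognitive task, seconds.
#' @param sides character bucket locations.
#' @param trials_per_combination positive integer, trials per design cell.
#' @param n_participants positive integer.
#' @param loaded_weight which element of `weights` is the loaded bucket; the
#'   remaining weight is the empty bucket. The mapping is declared, never
#'   inferred from the data.
#' @return An object of class `"experiment_design"`.
#' @examples
#' d <- experiment_design()
#' n_cells(d)          # 12 collapsed cells
#' n_trials(d)         # 24 trials per participant
#' @export
experiment_design <- function(weights = c(0.0, 3.2),
                              difficulties = c("easy", "hard"),
                              durations = c(9, 18, 27),
                              sides = c("left", "right"),
                              trials_per_combination = 1L,
                              n_participants = 48L,
                              loaded_weight = max(weights)) {
  stopifnot(is.numeric(weights), is.character(difficulties),
            is.numeric(durations), is.character(sides))
  for (nm in c("weights", "difficulties", "durations", "sides")) {
    v <- get(nm)
    if (length(v) == 0L) stop("'", nm, "' must be non-empty")
    if (anyDuplicated(v)) stop("'", nm, "' must have unique levels")
  }
  if (!is.numeric(trials_per_combination) || trials_per_combination < 1)
    stop("'trials_per_combination' must be a positive integer")
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("'n_participants' must be a positive integer")
  if (!loaded_weight %in% weights)
    stop("'loaded_weight' must be one of 'weights'")
  structure(list(weights = weights,
                 difficulties = difficulties,
                 durations = durations,
                 sides = sides,
                 trials_per_combination = as.integer(trials_per_combination),
                 n_participants = as.integer(n_participants),
                 loaded_weight = loaded_weight),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Within-participant choice design\n")
  cat("  weights (kg):   ", paste(x$weights, collapse = ", "),
      " (loaded: ", x$loaded_weight, ")\n", sep = "")
  cat("  difficulties:   ", paste(x$difficulties, collapse = " < "), "\n", sep = "")
  cat("  durations (s):  ", paste(x$durations, collapse = ", "), "\n", sep = "")
  cat("  sides:          ", paste(x$sides, collapse = ", "), "\n", sep = "")
  cat("  trials/cell:    ", x$trials_per_combination, "\n", sep = "")
  cat("  participants:   ", x$n_participants, "\n", sep = "")
  cat("  trials/participant: ", n_trials(x), "\n", sep = "")
  invisible(x)
}

#' Number of collapsed design cells (weight x difficulty x duration)
#' @param design an [experiment_design()].
#' @return integer
#' @export
n_cells <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  length(design$weights) * length(design$difficulties) * length(design$durations)
}

#' Number of trials each participant contributes
#' @param design an [experiment_design()].
#' @return integer
#' @export
n_trials <- function(design) {
  n_cells(design) * length(design$sides) * design$trials_per_combination
}

#' Declare which factor levels play which role in the Phi mapping
#'
#' The common-currency model takes the loaded bucket combined with the easier
#' cognitive task as its baseline (Phi = duration); the harder cognitive task
#' adds `k` and the empty bucket adds `h`. Which weight is "loaded" and which
#' difficulty label is "harder" are explicit declarations, never inferred
#' from the data.
#'
#' @param loaded_weight numeric weight (kg) of the loaded bucket.
#' @param empty_weight numeric weight of the empty bucket.
#' @param harder_difficulty label of the harder cognitive-task level.
#' @param easier_difficulty label of the easier level.
#' @return An object of class `"level_roles"`.
#' @examples
#' level_roles()  # defaults match experiment_design()
#' @export
level_roles <- function(loaded_weight = 3.2, empty_weight = 0.0,
                        harder_difficulty = "hard", easier_difficulty = "easy") {
  if (!is.numeric(loaded_weight) || !is.numeric(empty_weight))
    stop("weights must be numeric")
  if (isTRUE(loaded_weight == empty_weight))
    stop("'loaded_weight' and 'empty_weight' must differ")
  if (identical(harder_difficulty, easier_difficulty))
    stop("'harder_difficulty' and 'easier_difficulty' must differ")
  structure(list(loaded_weight = loaded_weight, empty_weight = empty_weight,
                 harder_difficulty = as.character(harder_difficulty),
                 easier_difficulty = as.character(easier_difficulty)),
            class = "level_roles")
}

#' @export
print.level_roles <- function(x, ...) {
  cat("Level roles for the Phi mapping\n")
  cat("  loaded bucket:  ", x$loaded_weight, " kg (baseline)\n", sep = "")
  cat("  empty bucket:   ", x$empty_weight, " kg (+h)\n", sep = "")
  cat("  easier task:    ", x$easier_difficulty, " (baseline)\n", sep = "")
  cat("  harder task:    ", x$harder_difficulty, " (+k)\n", sep = "")
  invisible(x)
}

#' Level roles implied by a design
#'
#' The design's declared `loaded_weight` and the ordering of its difficulty
#' labels (easiest first) determine the roles.
#'
#' @param design an [experiment_design()].
#' @return a [level_roles()] object.
#' @export
design_roles <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (length(design$weights) != 2L || length(design$difficulties) != 2L)
    stop("roles are defined only for designs with two weights and two difficulties")
  level_roles(loaded_weight = design$loaded_weight,
              empty_weight = setdiff(design$weights, design$loaded_weight),
              harder_difficulty = design$difficulties[length(design$difficulties)],
              easier_difficulty = design$difficulties[1L])
}
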