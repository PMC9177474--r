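#' Generative model parameters for synthetic choice data
#'
#' The generator draws each binary choice Bernoulli from the four-parameter
#' logistic evaluated at the cell's Phi value under the two-shift mapping
#' (difficulty shift `true_k`, empty-bucket shift `true_h`). Participant
#' heterogeneity is a normal perturbation of the logistic inflection point
#' (mean 0, sd `participant_sd`), which keeps the group-level curve a
#' logistic in the `participant_sd -> 0` limit. A hook for a bucket-side
#' effect exists (`side_shift`, a Phi increment for the second side level)
#' but defaults to zero, matching the observation that bucket location does
#' not affect choices.
#'
#' @param true_k Phi shift for the harder cognitive task (seconds-equivalent).
#' @param true_h Phi shift for the empty bucket.
#' @param logistic a [logistic_params()] object, the group-level curve.
#' @param participant_sd nonnegative sd of the per-participant inflection
#'   perturbation.
#' @param side_shift Phi increment applied to trials on the second side level;
#'   0 by default (no generative side effect).
#' @param seed integer RNG seed.
#' @return An object of class `"generative_params"`.
#' @export
generative_params <- function(true_k = 24, true_h = 8,
                              logistic = logistic_params(0.05, 0.95, 30, 0.3),
                              participant_sd = 0, side_shift = 0, seed = 1L) {
  check_finite_scalar(true_k, "true_k")
  check_finite_scalar(true_h, "true_h")
  check_finite_scalar(participant_sd, "participant_sd")
  check_finite_scalar(side_shift, "side_shift")
  stopifnot(inherits(logistic, "logistic_params"))
  if (participant_sd < 0) stop("'participant_sd' must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a finite integer")
  structure(list(true_k = true_k, true_h = true_h, logistic = logistic,
                 participant_sd = participant_sd, side_shift = side_shift,
                 seed = as.integer(seed)),
            class = "generative_params")
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf("Generative Phi-logistic: true_k=%.3g true_h=%.3g participant_sd=%.3g seed=%d\n",
              x$true_k, x$true_h, x$participant_sd, x$seed))
  print(x$logistic)
  invisible(x)
}

# Evaluate RNG-consuming code under a local, seeded stream, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Full trial grid for one participant, in deterministic cell order.
trial_grid <- function(design) {
  g <- expand.grid(rep = seq_len(design$trials_per_combination),
                   side = design$sides,
                   duration = design$durations,
                   difficulty = design$difficulties,
                   bucket_weight = design$weights,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rep <- NULL
  g[, c("bucket_weight", "difficulty", "duration", "side")]
}

#' Simulate trial-level choices from the generative Phi-logistic
#'
#' Produces one row per trial for every participant x design cell x side x
#' repetition, with `choice` drawn Bernoulli from
#' `logistic(Phi(cell; true_k, true_h))` using the participant's perturbed
#' inflection point. Identical inputs (including the seed stored in
#' `params`) give identical output.
#'
#' @param design an [experiment_design()].
#' @param params a [generative_params()].
#' @return data.frame with columns `participant_id`, `bucket_weight_kg`,
#'   `difficulty`, `duration_s`, `bucket_side`, `choice`
#'   (`"bucket"`/`"cognitive"`).
#' @examples
#' d <- experiment_design(n_participants = 4)
#' trials <- generate_choices(d, generative_params(seed = 7))
#' nrow(trials)  # 4 participants x 24 trials
#' @export
generate_choices <- function(design, params) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "generative_params"))
  roles <- design_roles(design)
  grid <- trial_grid(design)
  nper <- nrow(grid)
  n <- design$n_participants
  phi_base <- phi_two_shift(grid$duration, grid$bucket_weight, grid$difficulty,
                            k = params$true_k, h = params$true_h, roles = roles)
  side_on <- as.numeric(grid$side == design$sides[length(design$sides)])
  phi_base <- phi_base + params$side_shift * side_on
  with_seed(params$seed, {
    shifts <- stats::rnorm(n, 0, params$participant_sd)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      lp <- params$logistic
      pr <- lp$lower + (lp$upper - lp$lower) *
        stats::plogis(lp$steepness * (phi_base - (lp$inflection + shifts[i])))
      choice <- ifelse(stats::rbinom(nper, 1L, pr) == 1L, "bucket", "cognitive")
      out[[i]] <- data.frame(participant_id = sprintf("P%03d", i),
                             bucket_weight_kg = grid$bucket_weight,
                             difficulty = grid$difficulty,
                             duration_s = grid$duration,
                             bucket_side = grid$side,
                             choice = choice,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Analytic (noiseless) group cell means under the generative model
#'
#' The expected group-level p(Bucket) per weight x difficulty x duration
#' cell, `logistic(Phi(cell))`, with no sampling noise. Requires
#' `participant_sd = 0` (with heterogeneity the group mean is no longer the
#' logistic at the group inflection).
#'
#' @inheritParams generate_choices
#' @return data.frame with columns `bucket_weight_kg`, `difficulty`,
#'   `duration_s`, `p_bucket`.
#' @export
generate_noiseless_cell_means <- function(design, params) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "generative_params"))
  if (params$participant_sd > 0)
    stop("noiseless cell means require participant_sd = 0")
  roles <- design_roles(design)
  cells <- expand.grid(duration_s = design$durations,
                       difficulty = design$difficulties,
                       bucket_weight_kg = design$weights,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  phi <- phi_two_shift(cells$duration_s, cells$bucket_weight_kg,
                       cells$difficulty, k = params$true_k, h = params$true_h,
                       roles = roles)
  cells$p_bucket <- logistic_value(phi, params$logistic)
  cells[, c("bucket_weight_kg", "difficulty", "duration_s", "p_bucket")]
}

#' Simulate an exposure block: per-trial correctness and response time
#'
#' Emulates the pre-choice exposure phase in which each cognitive difficulty
#' level is performed repeatedly so its demands become salient. Correctness
#' is Bernoulli with the level's error rate; response times are lognormal
#' with the level's mean and sd (in ms), so empirical error rates and mean
#' RTs converge to the specified values as trials grow.
#'
#' @param n_participants positive integer.
#' @param difficulty_effects named list, one entry per difficulty level, each
#'   a numeric vector with elements `error_rate` (in `[0,1]`), `mean_rt` and
#'   `rt_sd` (positive, ms).
#' @param trials_per_level positive integer, trials per level (40 in the
#'   emulated procedure).
#' @param seed integer RNG seed.
#' @return data.frame with columns `participant_id`, `difficulty`, `trial`,
#'   `correct` (0/1), `rt`.
#' @export
generate_exposure_performance <- function(n_participants,
                                          difficulty_effects,
                                          trials_per_level = 40L,
                                          seed = 1L) {
  if (!is.numeric(trials_per_level) || trials_per_level < 1)
    stop("'trials_per_level' must be >= 1")
  if (!is.list(difficulty_effects) || is.null(names(difficulty_effects)))
    stop("'difficulty_effects' must be a named list")
  for (nm in names(difficulty_effects)) {
    e <- difficulty_effects[[nm]]
    if (!all(c("error_rate", "mean_rt", "rt_sd") %in% names(e)))
      stop("difficulty_effects[['", nm,
           "']] needs elements error_rate, mean_rt, rt_sd")
    if (e[["error_rate"]] < 0 || e[["error_rate"]] > 1)
      stop("error_rate for '", nm, "' must be in [0, 1]")
    if (e[["mean_rt"]] <= 0 || e[["rt_sd"]] <= 0)
      stop("rt parameters for '", nm, "' must be positive")
  }
  trials_per_level <- as.integer(trials_per_level)
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n_participants)) {
      for (nm in names(difficulty_effects)) {
        e <- difficulty_effects[[nm]]
        ntr <- trials_per_level
        correct <- 1L - stats::rbinom(ntr, 1L, e[["error_rate"]])
        cv2 <- (e[["rt_sd"]] / e[["mean_rt"]])^2
        sdlog <- sqrt(log(1 + cv2))
        meanlog <- log(e[["mean_rt"]]) - sdlog^2 / 2
        rt <- stats::rlnorm(ntr, meanlog, sdlog)
        out[[length(out) + 1L]] <-
          data.frame(participant_id = sprintf("P%03d", i),
                     difficulty = nm, trial = seq_len(ntr),
                     correct = correct, rt = rt,
                     stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
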