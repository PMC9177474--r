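#' Fit the common-currency Phi model to choice probabilities
#'
#' The central fitting routine. Group-level p(Bucket) cell means (weight x
#' difficulty x duration) are mapped onto the latent axis Phi by a piecewise
#' shift mapping — `two_shift`: Phi = duration, plus `k` for the harder
#' cognitive task, plus `h` for the empty bucket; `one_shift`: Phi =
#' duration, plus `h` for the empty bucket, ignoring difficulty — and a
#' four-parameter logistic (lower bound, upper bound, inflection point,
#' steepness) is fitted to the (Phi, p) points to maximise the coefficient
#' of determination `R^2 = 1 - SS_residuals / SS_total`. The shifts are
#' estimated by exhaustive search over integer grids: every grid point is
#' evaluated (logistic refitted), and the point with maximal R^2 wins, ties
#' broken by smallest `(|k|, |h|)` lexicographically (the most parsimonious
#' shift).
#'
#' All cell means enter the fit; under `one_shift` the difficulty-paired
#' cells share a Phi value and both points are retained.
#'
#' @param data trial records (a data.frame with a `choice` column, see
#'   [generate_choices()]), a `choice_table` from [aggregate_choices()], or a
#'   data.frame of group cell means with columns `bucket_weight_kg`,
#'   `difficulty`, `duration_s`, `p_bucket`.
#' @param variant `"two_shift"` (difficulty and weight shifts) or
#'   `"one_shift"` (weight shift only).
#' @param roles a [level_roles()] declaration of which weight is loaded and
#'   which difficulty is harder.
#' @param k_grid,h_grid integer-valued candidate grids for the shifts. The
#'   defaults span +/- the design's duration range. `k_grid` is ignored for
#'   `one_shift`.
#' @param fixed_h if non-`NULL`, `h` is frozen at this value and only the
#'   logistic is (re)fitted — the cross-experiment transfer fit.
#' @return An object of class `"phifit"` with components `variant`, `k`
#'   (`NA` for `one_shift`), `h`, `logistic` (a [logistic_params()]),
#'   `r_squared`, `fitted_points` (per-cell Phi, observed, predicted), and
#'   `grid` (the full R^2 surface over the evaluated grid).
#' @examples
#' cm <- generate_noiseless_cell_means(experiment_design(),
#'                                     generative_params(true_k = 24, true_h = 8))
#' fit <- phifit(cm, variant = "two_shift", k_grid = 20:28, h_grid = 4:12)
#' coef(fit)
#' @seealso [grid_fit()], [transfer_fit()], [plot.phifit()]
#' @export
phifit <- function(data, variant = c("two_shift", "one_shift"),
                   roles = level_roles(),
                   k_grid = -36:72, h_grid = -36:36,
                   fixed_h = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(roles, "level_roles"))
  if (is.data.frame(data) && "choice" %in% names(data))
    data <- aggregate_choices(data)
  cm <- as_cell_means(data)
  check_full_factorial(cm)
  if (variant == "two_shift" && length(k_grid) == 0L) stop("'k_grid' is empty")
  if (is.null(fixed_h) && length(h_grid) == 0L) stop("'h_grid' is empty")

  p <- cm$p_bucket
  ss_tot <- sum((p - mean(p))^2)
  if (ss_tot == 0)
    stop("observed cell means are all identical: R^2 undefined")

  if (!is.null(fixed_h)) {
    check_finite_scalar(fixed_h, "fixed_h")
    h_grid <- fixed_h
  }
  grid <- if (variant == "two_shift") {
    expand.grid(k = as.numeric(k_grid), h = as.numeric(h_grid),
                KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(k = NA_real_, h = as.numeric(h_grid))
  }

  # Phi values for every design cell under every grid point: the inner
  # logistic fit (asymptotes profiled exactly, compass-refined inflection
  # and steepness) runs to convergence at each grid point in compiled code,
  # so neighbouring shift candidates are ranked by their true profile SS.
  dur <- cm$duration_s
  empty_ind <- match_role(cm$bucket_weight_kg, roles$empty_weight,
                          roles$loaded_weight, "bucket_weight")
  harder_ind <- if (variant == "two_shift")
    match_role(cm$difficulty, roles$harder_difficulty,
               roles$easier_difficulty, "difficulty") else numeric(length(dur))
  kvec <- ifelse(is.na(grid$k), 0, grid$k)
  phi_mat <- outer(kvec, harder_ind) + outer(grid$h, empty_ind) +
    matrix(dur, nrow(grid), length(dur), byrow = TRUE)
  scan <- .profile_scan_cpp(phi_mat, p)
  ss_best <- scan[, 1L]

  # winner: smallest SS; near-ties (R^2 within 1e-9) resolved by the most
  # parsimonious shift, smallest (|k|, |h|) lexicographically
  r2 <- 1 - ss_best / ss_tot
  tie <- which(r2 >= max(r2) - 1e-9)
  if (length(tie) > 1L) {
    ord <- if (variant == "two_shift")
      order(abs(grid$k[tie]), abs(grid$h[tie])) else order(abs(grid$h[tie]))
    win <- tie[ord[1L]]
  } else win <- tie
  phi_w <- phi_for_cells(cm, variant, grid$k[win], grid$h[win], roles)

  # final full multi-start fit at the winning grid point, seeded with the
  # scan's converged (inflection, steepness); keep whichever is better so
  # the reported optimum can only improve on the recorded surface
  full <- fit_logistic_core(phi_w, p, ss_tot,
                            extra_starts = data.frame(cpar = scan[win, 2L],
                                                      spar = scan[win, 3L]))
  if (scan[win, 1L] < full$ss) {
    params <- logistic_params(min(max(scan[win, 4L], 0), 1),
                              min(max(scan[win, 5L], 0), 1),
                              scan[win, 2L], scan[win, 3L])
    full <- list(params = params,
                 r_squared = 1 - scan[win, 1L] / ss_tot,
                 ss = scan[win, 1L],
                 fitted = logistic_value(phi_w, params))
  }
  ss_best[win] <- full$ss

  fitted_points <- data.frame(cm[c("bucket_weight_kg", "difficulty", "duration_s")],
                              phi = phi_w, observed = p, predicted = full$fitted)
  fitted_points <- fitted_points[order(fitted_points$phi), , drop = FALSE]
  rownames(fitted_points) <- NULL

  grid$r_squared <- 1 - ss_best / ss_tot
  structure(list(variant = variant,
                 k = grid$k[win],
                 h = grid$h[win],
                 fixed_h = !is.null(fixed_h),
                 logistic = full$params,
                 r_squared = full$r_squared,
                 ss = full$ss,
                 ss_total = ss_tot,
                 fitted_points = fitted_points,
                 grid = grid,
                 roles = roles,
                 n_participants = if (inherits(data, "choice_table"))
                   data$n_participants else NA_integer_,
                 call = match.call()),
            class = "phifit")
}

#' Exhaustive grid search for the Phi shift parameters
#'
#' Thin wrapper around [phifit()] matching the pipeline vocabulary: evaluates
#' every point of the shift grids, refits the logistic at each, and returns
#' the fit with maximal R^2.
#'
#' @param cell_means a `choice_table` or cell-means data.frame (see
#'   [phifit()]).
#' @inheritParams phifit
#' @return a `"phifit"` object.
#' @export
grid_fit <- function(cell_means, variant = c("two_shift", "one_shift"),
                     k_grid = -36:72, h_grid = -36:36,
                     roles = level_roles()) {
  phifit(cell_means, variant = match.arg(variant), roles = roles,
         k_grid = k_grid, h_grid = h_grid)
}

#' Transfer fit: refit the logistic with the weight shift h frozen
#'
#' Used to carry a shift estimated in one experiment into another: `h` is
#' held at `fixed_h` and only the four logistic parameters are refitted.
#' When `fixed_h` lies on the grid searched by [grid_fit()], the transfer
#' R^2 cannot exceed the free optimum.
#'
#' @inheritParams grid_fit
#' @param fixed_h the frozen value of `h`.
#' @return a `"phifit"` object with `fixed_h = TRUE`.
#' @export
transfer_fit <- function(cell_means, fixed_h,
                         variant = c("one_shift", "two_shift"),
                         k_grid = -36:72, roles = level_roles()) {
  phifit(cell_means, variant = match.arg(variant), roles = roles,
         k_grid = k_grid, fixed_h = fixed_h)
}

#' @export
print.phifit <- function(x, digits = 4, ...) {
  cat("Common-currency Phi model (", x$variant, ")\n", sep = "")
  if (x$variant == "two_shift")
    cat("  k (harder cognitive task): ", format(x$k, digits = digits), "\n", sep = "")
  cat("  h (empty bucket):          ", format(x$h, digits = digits),
      if (x$fixed_h) "  [frozen]" else "", "\n", sep = "")
  cat(sprintf("  logistic: lower=%.3f upper=%.3f inflection=%.2f steepness=%.3f\n",
              x$logistic$lower, x$logistic$upper,
              x$logistic$inflection, x$logistic$steepness))
  cat("  R^2 = ", format(x$r_squared, digits = digits), " on ",
      nrow(x$fitted_points), " cell means\n", sep = "")
  invisible(x)
}

#' @export
summary.phifit <- function(object, ...) {
  structure(list(fit = object,
                 points = object$fitted_points,
                 grid_size = nrow(object$grid),
                 top = utils::head(object$grid[order(-object$grid$r_squared), ], 5L)),
            class = "summary.phifit")
}

#' @export
print.summary.phifit <- function(x, ...) {
  print(x$fit)
  cat("\nFitted points (ordered by Phi):\n")
  pts <- x$points
  pts$observed <- round(pts$observed, 3)
  pts$predicted <- round(pts$predicted, 3)
  print(pts, row.names = FALSE)
  cat("\nGrid:", x$grid_size, "candidate shift combinations; leading R^2 values:\n")
  top <- x$top
  top$r_squared <- round(top$r_squared, 4)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.phifit <- function(object, ...) {
  c(k = object$k, h = object$h,
    lower = object$logistic$lower, upper = object$logistic$upper,
    inflection = object$logistic$inflection,
    steepness = object$logistic$steepness)
}

#' Predicted p(Bucket) from a fitted Phi model
#'
#' @param object a `"phifit"` object.
#' @param newdata optional data.frame with columns `bucket_weight_kg`,
#'   `difficulty` (two-shift only) and `duration_s`; defaults to the fitted
#'   cells.
#' @param phi alternatively, Phi values at which to evaluate the curve.
#' @param ... unused.
#' @return numeric vector of predicted probabilities.
#' @export
predict.phifit <- function(object, newdata = NULL, phi = NULL, ...) {
  if (!is.null(phi)) return(logistic_value(phi, object$logistic))
  if (is.null(newdata)) return(object$fitted_points$predicted)
  k <- if (object$variant == "two_shift") object$k else NA_real_
  phi <- phi_for_cells(newdata, object$variant, k, object$h, object$roles)
  logistic_value(phi, object$logistic)
}

#' @export
fitted.phifit <- function(object, ...) object$fitted_points$predicted

#' @export
residuals.phifit <- function(object, ...) {
  object$fitted_points$observed - object$fitted_points$predicted
}

#' Plot fitted points and the logistic curve on the Phi axis
#'
#' Cell means plotted against their Phi values with the fitted
#' four-parameter logistic drawn through them.
#'
#' @param x a `"phifit"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.phifit <- function(x, ...) {
  pts <- x$fitted_points
  rng <- range(pts$phi)
  pad <- 0.1 * diff(rng)
  xx <- seq(rng[1] - pad, rng[2] + pad, length.out = 200)
  graphics::plot(pts$phi, pts$observed, xlab = expression(Phi~"(s-equivalent)"),
                 ylab = "p(Bucket)", ylim = c(0, 1), pch = 19, ...)
  graphics::lines(xx, logistic_value(xx, x$logistic), lwd = 2)
  lab <- if (x$variant == "two_shift")
    sprintf("k = %.3g, h = %.3g, R2 = %.3f", x$k, x$h, x$r_squared)
  else sprintf("h = %.3g, R2 = %.3f", x$h, x$r_squared)
  graphics::mtext(lab, side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}

#' Simulate trial-level datasets from a fitted Phi model
#'
#' Uses the fitted shifts and logistic as the generative truth (no
#' participant heterogeneity) and draws Bernoulli choices for a full design.
#'
#' @param object a `"phifit"` object.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param design an [experiment_design()]; defaults to the standard 24-trial
#'   design with the fit's declared roles.
#' @param ... unused.
#' @return a list of `nsim` trial data.frames.
#' @export
simulate.phifit <- function(object, nsim = 1, seed = 1L, design = NULL, ...) {
  if (is.null(design)) {
    r <- object$roles
    design <- experiment_design(weights = sort(c(r$loaded_weight, r$empty_weight)),
                                difficulties = c(r$easier_difficulty,
                                                 r$harder_difficulty),
                                loaded_weight = r$loaded_weight)
  }
  k <- if (object$variant == "two_shift") object$k else 0
  lapply(seq_len(nsim), function(i) {
    generate_choices(design,
                     generative_params(true_k = k, true_h = object$h,
                                       logistic = object$logistic,
                                       participant_sd = 0,
                                       seed = seed + i - 1L))
  })
}
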