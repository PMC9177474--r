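#' Four-parameter logistic
#'
#' The psychometric curve used throughout the package:
#' \deqn{p(\Phi) = lower + (upper - lower) \,\sigma(steepness\,(\Phi - inflection))}
#' where \eqn{\sigma} is the standard sigmoid. `lower` and `upper` are the
#' asymptotic choice probabilities, `inflection` the Phi value at the curve's
#' midpoint (seconds-equivalent), and `steepness` the slope per Phi unit.
#'
#' @param lower,upper asymptotes, with `0 <= lower <= upper <= 1`.
#' @param inflection midpoint on the Phi axis.
#' @param steepness positive slope parameter.
#' @return An object of class `"logistic_params"`.
#' @examples
#' lp <- logistic_params(0.05, 0.95, 30, 0.3)
#' logistic_value(30, lp)  # midpoint: (0.05 + 0.95) / 2
#' @export
logistic_params <- function(lower, upper, inflection, steepness) {
  for (nm in c("lower", "upper", "inflection", "steepness"))
    check_finite_scalar(get(nm), nm)
  if (lower < 0 || upper > 1 || lower > upper)
    stop("need 0 <= lower <= upper <= 1")
  if (steepness <= 0) stop("'steepness' must be > 0")
  structure(list(lower = lower, upper = upper,
                 inflection = inflection, steepness = steepness),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("4-parameter logistic: lower=%.4g upper=%.4g inflection=%.4g steepness=%.4g\n",
              x$lower, x$upper, x$inflection, x$steepness))
  invisible(x)
}

#' Evaluate the four-parameter logistic
#'
#' @param phi numeric vector of Phi values.
#' @param params a [logistic_params()] object.
#' @return choice probabilities in `[lower, upper]`.
#' @export
logistic_value <- function(phi, params) {
  stopifnot(inherits(params, "logistic_params"))
  params$lower + (params$upper - params$lower) *
    stats::plogis(params$steepness * (phi - params$inflection))
}

#' Coefficient of determination
#'
#' `1 - SS_residuals / SS_total`, with `SS_total` taken around the mean of
#' the observed values. Equals 1 iff predictions are exact; may be negative
#' when the fit is worse than the observed mean.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return numeric scalar.
#' @examples
#' r_squared(c(0.2, 0.4, 0.9), c(0.3, 0.4, 0.8))
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 2L) stop("need at least 2 points")
  if (!all(is.finite(observed)) || !all(is.finite(predicted)))
    stop("inputs must be finite")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed values are all identical: SS_total = 0, R^2 undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

# ---- profiled least squares ------------------------------------------------
#
# For fixed (inflection c, steepness s) the prediction is linear in the
# asymptotes: pred = lower * (1 - sig) + upper * sig. The box/order
# constrained minimiser over (lower, upper) is found exactly by active-set
# enumeration: unconstrained 2x2 solve if feasible, else the best of the
# constrained edges lower = 0, upper = 1, lower = upper (flat line).

best_bounds <- function(sig, p) {
  x1 <- 1 - sig
  s11 <- sum(x1 * x1); s12 <- sum(x1 * sig); s22 <- sum(sig * sig)
  y1 <- sum(x1 * p);   y2 <- sum(sig * p)
  ss_of <- function(a, b) sum((a * x1 + b * sig - p)^2)
  best <- NULL
  det <- s11 * s22 - s12 * s12
  if (det > .Machine$double.eps * max(s11 * s22, 1)) {
    a <- (y1 * s22 - y2 * s12) / det
    b <- (s11 * y2 - s12 * y1) / det
    if (a >= 0 && b <= 1 && a <= b)
      best <- list(lower = a, upper = b, ss = ss_of(a, b))
  }
  # edge lower = 0
  b0 <- if (s22 > 0) min(max(y2 / s22, 0), 1) else 0
  cand <- list(lower = 0, upper = b0, ss = ss_of(0, b0))
  if (is.null(best) || cand$ss < best$ss) best <- cand
  # edge upper = 1
  a1 <- if (s11 > 0) min(max((y1 - s12) / s11, 0), 1) else 0
  cand <- list(lower = a1, upper = 1, ss = ss_of(a1, 1))
  if (cand$ss < best$ss) best <- cand
  # edge lower = upper (flat line at the clamped mean)
  t0 <- min(max(mean(p), 0), 1)
  cand <- list(lower = t0, upper = t0, ss = ss_of(t0, t0))
  if (cand$ss < best$ss) best <- cand
  best
}

profile_ss <- function(cpar, spar, phi, p) {
  sig <- stats::plogis(spar * (phi - cpar))
  best_bounds(sig, p)$ss
}

# Vectorised lattice of profiled SS over (inflection, steepness) pairs.
# Returns the lattice data.frame with an ss column. Used both as the coarse
# scan inside grid_fit and to seed Nelder-Mead refinement.
profile_ss_lattice <- function(phi, p, cgrid, sgrid) {
  lat <- expand.grid(cpar = cgrid, spar = sgrid, KEEP.OUT.ATTRS = FALSE)
  m <- length(phi)
  J <- nrow(lat)
  Z <- (matrix(phi, J, m, byrow = TRUE) - lat$cpar) * lat$spar
  sig <- stats::plogis(Z)
  x1 <- 1 - sig
  P <- matrix(p, J, m, byrow = TRUE)
  s11 <- rowSums(x1 * x1); s12 <- rowSums(x1 * sig); s22 <- rowSums(sig * sig)
  y1 <- rowSums(x1 * P);   y2 <- rowSums(sig * P)
  pp <- sum(p * p)
  ss_lin <- function(a, b) {
    # ||a x1 + b sig - p||^2 expanded through the precomputed cross-products
    a * a * s11 + b * b * s22 + 2 * a * b * s12 - 2 * a * y1 - 2 * b * y2 + pp
  }
  det <- s11 * s22 - s12 * s12
  ok <- det > .Machine$double.eps * pmax(s11 * s22, 1)
  a_u <- ifelse(ok, (y1 * s22 - y2 * s12) / det, NA_real_)
  b_u <- ifelse(ok, (s11 * y2 - s12 * y1) / det, NA_real_)
  feas <- ok & !is.na(a_u) & a_u >= 0 & b_u <= 1 & a_u <= b_u
  ss <- rep(Inf, J)
  ss[feas] <- ss_lin(a_u, b_u)[feas]
  b0 <- pmin(pmax(ifelse(s22 > 0, y2 / s22, 0), 0), 1)
  ss <- pmin(ss, ss_lin(0, b0))
  a1 <- pmin(pmax((y1 - s12) / pmax(s11, .Machine$double.xmin), 0), 1)
  ss <- pmin(ss, ss_lin(a1, 1))
  t0 <- min(max(mean(p), 0), 1)
  ss <- pmin(ss, ss_lin(t0, t0))
  lat$ss <- pmax(ss, 0)  # guard tiny negative round-off
  lat
}

default_steepness_starts <- c(0.05, 0.2, 1, 5)

# Nelder-Mead refinement of (inflection, log steepness) from one start.
refine_fit <- function(phi, p, cpar, spar, reltol = 1e-10) {
  obj <- function(par) profile_ss(par[1], exp(par[2]), phi, p)
  opt <- stats::optim(c(cpar, log(spar)), obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 1000))
  cpar <- opt$par[1]; spar <- exp(opt$par[2])
  sig <- stats::plogis(spar * (phi - cpar))
  bb <- best_bounds(sig, p)
  list(cpar = cpar, spar = spar, lower = bb$lower, upper = bb$upper, ss = bb$ss)
}

#' Fit the four-parameter logistic to (Phi, choice probability) points
#'
#' Bounded least squares under the constraints `0 <= lower <= upper <= 1`,
#' `steepness > 0`. The asymptotes are profiled out exactly (they enter the
#' prediction linearly), and the remaining (inflection, steepness) surface is
#' minimised by deterministic Nelder-Mead from a multi-start lattice:
#' inflection spread over the observed Phi range crossed with steepness
#' in `{0.05, 0.2, 1, 5}`, plus the best point of a finer profiled scan.
#' The best start's solution is kept.
#'
#' @param phi numeric Phi values (at least 4 distinct).
#' @param observed observed choice probabilities, same length.
#' @param reltol convergence tolerance on the residual sum of squares.
#' @return list with components `params` (a [logistic_params()]), `r_squared`,
#'   `ss` (residual sum of squares), and `fitted`.
#' @examples
#' lp <- logistic_params(0.1, 0.9, 20, 0.4)
#' phi <- seq(5, 40, length.out = 8)
#' fit <- fit_logistic(phi, logistic_value(phi, lp))
#' fit$r_squared   # 1 up to optimiser tolerance
#' @export
fit_logistic <- function(phi, observed, reltol = 1e-10) {
  if (length(phi) != length(observed))
    stop("'phi' and 'observed' must have equal length")
  if (length(unique(phi)) < 4L)
    stop("underdetermined fit: need at least 4 distinct Phi values, got ",
         length(unique(phi)))
  if (!all(is.finite(phi)) || !all(is.finite(observed)))
    stop("inputs must be finite")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed values are all identical: logistic fit is degenerate")
  fit_logistic_core(phi, observed, ss_tot, reltol)
}

fit_logistic_core <- function(phi, observed, ss_tot, reltol = 1e-10,
                              extra_starts = NULL) {
  rng <- range(phi)
  starts <- expand.grid(cpar = seq(rng[1], rng[2], length.out = 5),
                        spar = default_steepness_starts,
                        KEEP.OUT.ATTRS = FALSE)
  lat <- profile_ss_lattice(phi, observed,
                            cgrid = seq(rng[1], rng[2], length.out = 21),
                            sgrid = exp(seq(log(0.02), log(5), length.out = 13)))
  best_lat <- lat[which.min(lat$ss), ]
  starts <- rbind(starts, data.frame(cpar = best_lat$cpar, spar = best_lat$spar))
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- refine_fit(phi, observed, starts$cpar[i], starts$spar[i], reltol)
    if (is.null(best) || res$ss < best$ss) best <- res
  }
  params <- logistic_params(min(max(best$lower, 0), 1),
                            min(max(best$upper, 0), 1),
                            best$cpar, best$spar)
  fitted <- logistic_value(phi, params)
  list(params = params,
       r_squared = 1 - best$ss / ss_tot,
       ss = best$ss,
       fitted = fitted)
}
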