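#' Paired t test with Cohen's d for repeated measures
#'
#' Two-sided paired t test on the per-participant differences `x - y`, with
#' the paired-samples effect size `d_z = mean(diff) / sd(diff)` (so the
#' printed `t`, `n`, and `d` satisfy `d = t / sqrt(n)`). If the differences
#' have zero variance with a nonzero mean, the t statistic is infinite; this
#' is signalled explicitly with a warning rather than an error.
#'
#' @param x,y equal-length numeric vectors of per-participant values
#'   (condition means), `n >= 2`.
#' @return list with elements `t`, `df`, `p`, `cohens_d`, `mean_diff`, `n`.
#' @examples
#' paired_t(c(3, 5, 7), c(2, 3, 4))   # diffs 1, 2, 3: t = 2*sqrt(3), d = 2
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 2L) stop("need n >= 2 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0)
      return(list(t = 0, df = n - 1L, p = 1, cohens_d = 0,
                  mean_diff = 0, n = n))
    warning("zero variance of differences with nonzero mean: t is infinite")
    return(list(t = sign(md) * Inf, df = n - 1L, p = 0,
                cohens_d = sign(md) * Inf, mean_diff = md, n = n))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = md / sdd, mean_diff = md, n = n)
}

#' Within-participant confidence interval for a paired difference
#'
#' Half-width of the level-`level` CI of the mean paired difference,
#' `t_crit((1 + level)/2, n - 1) * sd(diff) / sqrt(n)` — the error bar used
#' for within-participant comparisons (e.g. empty vs loaded bucket within
#' each difficulty x duration cell).
#'
#' @inheritParams paired_t
#' @param level confidence level in `[0, 1)`; 0.95 by default.
#' @return numeric half-width.
#' @export
within_ci <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 2L) stop("need n >= 2 pairs")
  if (!is.numeric(level) || level < 0 || level >= 1)
    stop("'level' must be in [0, 1)")
  d <- x - y
  stats::qt((1 + level) / 2, df = n - 1L) * stats::sd(d) / sqrt(n)
}
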