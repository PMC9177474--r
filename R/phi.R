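#' Map a design cell onto the common-currency axis Phi (two-shift variant)
#'
#' The two-shift mapping treats the loaded bucket paired with the easier
#' cognitive task as the baseline, for which Phi equals the imposed duration
#' of the cognitive task (in seconds). The harder cognitive task adds the
#' shift `k`; the empty bucket adds the shift `h`; the two increments are
#' additive:
#'
#' \deqn{\Phi = duration + k \cdot [harder] + h \cdot [empty]}
#'
#' Both shifts are expressed in seconds-equivalent units on the Phi axis.
#'
#' @param duration numeric, imposed cognitive-task duration in seconds.
#' @param bucket_weight numeric bucket weight (kg); must equal either the
#'   declared loaded or empty weight.
#' @param difficulty difficulty label; must equal either the declared harder
#'   or easier level.
#' @param k Phi increment for the harder cognitive task.
#' @param h Phi increment for the empty bucket.
#' @param roles a [level_roles()] declaration.
#' @return numeric vector of Phi values (seconds-equivalent).
#' @examples
#' phi_two_shift(9, 3.2, "easy", k = 24, h = 8)    # baseline cell: 9
#' phi_two_shift(27, 0, "hard", k = 24, h = 8)     # 27 + 24 + 8 = 59
#' @seealso [phi_one_shift()] for the duration-plus-weight-only variant.
#' @export
phi_two_shift <- function(duration, bucket_weight, difficulty, k, h,
                          roles = level_roles()) {
  stopifnot(inherits(roles, "level_roles"))
  check_finite_scalar(k, "k")
  check_finite_scalar(h, "h")
  if (!all(is.finite(duration))) stop("'duration' must be finite")
  harder <- match_role(difficulty, roles$harder_difficulty, roles$easier_difficulty,
                       "difficulty")
  empty <- match_role(bucket_weight, roles$empty_weight, roles$loaded_weight,
                      "bucket_weight")
  duration + k * harder + h * empty
}

#' Map a design cell onto Phi ignoring cognitive difficulty (one-shift variant)
#'
#' Used when cognitive-task difficulty has no detectable effect on choices:
#' Phi is the imposed duration, plus the single shift `h` when the bucket is
#' empty.
#'
#' @inheritParams phi_two_shift
#' @return numeric vector of Phi values.
#' @examples
#' phi_one_shift(18, 3.2, h = 7)   # 18
#' phi_one_shift(18, 0, h = 7)     # 25
#' @export
phi_one_shift <- function(duration, bucket_weight, h, roles = level_roles()) {
  stopifnot(inherits(roles, "level_roles"))
  check_finite_scalar(h, "h")
  if (!all(is.finite(duration))) stop("'duration' must be finite")
  empty <- match_role(bucket_weight, roles$empty_weight, roles$loaded_weight,
                      "bucket_weight")
  duration + h * empty
}

# 1 where value matches the "on" level, 0 at the reference level, error else.
match_role <- function(value, on_level, ref_level, what) {
  out <- ifelse(value == on_level, 1,
                ifelse(value == ref_level, 0, NA_real_))
  if (anyNA(out)) {
    bad <- unique(value[is.na(out)])
    stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
         " (declared levels: ", on_level, ", ", ref_level, ")")
  }
  out
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  invisible(x)
}

# Vectorised Phi for a cell table under either variant.
phi_for_cells <- function(cells, variant, k, h, roles) {
  if (variant == "two_shift") {
    phi_two_shift(cells$duration, cells$bucket_weight, cells$difficulty,
                  k = k, h = h, roles = roles)
  } else {
    phi_one_shift(cells$duration, cells$bucket_weight, h = h, roles = roles)
  }
}
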