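# Independent repeated-measures sums-of-squares oracle.
#
# Classical balanced decomposition by Moebius inversion over factor subsets:
# the pure effect of a subset S of factors (participant included) is the
# S-marginal mean minus all pure effects of proper subsets, and
# SS_S = (N / #combos(S)) * sum(effect^2). Each within effect is tested
# against its interaction with the participant factor. Shares no code with
# rm_anova(), which goes through stats::aov().
oracle_rm_anova <- function(df, dv, id, within) {
  facs <- c(id, within)
  N <- nrow(df)
  grand <- mean(df[[dv]])
  eff <- list()  # keyed by subset signature, named vector over combos
  key_of <- function(d, S) do.call(paste, c(d[S], sep = "\r"))
  subsets <- unlist(lapply(seq_along(facs), function(k)
    utils::combn(facs, k, simplify = FALSE)), recursive = FALSE)
  subsets <- lapply(subsets[order(lengths(subsets))], sort)
  ss <- df_free <- numeric(0)
  for (S in subsets) {
    sig <- paste(S, collapse = "+")
    agg <- stats::aggregate(df[[dv]], df[S], mean)
    vals <- agg$x
    names(vals) <- key_of(agg, S)
    e <- vals - grand
    for (Tsig in names(eff)) {
      Tfac <- strsplit(Tsig, "+", fixed = TRUE)[[1L]]
      if (all(Tfac %in% S) && length(Tfac) < length(S))
        e <- e - eff[[Tsig]][key_of(agg, Tfac)]
    }
    eff[[sig]] <- e
    ss[sig] <- (N / length(e)) * sum(e^2)
    df_free[sig] <- prod(vapply(S, function(f) length(unique(df[[f]])) - 1L, 1L))
  }
  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  out <- lapply(effects, function(S) {
    esig <- paste(sort(S), collapse = "+")
    rsig <- paste(sort(c(id, S)), collapse = "+")
    Fv <- (ss[esig] / df_free[esig]) / (ss[rsig] / df_free[rsig])
    list(effect = paste(S, collapse = ":"),
         ss_effect = unname(ss[esig]), ss_error = unname(ss[rsig]),
         df_effect = unname(df_free[esig]), df_error = unname(df_free[rsig]),
         F = unname(Fv),
         pes = unname(ss[esig] / (ss[esig] + ss[rsig])))
  })
  names(out) <- vapply(out, `[[`, "", "effect")
  out
}

# Long-format 2x2 within fixture, n = 3, with hand-workable integers.
anova_fixture_2x2 <- function() {
  # y[participant, B, A]
  vals <- c(1, 2, 1,  2, 3, 3,  3, 4, 2,  5, 5, 6)
  expand.grid(participant_id = paste0("P", 1:3),
              B = c("b1", "b2"), A = c("a1", "a2"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(y = vals)
}

# Random generative logistic with an identifiable transition: asymptote gap
# >= 0.3, and steepness/inflection jointly constrained so that every design
# cell keeps |steepness * (Phi - inflection)| <= 6. Cells parked on a fully
# saturated asymptote carry no information about their shift (the shift and
# the inflection then trade off exactly), so recovery is only defined for
# curves whose cells all sample the dynamic range.
random_identifiable_logistic <- function(phi_range) {
  lower <- stats::runif(1, 0, 0.2)
  upper <- stats::runif(1, lower + 0.3, 1)
  range <- max(diff(phi_range), 1)
  steepness <- stats::runif(1, 6 / range, 12 / range)
  inflection <- stats::runif(1, phi_range[2] - 6 / steepness,
                             phi_range[1] + 6 / steepness)
  logistic_params(lower, upper, inflection, steepness)
}

# Phi values of the 12 design cells, enumerated directly from the piecewise
# definition (independent of phi_two_shift's vectorised arithmetic).
enumerate_cell_phis <- function(k, h) {
  out <- NULL
  for (w in c(0, 3.2)) for (dif in c("easy", "hard")) for (dur in c(9, 18, 27)) {
    phi <- dur
    if (dif == "hard") phi <- phi + k
    if (w == 0) phi <- phi + h
    out <- rbind(out, data.frame(bucket_weight_kg = w, difficulty = dif,
                                 duration_s = dur, phi = phi))
  }
  out
}

# Generative settings used across recovery tests: the study-scale design
# (48 participants) with a steep curve centred on the Phi range.
recovery_params <- function(seed, true_k = 24, true_h = 8, participant_sd = 0) {
  generative_params(true_k = true_k, true_h = true_h,
                    logistic = logistic_params(0.05, 0.95, 30, 0.3),
                    participant_sd = participant_sd, seed = seed)
}
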