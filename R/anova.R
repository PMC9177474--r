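#' Fully within-subjects repeated-measures ANOVA
#'
#' Univariate repeated-measures ANOVA for a balanced, fully within-subjects
#' factorial: every main effect and interaction is tested against its own
#' effect-by-participant interaction (`F = MS_effect / MS_error`), with
#' uncorrected p values from the F distribution by default and partial
#' eta-squared `SS_effect / (SS_effect + SS_error)` as the effect size. The
#' sums of squares are obtained through [stats::aov()] with an
#' `Error(participant/(...))` stratification; for a balanced design this is
#' the classical marginal-means decomposition, and the total corrected SS
#' equals participant SS plus the sum of all effect and error SS.
#'
#' No sphericity correction is applied by default; set
#' `correction = "greenhouse-geisser"` for Greenhouse-Geisser adjusted
#' degrees of freedom and p values (the F statistic is unchanged).
#'
#' If an effect's SS is numerically zero its F is reported as 0 with p = 1
#' (this covers the degenerate case where the error SS is also zero).
#'
#' @param data a `choice_table` from [aggregate_choices()] (analysed on the
#'   per-participant p(Bucket) values, untransformed) or a long data.frame
#'   with one row per participant x cell.
#' @param dv name of the response column.
#' @param id name of the participant identifier column.
#' @param within character vector of within-subject factor names, in display
#'   order. Defaults to duration, difficulty, weight for a `choice_table`.
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @param labels optional named character vector renaming factors for
#'   display, e.g. `c(duration_s = "Duration")`.
#' @return An object of class `"anova_rm"`: a data.frame with columns
#'   `effect`, `F`, `df_effect`, `df_error`, `p`, `partial_eta_sq` (plus
#'   `epsilon` and `p_gg` under correction), with the full SS decomposition
#'   in `attr(, "ss")` and the sample size in `attr(, "n")`.
#' @examples
#' trials <- generate_choices(experiment_design(n_participants = 10),
#'                            generative_params(seed = 3))
#' rm_anova(aggregate_choices(trials))
#' @export
rm_anova <- function(data, dv = "p_bucket", id = "participant_id",
                     within = NULL,
                     correction = c("none", "greenhouse-geisser"),
                     labels = NULL) {
  correction <- match.arg(correction)
  if (inherits(data, "choice_table")) {
    if (is.null(within))
      within <- intersect(c("duration_s", "difficulty", "bucket_weight_kg"),
                          data$cells)
    if (is.null(labels))
      labels <- c(duration_s = "Duration", difficulty = "Difficulty",
                  bucket_weight_kg = "Weight", bucket_side = "Side")
    data <- data$per_participant
  }
  if (is.null(within)) stop("'within' factors must be given for data.frame input")
  miss <- setdiff(c(dv, id, within), names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))

  df <- data[c(id, within, dv)]
  for (v in c(id, within)) df[[v]] <- factor(df[[v]])
  n <- nlevels(df[[id]])
  if (n < 2L) stop("need at least 2 participants")
  ncell <- prod(vapply(df[within], nlevels, 1L))
  tab <- table(df[[id]], interaction(df[within], drop = FALSE))
  if (any(tab != 1L))
    stop("design not balanced with one value per participant x cell ",
         "(missing or duplicated cells)")

  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(paste(dv, "~", rhs, "+ Error(", id, "/(", rhs, "))"))
  av <- stats::aov(fml, data = df)
  sm <- summary(av)

  terms_order <- attr(stats::terms(stats::as.formula(paste("~", rhs))),
                      "term.labels")
  ss_rows <- list()
  res <- data.frame(effect = terms_order, F = NA_real_,
                    df_effect = NA_integer_, df_error = NA_integer_,
                    p = NA_real_, partial_eta_sq = NA_real_,
                    stringsAsFactors = FALSE)
  total_ss <- sum((df[[dv]] - mean(df[[dv]]))^2)
  for (st in sm) {
    t1 <- st[[1L]]
    rn <- trimws(rownames(t1))
    for (r in seq_along(rn)) {
      if (rn[r] == "Residuals") next
      eff <- rn[r]
      ridx <- which(rn == "Residuals")
      ss_e <- t1[r, "Sum Sq"]; df_e <- t1[r, "Df"]
      ss_r <- if (length(ridx)) t1[ridx, "Sum Sq"] else NA_real_
      df_r <- if (length(ridx)) t1[ridx, "Df"] else NA_integer_
      i <- match(eff, res$effect)
      if (is.na(i)) next
      if (ss_e <= 1e-12 * max(total_ss, 1)) {
        Fv <- 0; pv <- 1
      } else {
        Fv <- (ss_e / df_e) / (ss_r / df_r)
        pv <- stats::pf(Fv, df_e, df_r, lower.tail = FALSE)
      }
      res$F[i] <- Fv
      res$df_effect[i] <- df_e
      res$df_error[i] <- df_r
      res$p[i] <- pv
      res$partial_eta_sq[i] <- if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0
      ss_rows[[eff]] <- c(ss_effect = ss_e, ss_error = ss_r)
    }
  }
  # participant stratum SS for the decomposition record
  part_name <- paste0("Error: ", id)
  part_ss <- if (!is.null(sm[[part_name]])) {
    t0 <- sm[[part_name]][[1L]]
    t0[trimws(rownames(t0)) == "Residuals", "Sum Sq"]
  } else NA_real_

  if (correction == "greenhouse-geisser") {
    res$epsilon <- NA_real_
    res$p_gg <- NA_real_
    for (i in seq_len(nrow(res))) {
      fs <- strsplit(res$effect[i], ":", fixed = TRUE)[[1L]]
      eps <- gg_epsilon(df, dv, id, fs)
      res$epsilon[i] <- eps
      res$p_gg[i] <- if (res$F[i] == 0) 1 else
        stats::pf(res$F[i], eps * res$df_effect[i], eps * res$df_error[i],
                  lower.tail = FALSE)
    }
  }

  ss_tab <- do.call(rbind, ss_rows)
  attr(res, "ss") <- ss_tab
  attr(res, "ss_participant") <- part_ss
  attr(res, "ss_total") <- total_ss
  attr(res, "n") <- n
  attr(res, "labels") <- labels
  class(res) <- c("anova_rm", "data.frame")
  res
}

# Greenhouse-Geisser epsilon for one effect: covariance of per-participant
# contrast scores on the effect's marginal means, eps = tr(S)^2/(d tr(S^2)).
gg_epsilon <- function(df, dv, id, factors) {
  arr <- tapply(df[[dv]], df[c(id, factors)], mean)
  mat <- matrix(arr, nrow = dim(arr)[1L])
  Cs <- lapply(rev(factors), function(f) {
    L <- nlevels(df[[f]])
    stats::contr.poly(L)  # orthonormal columns
  })
  M <- Reduce(kronecker, Cs)
  scores <- mat %*% M
  S <- stats::cov(scores)
  d <- ncol(M)
  tr <- sum(diag(as.matrix(S)))
  tr^2 / (d * sum(S * S))
}

#' @export
print.anova_rm <- function(x, digits = 3, ...) {
  labels <- attr(x, "labels")
  fmt_eff <- function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1L]]
    if (!is.null(labels))
      parts <- ifelse(parts %in% names(labels), labels[parts], parts)
    paste(parts, collapse = " × ")
  }
  cat("Repeated-measures ANOVA (fully within-subjects, n = ",
      attr(x, "n"), ")\n", sep = "")
  out <- data.frame(Effect = vapply(x$effect, fmt_eff, ""),
                    F = sprintf("%.2f", x$F),
                    df = sprintf("(%d, %d)", x$df_effect, x$df_error),
                    p = format.pval(x$p, digits = digits, eps = 1e-3),
                    `eta_p^2` = sprintf("%.2f", x$partial_eta_sq),
                    check.names = FALSE)
  if (!is.null(x$p_gg)) {
    out$epsilon <- sprintf("%.3f", x$epsilon)
    out$`p[GG]` <- format.pval(x$p_gg, digits = digits, eps = 1e-3)
  }
  print(out, row.names = FALSE, right = FALSE)
  invisible(x)
}
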