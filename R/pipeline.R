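#' Configuration for an end-to-end analysis run
#'
#' @param input path to a trial CSV, or a trial data.frame.
#' @param variant Phi-mapping variant, `"two_shift"` or `"one_shift"`.
#' @param roles a [level_roles()] declaration.
#' @param k_grid,h_grid shift-parameter search grids.
#' @param fixed_h optional frozen `h` for an additional transfer fit.
#' @param ci_level confidence level for the within-participant CIs.
#' @param followup_alpha follow-up two-way ANOVAs per difficulty level are
#'   run when the three-way interaction's uncorrected p is at or below this
#'   threshold (0.05 by default).
#' @param column_map optional schema adapter passed to [read_trials()].
#' @param performance optional exposure-performance data.frame (see
#'   [generate_exposure_performance()]) for the descriptive t-test stage.
#' @param seed integer seed recorded for provenance.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input, variant = c("two_shift", "one_shift"),
                       roles = level_roles(),
                       k_grid = -36:72, h_grid = -36:36, fixed_h = NULL,
                       ci_level = 0.95, followup_alpha = 0.05,
                       column_map = NULL, performance = NULL, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(roles, "level_roles"))
  if (length(h_grid) == 0L || (variant == "two_shift" && length(k_grid) == 0L))
    stop("shift grids must be non-empty")
  structure(list(input = input, variant = variant, roles = roles,
                 k_grid = k_grid, h_grid = h_grid, fixed_h = fixed_h,
                 ci_level = ci_level, followup_alpha = followup_alpha,
                 column_map = column_map, performance = performance,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: trial reading/validation, aggregation to p(Bucket),
#' the three-way within-subjects ANOVA, follow-up two-way ANOVAs per
#' difficulty level when the three-way interaction is significant at the
#' configured threshold, within-participant CIs for the empty-vs-loaded
#' difference in each difficulty x duration cell, the Phi-model grid fit,
#' and (when `fixed_h` is configured) the transfer fit. Exposure-performance
#' descriptives (error rate and mean RT per difficulty, paired t tests) are
#' computed when performance data is supplied. Fully deterministic given the
#' configuration; any stage failure is reported with the stage name.
#'
#' @param config a [run_config()].
#' @return An object of class `"analysis_report"`.
#' @examples
#' trials <- generate_choices(experiment_design(n_participants = 8),
#'                            generative_params(seed = 11))
#' rep <- run_pipeline(run_config(trials, k_grid = 16:32, h_grid = 0:16))
#' rep$phi_fit
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  checksum <- NA_character_
  trials <- stage("read_trials", {
    if (is.character(config$input)) {
      checksum <- unname(tools::md5sum(config$input))
      read_trials(config$input, column_map = config$column_map, quiet = TRUE)
    } else config$input
  })
  if (is.character(config$input))
    checksum <- unname(tools::md5sum(config$input))

  choices <- stage("aggregate_choices", aggregate_choices(trials))
  anova_full <- stage("rm_anova", rm_anova(choices))

  followups <- NULL
  i3 <- grep(":.*:", anova_full$effect)
  p3 <- if (length(i3)) anova_full$p[i3[1L]] else NA_real_
  if (isTRUE(p3 <= config$followup_alpha)) {
    followups <- stage("followup_anovas", {
      per <- choices$per_participant
      out <- list()
      for (lev in unique(per$difficulty)) {
        sub <- per[per$difficulty == lev, ]
        out[[as.character(lev)]] <-
          rm_anova(sub, dv = "p_bucket", id = "participant_id",
                   within = c("duration_s", "bucket_weight_kg"),
                   labels = c(duration_s = "Duration",
                              bucket_weight_kg = "Weight"))
      }
      out
    })
  }

  cis <- stage("within_ci", {
    per <- choices$per_participant
    r <- config$roles
    cells <- unique(per[c("difficulty", "duration_s")])
    cells <- cells[order(cells$difficulty, cells$duration_s), , drop = FALSE]
    half <- mapply(function(dif, dur) {
      sel <- per$difficulty == dif & per$duration_s == dur
      e <- per[sel & per$bucket_weight_kg == r$empty_weight, ]
      l <- per[sel & per$bucket_weight_kg == r$loaded_weight, ]
      e <- e[order(e$participant_id), ]; l <- l[order(l$participant_id), ]
      within_ci(e$p_bucket, l$p_bucket, level = config$ci_level)
    }, cells$difficulty, cells$duration_s)
    cbind(cells, ci_half_width = unname(half))
  })

  fit <- stage("grid_fit",
               phifit(choices, variant = config$variant, roles = config$roles,
                      k_grid = config$k_grid, h_grid = config$h_grid))
  transfer <- if (!is.null(config$fixed_h)) {
    stage("transfer_fit",
          phifit(choices, variant = config$variant, roles = config$roles,
                 k_grid = config$k_grid, fixed_h = config$fixed_h))
  } else NULL

  descriptives <- if (!is.null(config$performance)) {
    stage("exposure_descriptives", exposure_descriptives(config$performance))
  } else NULL

  structure(list(choices = choices,
                 anova = anova_full,
                 followups = followups,
                 within_cis = cis,
                 phi_fit = fit,
                 transfer_fit = transfer,
                 descriptives = descriptives,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("phichoice")),
                   seed = config$seed,
                   variant = config$variant,
                   k_grid = range(config$k_grid),
                   h_grid = range(config$h_grid),
                   fixed_h = config$fixed_h,
                   ci_level = config$ci_level,
                   followup_alpha = config$followup_alpha,
                   input_checksum = checksum,
                   n_trials = nrow(trials))),
            class = "analysis_report")
}

# Per-difficulty error rates and mean RTs from an exposure block, with
# paired t tests on the per-participant means (two levels assumed).
exposure_descriptives <- function(perf) {
  req <- c("participant_id", "difficulty", "correct", "rt")
  miss <- setdiff(req, names(perf))
  if (length(miss))
    stop("performance table lacks column(s): ", paste(miss, collapse = ", "))
  agg <- stats::aggregate(list(error_rate = 1 - perf$correct, mean_rt = perf$rt),
                          perf[c("participant_id", "difficulty")],
                          FUN = mean)
  levs <- sort(unique(agg$difficulty))
  group <- stats::aggregate(agg[c("error_rate", "mean_rt")],
                            agg["difficulty"], FUN = mean)
  tests <- NULL
  if (length(levs) == 2L) {
    a <- agg[agg$difficulty == levs[1L], ]
    b <- agg[agg$difficulty == levs[2L], ]
    a <- a[order(a$participant_id), ]; b <- b[order(b$participant_id), ]
    tests <- list(error_rate = paired_t(b$error_rate, a$error_rate),
                  mean_rt = paired_t(b$mean_rt, a$mean_rt),
                  contrast = paste(levs[2L], "-", levs[1L]))
  }
  list(per_participant = agg, group = group, tests = tests)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("=== Choice analysis report ===\n\n")
  print(x$choices)
  cat("\n")
  print(x$anova)
  if (!is.null(x$followups)) {
    for (nm in names(x$followups)) {
      cat("\nFollow-up (difficulty = ", nm, "):\n", sep = "")
      print(x$followups[[nm]])
    }
  }
  cat("\nWithin-participant ", 100 * x$provenance$ci_level,
      "% CIs (empty - loaded):\n", sep = "")
  print(x$within_cis, row.names = FALSE)
  cat("\n")
  print(x$phi_fit)
  if (!is.null(x$transfer_fit)) {
    cat("\nTransfer fit:\n")
    print(x$transfer_fit)
  }
  if (!is.null(x$descriptives)) {
    cat("\nExposure-block descriptives:\n")
    print(x$descriptives$group, row.names = FALSE)
    if (!is.null(x$descriptives$tests)) {
      tt <- x$descriptives$tests
      cat(sprintf("  error rate (%s): t(%d) = %.2f, p = %.3g, d = %.2f\n",
                  tt$contrast, tt$error_rate$df, tt$error_rate$t,
                  tt$error_rate$p, tt$error_rate$cohens_d))
      cat(sprintf("  mean RT    (%s): t(%d) = %.2f, p = %.3g, d = %.2f\n",
                  tt$contrast, tt$mean_rt$df, tt$mean_rt$t,
                  tt$mean_rt$p, tt$mean_rt$cohens_d))
    }
  }
  invisible(x)
}

#' Serialise an analysis report (or a Phi fit) to JSON
#'
#' Every number in the JSON is traceable to one of the package's
#' operations: cell means, ANOVA rows, CI half-widths, fit parameters and
#' per-cell (Phi, observed, predicted) triples, plus the provenance block.
#'
#' @param x an `"analysis_report"` or `"phifit"` object.
#' @param path output file; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_json <- function(x, path = NULL) {
  to_list <- function(obj) {
    if (inherits(obj, "phifit")) {
      list(variant = obj$variant,
           k = if (obj$variant == "two_shift") obj$k else NULL,
           h = obj$h, fixed_h = obj$fixed_h,
           logistic = unclass(obj$logistic),
           r_squared = obj$r_squared,
           points = obj$fitted_points)
    } else if (inherits(obj, "anova_rm")) {
      as.data.frame(obj)
    } else obj
  }
  payload <- if (inherits(x, "phifit")) to_list(x) else {
    list(group_means = x$choices$group,
         n_participants = x$choices$n_participants,
         anova = to_list(x$anova),
         followups = lapply(x$followups, to_list),
         within_cis = x$within_cis,
         phi_fit = to_list(x$phi_fit),
         transfer_fit = if (!is.null(x$transfer_fit)) to_list(x$transfer_fit),
         descriptives = x$descriptives,
         provenance = x$provenance)
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
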