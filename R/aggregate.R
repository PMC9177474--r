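#' Aggregate trial-level choices into per-participant and group p(Bucket)
#'
#' Computes each participant's probability of choosing the bucket task in
#' every weight x difficulty x duration cell, and the group mean per cell.
#' By default choices are aggregated regardless of where the bucket stood
#' (`collapse_side = TRUE`). The design must be balanced: every participant
#' must contribute the same number of trials to every cell.
#'
#' @param trials data.frame of trial records with columns `participant_id`,
#'   `bucket_weight_kg`, `difficulty`, `duration_s`, `bucket_side`, `choice`
#'   (values `"bucket"`/`"cognitive"`), as produced by [generate_choices()]
#'   or [read_trials()].
#' @param collapse_side if `TRUE` (default) the side factor is pooled; if
#'   `FALSE` cells are weight x difficulty x duration x side.
#' @return An object of class `"choice_table"`: a list with
#'   `per_participant` (data.frame with a `p_bucket` column per cell),
#'   `group` (cell means), `n_participants`, and `cells` (the cell factors).
#' @examples
#' trials <- generate_choices(experiment_design(n_participants = 6),
#'                            generative_params(seed = 2))
#' ct <- aggregate_choices(trials)
#' ct$group
#' @export
aggregate_choices <- function(trials, collapse_side = TRUE) {
  req <- c("participant_id", "bucket_weight_kg", "difficulty", "duration_s",
           "bucket_side", "choice")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !trials$choice %in% c("bucket", "cognitive")
  if (any(bad))
    stop("non-binary choice coding in row(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  cell_vars <- c("bucket_weight_kg", "difficulty", "duration_s")
  if (!collapse_side) cell_vars <- c(cell_vars, "bucket_side")

  counts <- stats::aggregate(list(n = seq_len(nrow(trials))),
                             trials[c("participant_id", cell_vars)], FUN = length)
  # balance: every participant x full-factorial cell with the same trial count
  lv <- lapply(trials[cell_vars], unique)
  full <- expand.grid(c(list(participant_id = unique(trials$participant_id)), lv),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  merged <- merge(full, counts, all.x = TRUE)
  merged$n[is.na(merged$n)] <- 0L
  if (length(unique(merged$n)) != 1L) {
    off <- merged[merged$n != stats::median(merged$n), , drop = FALSE]
    stop("unbalanced design: participant x cell trial counts differ; offenders: ",
         paste(utils::head(paste0(off$participant_id, "/",
                                  apply(off[cell_vars], 1, paste, collapse = ":"),
                                  " (n=", off$n, ")"), 8L), collapse = ", "))
  }

  trials$is_bucket <- as.numeric(trials$choice == "bucket")
  per <- stats::aggregate(list(p_bucket = trials$is_bucket),
                          trials[c("participant_id", cell_vars)], FUN = mean)
  per <- per[do.call(order, per[c("participant_id", cell_vars)]), , drop = FALSE]
  rownames(per) <- NULL
  grp <- stats::aggregate(list(p_bucket = per$p_bucket), per[cell_vars], FUN = mean)
  grp <- grp[do.call(order, grp[cell_vars]), , drop = FALSE]
  rownames(grp) <- NULL
  structure(list(per_participant = per,
                 group = grp,
                 n_participants = length(unique(per$participant_id)),
                 cells = cell_vars),
            class = "choice_table")
}

#' @export
print.choice_table <- function(x, digits = 3, ...) {
  cat("Choice probabilities, n =", x$n_participants, "participants\n")
  cat("Group p(Bucket) per cell:\n")
  g <- x$group
  g$p_bucket <- round(g$p_bucket, digits)
  print(g, row.names = FALSE)
  invisible(x)
}

# Accept a choice_table or a bare group-means data.frame; return the group
# cell means with canonical column names.
as_cell_means <- function(x) {
  if (inherits(x, "choice_table")) {
    g <- x$group
    g <- g[, c("bucket_weight_kg", "difficulty", "duration_s", "p_bucket")]
    return(g)
  }
  if (is.data.frame(x)) {
    req <- c("bucket_weight_kg", "difficulty", "duration_s", "p_bucket")
    miss <- setdiff(req, names(x))
    if (length(miss))
      stop("cell means lack column(s): ", paste(miss, collapse = ", "))
    return(x[req])
  }
  stop("expected a choice_table or a data.frame of cell means")
}

# Check the cell means cover the full weight x difficulty x duration factorial.
check_full_factorial <- function(cm) {
  lv <- lapply(cm[c("bucket_weight_kg", "difficulty", "duration_s")], unique)
  full <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$bucket_weight_kg, d$difficulty, d$duration_s)
  missing <- setdiff(key(full), key(cm))
  if (length(missing))
    stop("incomplete factorial; missing cell(s): ",
         paste(missing, collapse = "; "))
  if (anyDuplicated(key(cm)))
    stop("duplicated cells in cell means")
  invisible(cm)
}
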