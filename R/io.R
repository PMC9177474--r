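#' Write trial records to the canonical long-format CSV
#'
#' Columns: `participant_id`, `bucket_weight_kg`, `difficulty`,
#' `duration_s`, `bucket_side`, `choice` (`"bucket"`/`"cognitive"`).
#' Generator parameters, when supplied, are echoed into the file header as
#' `# key = value` comment lines for provenance.
#'
#' @param trials trial data.frame (see [generate_choices()]).
#' @param path output file path.
#' @param params optional [generative_params()] (or any named list of
#'   scalars) echoed as header comments.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    flat <- if (inherits(params, "generative_params")) {
      c(true_k = params$true_k, true_h = params$true_h,
        lower = params$logistic$lower, upper = params$logistic$upper,
        inflection = params$logistic$inflection,
        steepness = params$logistic$steepness,
        participant_sd = params$participant_sd,
        side_shift = params$side_shift, seed = params$seed)
    } else unlist(params)
    for (nm in names(flat))
      writeLines(sprintf("# %s = %s", nm, format(flat[[nm]])), con)
  }
  utils::write.csv(trials, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate trial records from CSV
#'
#' Reads a long-format trial CSV (header lines starting with `#` are
#' skipped), optionally remapping column names and choice codings from a
#' foreign schema — e.g. an external data deposit whose columns are named
#' differently — via `column_map`. Records are validated: required columns
#' present, choice coding binary, factor levels enumerated.
#'
#' @param path CSV file path.
#' @param column_map optional named list adapting a foreign schema. Names
#'   are the canonical fields (`participant_id`, `bucket_weight_kg`,
#'   `difficulty`, `duration_s`, `bucket_side`, `choice`), values the source
#'   column names. An optional `choice_coding` entry is a named character
#'   vector mapping the source's choice values onto `"bucket"` and
#'   `"cognitive"`, e.g. `c("1" = "bucket", "0" = "cognitive")`.
#' @param quiet suppress the factor-level echo.
#' @return validated trial data.frame in canonical form.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' trials <- generate_choices(experiment_design(n_participants = 2),
#'                            generative_params(seed = 5))
#' write_trials(trials, f)
#' identical(read_trials(f, quiet = TRUE), trials)
#' @export
read_trials <- function(path, column_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  canon <- c("participant_id", "bucket_weight_kg", "difficulty",
             "duration_s", "bucket_side", "choice")
  coding <- NULL
  if (!is.null(column_map)) {
    coding <- column_map$choice_coding
    column_map$choice_coding <- NULL
    unknown <- setdiff(names(column_map), canon)
    if (length(unknown))
      stop("column_map names unknown field(s): ", paste(unknown, collapse = ", "))
    src_missing <- setdiff(unlist(column_map), names(raw))
    if (length(src_missing))
      stop("source file lacks mapped column(s): ",
           paste(src_missing, collapse = ", "))
    for (field in names(column_map))
      raw[[field]] <- raw[[column_map[[field]]]]
  }
  miss <- setdiff(canon, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- raw[canon]
  out$participant_id <- as.character(out$participant_id)
  out$difficulty <- as.character(out$difficulty)
  out$bucket_side <- as.character(out$bucket_side)
  out$choice <- as.character(out$choice)
  if (!is.null(coding)) {
    mapped <- unname(coding[out$choice])
    bad <- which(is.na(mapped))
    if (length(bad))
      stop("choice values outside the declared coding at row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
    out$choice <- mapped
  }
  bad <- which(!out$choice %in% c("bucket", "cognitive"))
  if (length(bad))
    stop("non-binary choice coding at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (!is.numeric(out$bucket_weight_kg) || !is.numeric(out$duration_s))
    stop("'bucket_weight_kg' and 'duration_s' must be numeric")
  out$bucket_weight_kg <- as.numeric(out$bucket_weight_kg)
  out$duration_s <- as.numeric(out$duration_s)
  if (!quiet) {
    message("read ", nrow(out), " trials, ",
            length(unique(out$participant_id)), " participants; levels: ",
            "weight {", paste(sort(unique(out$bucket_weight_kg)), collapse = ", "),
            "}, difficulty {", paste(sort(unique(out$difficulty)), collapse = ", "),
            "}, duration {", paste(sort(unique(out$duration_s)), collapse = ", "),
            "}, side {", paste(sort(unique(out$bucket_side)), collapse = ", "), "}")
  }
  out
}
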