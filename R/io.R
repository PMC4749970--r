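# Delimited-text readers/writers and JSON run reports.
#
# Measurement tables: CSV with a header row; columns `time`, one column per
# output, and optionally `sd_<output>` columns carrying per-point standard
# deviations.  Input tables: `time` plus one column per input.  Round trips
# are lossless to within float formatting.

#' Read a measurement table
#'
#' @param path CSV file: header row with `time`, one column per output and
#'   optional `sd_<output>` columns.
#' @return a [measurement_set()]; when no sd columns are present the weights
#'   default to the identity (a message notes this).
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("measurement file must have a 'time' column", call. = FALSE)
  if (is.unsorted(df$time, strictly = TRUE))
    stop("'time' column must be strictly increasing", call. = FALSE)
  sd_cols <- grep("^sd_", names(df), value = TRUE)
  out_cols <- setdiff(names(df), c("time", sd_cols))
  if (!length(out_cols))
    stop("measurement file has no output columns", call. = FALSE)
  for (cc in c(out_cols, sd_cols))
    if (!is.numeric(df[[cc]]))
      stop("non-numeric values in column '", cc, "'", call. = FALSE)
  sds <- NULL
  if (length(sd_cols)) {
    want <- paste0("sd_", out_cols)
    missing_sd <- setdiff(sd_cols, want)
    if (length(missing_sd))
      stop("sd column without matching output: ",
           paste(missing_sd, collapse = ", "), call. = FALSE)
    sds <- matrix(0, nrow(df), length(out_cols))
    for (j in seq_along(out_cols)) {
      cn <- paste0("sd_", out_cols[j])
      if (!cn %in% names(df))
        stop("missing sd column '", cn, "' (give sds for all outputs or none)",
             call. = FALSE)
      sds[, j] <- df[[cn]]
    }
  } else {
    message("no sd_* columns: using identity weighting")
  }
  measurement_set(df$time, as.matrix(df[out_cols]), sds = sds,
                  output_labels = out_cols)
}

#' Write a measurement table
#'
#' @param data a [measurement_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  stopifnot(inherits(data, "measurement_set"))
  df <- data.frame(time = data$sample_times, check.names = FALSE)
  for (j in seq_len(data$n_outputs))
    df[[data$output_labels[j]]] <- data$observations[, j]
  if (!is.null(data$sds))
    for (j in seq_len(data$n_outputs))
      df[[paste0("sd_", data$output_labels[j])]] <- data$sds[, j]
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a known-input table
#'
#' @param path CSV file: header row with `time` plus one column per input.
#' @param interpolation passed to [known_input()].
#' @return a [known_input()].
#' @export
read_input_table <- function(path, interpolation = "linear") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("input file must have a 'time' column", call. = FALSE)
  if (is.unsorted(df$time, strictly = TRUE))
    stop("'time' column must be strictly increasing", call. = FALSE)
  cols <- setdiff(names(df), "time")
  if (!length(cols)) stop("input file has no input columns", call. = FALSE)
  ki <- known_input(df$time, as.matrix(df[cols]), interpolation = interpolation)
  ki$input_labels <- cols
  ki
}

#' Write solution trajectories to CSV
#'
#' Writes time, state estimates, hidden-input estimates and fitted outputs on
#' the solution's report grid.
#'
#' @param solution a [solve_den()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(solution, path) {
  stopifnot(inherits(solution, "den_solution"))
  se <- solution$state_estimate
  w <- eval_hidden_input(solution$hidden_input, se$times)
  df <- data.frame(time = se$times)
  for (j in seq_len(ncol(se$states)))
    df[[paste0("xhat_", se$state_labels[j])]] <- se$states[, j]
  for (j in seq_len(ncol(w)))
    df[[paste0("what_", se$state_labels[j])]] <- w[, j]
  for (j in seq_len(ncol(se$outputs)))
    df[[paste0("yhat_", se$output_labels[j])]] <- se$outputs[, j]
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an AUC table to CSV
#'
#' @param auc an `auc_table` from [compute_auc()].
#' @param path output CSV path.
#' @export
write_auc <- function(auc, path) {
  df <- data.frame(component = names(auc$per_component),
                   auc = unname(auc$per_component),
                   fraction = if (auc$all_zero) NA else unname(auc$fractions))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' The report echoes the configuration, package version, seed and config
#' hash, plus the objective breakdown, AUC table and identified targets —
#' enough, together with the input files, to reproduce the run.
#'
#' @param solution a [solve_den()] result.
#' @param path output JSON path.
#' @param config_echo optional list echoed verbatim (e.g. the parsed YAML
#'   run configuration).
#' @param seed master seed recorded in the report.
#' @param extra optional named list appended to the report.
#' @export
write_report <- function(solution, path, config_echo = NULL, seed = NULL,
                         extra = NULL) {
  stopifnot(inherits(solution, "den_solution"))
  auc <- compute_auc(solution$hidden_input)
  targets <- identify_targets(auc)
  report <- c(list(
    package = "dynelnet",
    version = as.character(utils::packageVersion("dynelnet")),
    seed = seed,
    config_hash = config_hash(config_echo),
    config = config_echo,
    model = solution$model_name,
    solver_status = solution$objective$solver_status,
    objective = solution$objective[c("total", "fit_term", "l1_term", "l2_term")],
    regularisation = list(lambda1 = solution$config$lambda1,
                          lambda2 = solution$config$lambda2),
    auc = as.list(auc$per_component),
    target_nodes = targets$nodes,
    target_cumulative_fraction = targets$cumulative_fraction,
    diagnostics = solution$diagnostics[c("iterations", "convergence",
                                         "transcription_gap")]
  ), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# stable content hash of a configuration list (md5 of its serialised form)
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}
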