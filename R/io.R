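event_log_columns <- function() {
  c("participant", "trial", "phase", "choice", "target",
    "v_internal", "v_external", "v_accept", "cost")
}

#' Write an event log as TSV with a JSON sidecar
#'
#' One row per decision phase; numerics are written with 6 significant
#' digits. The sidecar (`<path>.json`) records the task configuration, the
#' seed and the column schema version, so a run can be reproduced exactly.
#'
#' @param events Event table.
#' @param path Output TSV path.
#' @param config Optional [task_config()] recorded in the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, config = NULL, seed = NULL) {
  stopifnot(all(event_log_columns() %in% names(events)))
  out <- events
  for (cl in names(out))
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- signif(out[[cl]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(schema = "event_log_v1", columns = names(out),
                  config = if (!is.null(config)) unclass(config),
                  seed = seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read and validate an event-log TSV
#'
#' @param path TSV path written by [write_event_log()].
#' @return The event table; a missing required column is an error naming
#'   the column.
#' @export
read_event_log <- function(path) {
  events <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(event_log_columns(), names(events))
  if (length(missing))
    stop("event log is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  events
}

#' Write an ROI series as TSV with a JSON sidecar
#'
#' @param series An [roi_series()].
#' @param path Output TSV path (columns `time`, `signal`).
#' @return `path`, invisibly.
#' @export
write_roi_series <- function(series, path) {
  stopifnot(inherits(series, "roi_series"))
  tt <- series$start_time + (seq_along(series$signal) - 1) * series$tr
  utils::write.table(data.frame(time = tt, signal = signif(series$signal, 6)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = series$tr, start_time = series$start_time,
                            roi = series$roi_id,
                            participant = series$participant),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ROI series TSV with its JSON sidecar
#'
#' @param path TSV path written by [write_roi_series()].
#' @return An [roi_series()].
#' @export
read_roi_series <- function(path) {
  tab <- utils::read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  roi_series(tab$signal, tr = meta$tr, start_time = meta$start_time,
             roi_id = meta$roi, participant = meta$participant)
}

#' Write a run manifest
#'
#' @param manifest Named list describing a run (configs, seeds, paths).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$tool_version <-
    as.character(utils::packageVersion("dialexplore"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Summarize a locally deposited behavioural dataset
#'
#' Ingests a local copy of a deposited behavioural dataset (no download is
#' performed) through a user-supplied column mapping, then computes the
#' descriptive and model-based group results: grand decision-type
#' proportions, per-trial zero-exploration shares (the fraction of trials
#' with no internal and with no external exploration), and the group
#' coefficient tests from per-participant multinomial-logit fits on
#' z-scored predictors.
#'
#' @param path Path to a local TSV/CSV file with one row per decision
#'   phase.
#' @param mapping Named character vector or list mapping the canonical
#'   column names (`participant`, `trial`, `choice`, `v_internal`,
#'   `v_external`, `v_accept`, `cost`, and optionally the labels used for
#'   the three decisions via `label_internal`, `label_external`,
#'   `label_accept`) to the file's column names/values. May also be a path
#'   to a YAML/JSON file holding that mapping.
#' @param ridge,restarts Passed to [fit_mle()].
#' @return List with `proportions` (percent internal/external/accept),
#'   `zero_internal_pct`, `zero_external_pct`, `coefficients` (the
#'   [group_coefficient_tests()] table), and `n_participants`.
#' @export
reproduce_osf <- function(path, mapping, ridge = 1e-6, restarts = 5L) {
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
    mapping <- if (grepl("\\.json$", mapping))
      jsonlite::read_json(mapping, simplifyVector = TRUE)
    else yaml::read_yaml(mapping)
  mapping <- as.list(mapping)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("participant", "trial", "choice", "v_internal", "v_external",
            "v_accept", "cost")
  for (cl in need) {
    src <- mapping[[cl]] %||chr% cl
    if (!src %in% names(raw))
      stop("mapped column not found in file: ", src, " (for ", cl, ")",
           call. = FALSE)
    raw[[cl]] <- raw[[src]]
  }
  labels <- c(internal = mapping$label_internal %||chr% "internal",
              external = mapping$label_external %||chr% "external",
              accept = mapping$label_accept %||chr% "accept")
  raw$choice <- names(labels)[match(raw$choice, labels)]
  if (anyNA(raw$choice)) stop("unmapped choice labels in file", call. = FALSE)
  ev <- raw[, need]
  props <- 100 * vapply(c("internal", "external", "accept"),
                        function(k) mean(ev$choice == k), numeric(1))
  per_trial <- split(ev$choice, paste(ev$participant, ev$trial))
  zero_int <- 100 * mean(vapply(per_trial, function(ch)
    !any(ch == "internal"), logical(1)))
  zero_ext <- 100 * mean(vapply(per_trial, function(ch)
    !any(ch == "external"), logical(1)))
  fits <- lapply(split(ev, ev$participant), function(sub)
    fit_mle(standardize_predictors(sub), ridge = ridge, restarts = restarts))
  list(proportions = props, zero_internal_pct = zero_int,
       zero_external_pct = zero_ext,
       coefficients = group_coefficient_tests(fits),
       n_participants = length(fits))
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a
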