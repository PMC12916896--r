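#' Internal exploration value of a trial state
#'
#' The greatest product of mean point and (population) SD over the revealed
#' options: internal exploration is most valuable for an option that is both
#' rewarding and uncertain.
#'
#' @param state A `trial_state` with at least one revealed option.
#' @return A non-negative scalar on the points-squared scale.
#' @export
value_internal <- function(state) {
  revealed <- which(state$revealed)
  if (!length(revealed)) stop("no revealed option", call. = FALSE)
  max(vapply(revealed, function(i) option_point(state, i) * option_sd(state, i),
             numeric(1)))
}

#' External exploration value of a trial state
#'
#' The average point of all options, hidden ones included. Under the default
#' `environment_average_mode = "fixed_at_trial_start"` every option
#' contributes its original full-dial mean, so the value is constant within a
#' trial; under `"recomputed_each_phase"` revealed options contribute their
#' current remaining-dial means.
#'
#' @param state A `trial_state`.
#' @return A scalar in points.
#' @export
value_external <- function(state) {
  if (state$config$environment_average_mode == "fixed_at_trial_start")
    return(mean(rowMeans(state$dials)))
  mean(vapply(seq_len(nrow(state$dials)), function(i) {
    if (state$revealed[i]) option_point(state, i) else mean(state$dials[i, ])
  }, numeric(1)))
}

#' Accept value of a trial state
#'
#' The mean point of the best revealed option.
#'
#' @param state A `trial_state` with at least one revealed option.
#' @return A scalar in points.
#' @export
value_accept <- function(state) {
  revealed <- which(state$revealed)
  if (!length(revealed)) stop("no revealed option", call. = FALSE)
  max(vapply(revealed, function(i) option_point(state, i), numeric(1)))
}

#' The three decision values and cost of a trial state
#'
#' @param state A `trial_state`.
#' @return A named list with `v_internal`, `v_external`, `v_accept`, `cost`.
#' @export
value_triple <- function(state) {
  list(v_internal = value_internal(state),
       v_external = value_external(state),
       v_accept = value_accept(state),
       cost = state$cumulated_cost)
}

# --- model-variant registry ---------------------------------------------

#' Built-in registry of alternative value-function definitions
#'
#' Each slot (internal, external, accept) maps definition names to functions
#' of a `trial_state`. The first definition in each slot is the best-fit
#' definition (greatest point-by-SD product; environment average; best
#' revealed mean). The alternatives are plausible competitors — e.g. pure
#' uncertainty (max SD), the SD of the best option, hidden-option averages,
#' the mean of revealed points — so that model families of realistic size can
#' be enumerated for comparison exercises.
#'
#' @return A list with elements `internal`, `external`, `accept`, each a
#'   named list of functions `trial_state -> scalar`.
#' @export
value_registry <- function() {
  point_of <- function(state, i) option_point(state, i)
  sd_of <- function(state, i) option_sd(state, i)
  rev_stat <- function(state, f) {
    revealed <- which(state$revealed)
    vapply(revealed, function(i) f(state, i), numeric(1))
  }
  hidden_means <- function(state) {
    h <- which(!state$revealed)
    if (!length(h)) return(NA_real_)
    rowMeans(state$dials)[h]
  }
  list(
    internal = list(
      best_point_sd = function(state) max(rev_stat(state, function(s, i)
        point_of(s, i) * sd_of(s, i))),
      max_sd = function(state) max(rev_stat(state, sd_of)),
      sd_of_best = function(state) {
        pts <- rev_stat(state, point_of)
        sds <- rev_stat(state, sd_of)
        sds[which.max(pts)]
      },
      mean_point_sd = function(state) mean(rev_stat(state, function(s, i)
        point_of(s, i) * sd_of(s, i)))
    ),
    external = list(
      environment_mean = function(state) value_external(state),
      hidden_mean = function(state) {
        h <- hidden_means(state)
        if (anyNA(h)) 0 else mean(h)
      },
      max_hidden_mean = function(state) {
        h <- hidden_means(state)
        if (anyNA(h)) 0 else max(h)
      }
    ),
    accept = list(
      best_point = function(state) max(rev_stat(state, point_of)),
      mean_revealed_point = function(state) mean(rev_stat(state, point_of)),
      best_point_minus_sd = function(state) {
        pts <- rev_stat(state, point_of)
        sds <- rev_stat(state, sd_of)
        max(pts) - sds[which.max(pts)]
      }
    )
  )
}

#' Enumerate a family of choice-model variants
#'
#' Takes the Cartesian product of the registered internal, external and
#' accept value definitions, optionally crossed with including the cumulated
#' cost as a predictor or not. Duplicate definition names within a slot are
#' collapsed, the ordering is deterministic, and the best-fit trio (first
#' definition of each slot, with cost) is always variant 1.
#'
#' @param registry A registry as returned by [value_registry()].
#' @param include_cost Logical vector of cost settings to cross
#'   (default `c(TRUE, FALSE)`).
#' @return A data frame with columns `variant_id`, `internal_def`,
#'   `external_def`, `accept_def`, `includes_cost`.
#' @export
enumerate_model_family <- function(registry = value_registry(),
                                   include_cost = c(TRUE, FALSE)) {
  for (slot in c("internal", "external", "accept")) {
    if (!length(registry[[slot]]))
      stop("empty registry slot: ", slot, call. = FALSE)
  }
  ints <- unique(names(registry$internal))
  exts <- unique(names(registry$external))
  accs <- unique(names(registry$accept))
  costs <- unique(include_cost)
  grid <- expand.grid(includes_cost = costs, accept_def = accs,
                      external_def = exts, internal_def = ints,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("internal_def", "external_def", "accept_def", "includes_cost")]
  # best-fit trio (first of each slot, with cost) first
  key <- with(grid, paste(internal_def, external_def, accept_def, includes_cost))
  best <- paste(ints[1], exts[1], accs[1], TRUE)
  ord <- order(key != best)
  grid <- grid[ord, , drop = FALSE]
  grid <- cbind(variant_id = sprintf("m%03d", seq_len(nrow(grid))), grid)
  rownames(grid) <- NULL
  grid
}

#' Load a model-variant registry selection from a YAML or JSON config
#'
#' The config names which registered definitions to use per slot, e.g.
#' `internal: [best_point_sd, max_sd]`. Unknown definition names are an
#' error.
#'
#' @param path Path to a YAML or JSON file with keys `internal`, `external`,
#'   `accept` and optionally `include_cost`.
#' @param registry Base registry to subset (default [value_registry()]).
#' @return A list with the subset registry and the `include_cost` setting.
#' @export
family_config <- function(path, registry = value_registry()) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  out <- registry
  for (slot in c("internal", "external", "accept")) {
    if (!is.null(cfg[[slot]])) {
      unknown <- setdiff(cfg[[slot]], names(registry[[slot]]))
      if (length(unknown))
        stop("unknown ", slot, " definition(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      out[[slot]] <- registry[[slot]][cfg[[slot]]]
    }
  }
  list(registry = out,
       include_cost = if (is.null(cfg$include_cost)) c(TRUE, FALSE)
                      else as.logical(cfg$include_cost))
}
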