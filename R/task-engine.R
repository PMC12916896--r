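#' Configuration of the multiple-option decision-making task
#'
#' The task presents `n_positions` option slots. Each option carries
#' `n_dials` candidate point values ("dials"); exactly one hidden dial (the
#' true dial) determines the option's actual payoff. On every decision phase
#' the agent chooses between *internal exploration* (remove one decoy dial of
#' a revealed option, reducing its uncertainty), *external exploration*
#' (reveal a new option from a hidden position), or *accept* (end the trial
#' and collect the accepted option's true-dial points net of the cumulated
#' exploration cost). Each exploration costs `exploration_cost` points. At
#' most `n_dials - 1` internal explorations can be made per option (the true
#' dial is never removed) and at most `n_positions - 1` external explorations
#' per trial.
#'
#' @param n_positions Number of option slots (default 9).
#' @param n_dials Number of dials per option (default 4).
#' @param n_trials Number of trials in a session (default 100).
#' @param exploration_cost Cost in points of each exploration (default 1).
#' @param dial_value_range Inclusive integer interval from which dial values
#'   are drawn uniformly (default `c(1, 100)`).
#' @param environment_average_mode How the environment average (the external
#'   exploration value) is computed: `"fixed_at_trial_start"` (all options
#'   contribute their original full-dial means; constant within a trial) or
#'   `"recomputed_each_phase"` (revealed options contribute their current
#'   remaining-dial means).
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_positions = 9L, n_dials = 4L, n_trials = 100L,
                        exploration_cost = 1,
                        dial_value_range = c(1L, 100L),
                        environment_average_mode = c("fixed_at_trial_start",
                                                     "recomputed_each_phase")) {
  environment_average_mode <- match.arg(environment_average_mode)
  n_positions <- as.integer(n_positions)
  n_dials <- as.integer(n_dials)
  n_trials <- as.integer(n_trials)
  if (n_positions < 1L) stop("`n_positions` must be >= 1", call. = FALSE)
  if (n_dials < 2L) stop("`n_dials` must be >= 2", call. = FALSE)
  if (exploration_cost < 0) stop("`exploration_cost` must be >= 0", call. = FALSE)
  if (length(dial_value_range) != 2L || dial_value_range[1] > dial_value_range[2])
    stop("`dial_value_range` must be an increasing length-2 interval", call. = FALSE)
  structure(list(
    n_positions = n_positions,
    n_dials = n_dials,
    n_trials = n_trials,
    exploration_cost = exploration_cost,
    max_internal_per_option = n_dials - 1L,
    max_external_per_trial = n_positions - 1L,
    dial_value_range = dial_value_range,
    environment_average_mode = environment_average_mode
  ), class = "task_config")
}

#' Start a new trial
#'
#' Draws all option dials independently and uniformly (integers) over
#' `config$dial_value_range`, draws one true dial per option, and reveals a
#' single option at a uniformly random position. Cost starts at zero.
#'
#' @param config A [task_config()].
#' @return An object of class `trial_state` with fields `dials`
#'   (`n_positions x n_dials` matrix), `true_dial`, `removed` (logical
#'   matrix), `revealed`, `internal_count`, `external_count`,
#'   `cumulated_cost`, `terminated`, `accepted_option`, `net_gain`.
#' @export
new_trial <- function(config) {
  stopifnot(inherits(config, "task_config"))
  rng <- config$dial_value_range
  dials <- matrix(
    sample.int(rng[2] - rng[1] + 1L, config$n_positions * config$n_dials,
               replace = TRUE) + rng[1] - 1L,
    nrow = config$n_positions, ncol = config$n_dials
  )
  true_dial <- sample.int(config$n_dials, config$n_positions, replace = TRUE)
  revealed <- rep(FALSE, config$n_positions)
  revealed[sample.int(config$n_positions, 1L)] <- TRUE
  structure(list(
    config = config,
    dials = dials,
    true_dial = true_dial,
    removed = matrix(FALSE, config$n_positions, config$n_dials),
    revealed = revealed,
    internal_count = rep(0L, config$n_positions),
    external_count = 0L,
    cumulated_cost = 0,
    terminated = FALSE,
    accepted_option = NA_integer_,
    net_gain = NA_real_
  ), class = "trial_state")
}

#' Enumerate the legal actions of a trial state
#'
#' Accept is legal for every revealed option; internal exploration is legal
#' for every revealed option that still has more than one non-removed decoy
#' dial available (at most `n_dials - 1` removals per option); external
#' exploration is legal while fewer than `n_positions - 1` external
#' explorations have been made.
#'
#' @param state A non-terminated `trial_state`.
#' @return A data frame with columns `kind` (`"internal"`, `"external"`,
#'   `"accept"`) and `target` (option index, `NA` for external).
#' @export
legal_actions <- function(state) {
  stopifnot(inherits(state, "trial_state"))
  if (state$terminated) stop("trial already terminated", call. = FALSE)
  cfg <- state$config
  revealed <- which(state$revealed)
  out <- data.frame(kind = character(0), target = integer(0))
  internal_ok <- revealed[state$internal_count[revealed] < cfg$max_internal_per_option]
  if (length(internal_ok))
    out <- rbind(out, data.frame(kind = "internal", target = internal_ok))
  if (state$external_count < cfg$max_external_per_trial && any(!state$revealed))
    out <- rbind(out, data.frame(kind = "external", target = NA_integer_))
  out <- rbind(out, data.frame(kind = "accept", target = revealed))
  rownames(out) <- NULL
  out
}

#' Apply an action to a trial state
#'
#' Internal exploration removes one dial drawn uniformly from the target
#' option's non-removed, non-true dials (the true dial is never removed, so
#' removal always reduces uncertainty about the actual outcome) and adds the
#' exploration cost. External exploration reveals one hidden option chosen
#' uniformly at random and adds the exploration cost. Accept terminates the
#' trial with `net_gain` equal to the accepted option's true-dial points
#' minus the cumulated cost.
#'
#' @param state A non-terminated `trial_state`.
#' @param kind One of `"internal"`, `"external"`, `"accept"`.
#' @param target Option index (required for internal and accept).
#' @return The updated `trial_state`.
#' @export
apply_action <- function(state, kind, target = NA_integer_) {
  legal <- legal_actions(state)
  kind <- match.arg(kind, c("internal", "external", "accept"))
  ok <- if (kind == "external") any(legal$kind == "external") else
    any(legal$kind == kind & legal$target == target)
  if (!isTRUE(ok)) stop("illegal action: ", kind, call. = FALSE)
  cfg <- state$config
  if (kind == "internal") {
    cand <- setdiff(which(!state$removed[target, ]), state$true_dial[target])
    pick <- cand[sample.int(length(cand), 1L)]
    state$removed[target, pick] <- TRUE
    state$internal_count[target] <- state$internal_count[target] + 1L
    state$cumulated_cost <- state$cumulated_cost + cfg$exploration_cost
  } else if (kind == "external") {
    hidden <- which(!state$revealed)
    state$revealed[hidden[sample.int(length(hidden), 1L)]] <- TRUE
    state$external_count <- state$external_count + 1L
    state$cumulated_cost <- state$cumulated_cost + cfg$exploration_cost
  } else {
    state$terminated <- TRUE
    state$accepted_option <- as.integer(target)
    state$net_gain <- state$dials[target, state$true_dial[target]] - state$cumulated_cost
  }
  state
}

#' Mean of a revealed option's remaining dial values
#'
#' @param state A `trial_state`.
#' @param option Option index; must be revealed.
#' @return The arithmetic mean of the option's non-removed dial values.
#' @export
option_point <- function(state, option) {
  if (!state$revealed[option]) stop("option is not revealed", call. = FALSE)
  mean(state$dials[option, !state$removed[option, ]])
}

#' Population standard deviation of a revealed option's remaining dials
#'
#' Uses the population divisor (the remaining dial count), so a one-dial
#' option has SD exactly 0.
#'
#' @inheritParams option_point
#' @return Population SD of the non-removed dial values.
#' @export
option_sd <- function(state, option) {
  if (!state$revealed[option]) stop("option is not revealed", call. = FALSE)
  v <- state$dials[option, !state$removed[option, ]]
  sqrt(mean((v - mean(v))^2))
}
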