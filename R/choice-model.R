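#' Trinomial choice probabilities of the 10-parameter multinomial logit
#'
#' Two log-odds equations share a trinomial probability model with accept as
#' the reference category:
#' \deqn{\eta_{int} = \beta_1 + \beta_2 v_{int} + \beta_3 v_{ext} + \beta_4 v_{acc} + \beta_5 c}
#' \deqn{\eta_{ext} = \beta_6 + \beta_7 v_{int} + \beta_8 v_{ext} + \beta_9 v_{acc} + \beta_{10} c}
#' with \eqn{P(accept) = 1/(1 + e^{\eta_{int}} + e^{\eta_{ext}})}. Computed
#' with a log-sum-exp shift so it is stable for \eqn{|\eta|} up to ~700.
#'
#' @param beta Numeric 10-vector ordered as intercept, v_internal,
#'   v_external, v_accept, cost for the internal-vs-accept logit, then the
#'   same five for external-vs-accept.
#' @param row A list or one-row data frame with `v_internal`, `v_external`,
#'   `v_accept`, `cost`.
#' @return Named probability vector `c(internal=, external=, accept=)`
#'   summing to 1.
#' @export
choice_probabilities <- function(beta, row) {
  stopifnot(length(beta) == 10L)
  x <- c(1, row$v_internal, row$v_external, row$v_accept, row$cost)
  eta <- c(internal = sum(beta[1:5] * x), external = sum(beta[6:10] * x), accept = 0)
  if (any(!is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Z-score the four predictors within participant
#'
#' Each of `v_internal`, `v_external`, `v_accept`, `cost` is standardized to
#' mean 0 and population SD 1 (divisor n) across each participant's events.
#' A constant predictor maps to all zeros. Idempotent on standardized input.
#'
#' @param events Data frame with a `participant` column and the four
#'   predictor columns (plus any others, passed through untouched).
#' @return The data frame with the four predictor columns standardized.
#' @export
standardize_predictors <- function(events) {
  if (!nrow(events)) stop("empty event table", call. = FALSE)
  cols <- c("v_internal", "v_external", "v_accept", "cost")
  stopifnot(all(cols %in% names(events)))
  pid <- if ("participant" %in% names(events)) events$participant else "p1"
  for (p in unique(pid)) {
    idx <- pid == p
    for (cl in cols) {
      v <- events[[cl]][idx]
      s <- sqrt(mean((v - mean(v))^2))
      events[[cl]][idx] <- if (s > 0) (v - mean(v)) / s else 0
    }
  }
  events
}

# design matrix (events x 5) from a standardized event table
choice_design <- function(rows) {
  cbind(1, rows$v_internal, rows$v_external, rows$v_accept, rows$cost)
}

# penalized negative log-likelihood and its analytic gradient
choice_negloglik <- function(beta, X, y_int, y_ext, ridge) {
  eta1 <- drop(X %*% beta[1:5])
  eta2 <- drop(X %*% beta[6:10])
  m <- pmax(0, eta1, eta2)
  lse <- m + log(exp(-m) + exp(eta1 - m) + exp(eta2 - m))
  ll <- sum(y_int * eta1 + y_ext * eta2 - lse)
  -ll + ridge * sum(beta^2)
}

choice_negloglik_grad <- function(beta, X, y_int, y_ext, ridge) {
  eta1 <- drop(X %*% beta[1:5])
  eta2 <- drop(X %*% beta[6:10])
  m <- pmax(0, eta1, eta2)
  denom <- exp(-m) + exp(eta1 - m) + exp(eta2 - m)
  p1 <- exp(eta1 - m) / denom
  p2 <- exp(eta2 - m) / denom
  c(drop(crossprod(X, p1 - y_int)), drop(crossprod(X, p2 - y_ext))) +
    2 * ridge * beta
}

#' Fit the choice model by penalized maximum likelihood
#'
#' Maximizes the trinomial log-likelihood minus a small ridge penalty (which
#' guarantees a finite optimum under quasi-separation). BFGS with the
#' analytic gradient, started from the zero vector plus `restarts` random
#' initializations; the best penalized optimum is kept.
#'
#' @param rows Standardized event table (see [standardize_predictors()])
#'   with a `choice` column in `c("internal","external","accept")`.
#' @param ridge Ridge penalty weight (default 1e-6).
#' @param restarts Number of random restarts in addition to the zero start
#'   (default 5).
#' @return Object of class `choice_fit`: `beta` (named 10-vector),
#'   `log_likelihood` (unpenalized, in nats), `n_events`, `converged`,
#'   `ridge`.
#' @export
fit_mle <- function(rows, ridge = 1e-6, restarts = 5L) {
  stopifnot(nrow(rows) >= 1L, ridge >= 0)
  X <- choice_design(rows)
  y_int <- as.numeric(rows$choice == "internal")
  y_ext <- as.numeric(rows$choice == "external")
  starts <- c(list(rep(0, 10)),
              replicate(restarts, stats::rnorm(10, 0, 1), simplify = FALSE))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, choice_negloglik, choice_negloglik_grad,
                   X = X, y_int = y_int, y_ext = y_ext, ridge = ridge,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimizer failed on all restarts", call. = FALSE)
  beta <- best$par
  names(beta) <- beta_names()
  ll <- -choice_negloglik(beta, X, y_int, y_ext, ridge = 0)
  structure(list(beta = beta, log_likelihood = ll, n_events = nrow(rows),
                 converged = best$convergence == 0L, ridge = ridge),
            class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("Trinomial choice-model fit:", x$n_events, "events, logL =",
      format(x$log_likelihood, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$beta, 4))
  invisible(x)
}

beta_names <- function() {
  c("int_(Intercept)", "int_v_internal", "int_v_external", "int_v_accept",
    "int_cost",
    "ext_(Intercept)", "ext_v_internal", "ext_v_external", "ext_v_accept",
    "ext_cost")
}

#' Simulate choices of a softmax agent on the task
#'
#' Plays `n_trials` of the task. At every decision phase the agent computes
#' the three decision values and the cumulated cost, standardizes them
#' against its running within-session statistics (Welford mean/SD over the
#' phases seen so far; the contract for downstream fitting is post-hoc
#' re-standardization of the emitted table with
#' [standardize_predictors()]), evaluates [choice_probabilities()], restricts
#' to the legal actions with proportional renormalization, and samples an
#' action. Internal explorations target the revealed option with the largest
#' point-by-SD product (ties to the lowest position); accepts target the
#' best revealed option.
#'
#' If a `timing` config is supplied the table also carries decision-phase
#' onsets and reaction times: onsets advance by RT + ISI after explorations
#' and by RT + outcome duration + ITI after accepts.
#'
#' @param beta Generating 10-vector (on the standardized-predictor scale).
#' @param config A [task_config()].
#' @param n_trials Number of trials (default `config$n_trials`).
#' @param timing Optional [timing_config()] for onsets/RTs.
#' @param participant Participant label (default "p1").
#' @param norm_stats Optional fixed standardization statistics, a list with
#'   `mu` and `sd` (length-4, ordered v_internal, v_external, v_accept,
#'   cost). When supplied the agent z-scores against these instead of its
#'   running statistics; see [calibrate_norm_stats()].
#' @param registry Optional value-definition registry
#'   ([value_registry()]). When supplied, every registered alternative value
#'   definition is evaluated on the live trial state at each phase and
#'   emitted as extra columns `alt_<slot>_<name>`, so model variants can be
#'   fit to the same session afterwards.
#' @return Event table: one row per decision phase with columns
#'   `participant`, `trial`, `phase`, `choice`, `target`, `v_internal`,
#'   `v_external`, `v_accept`, `cost` (raw values), and `onset_s`, `rt_s`
#'   when `timing` is given.
#' @export
simulate_choices <- function(beta, config = task_config(),
                             n_trials = config$n_trials,
                             timing = NULL, participant = "p1",
                             norm_stats = NULL, registry = NULL) {
  stopifnot(length(beta) == 10L)
  fixed <- !is.null(norm_stats)
  # running standardization state (Welford)
  n_seen <- 0; mu <- rep(0, 4); m2 <- rep(0, 4)
  rows <- vector("list", n_trials * 4L)
  nrow_used <- 0L
  clock <- 0
  for (tr in seq_len(n_trials)) {
    state <- new_trial(config)
    phase <- 0L
    while (!state$terminated) {
      phase <- phase + 1L
      v <- value_triple(state)
      raw <- c(v$v_internal, v$v_external, v$v_accept, v$cost)
      if (fixed) {
        z <- ifelse(norm_stats$sd > 0, (raw - norm_stats$mu) / norm_stats$sd, 0)
      } else {
        n_seen <- n_seen + 1
        d <- raw - mu
        mu <- mu + d / n_seen
        m2 <- m2 + d * (raw - mu)
        sd_run <- sqrt(m2 / n_seen)
        z <- ifelse(sd_run > 0, (raw - mu) / sd_run, 0)
      }
      pr <- choice_probabilities(beta, list(v_internal = z[1], v_external = z[2],
                                            v_accept = z[3], cost = z[4]))
      legal <- legal_actions(state)
      kinds <- unique(legal$kind)
      pk <- pr[kinds]
      pk <- pk / sum(pk)
      kind <- kinds[sample.int(length(kinds), 1L, prob = pk)]
      target <- if (kind == "internal") {
        cand <- which(state$revealed &
                        state$internal_count < config$max_internal_per_option)
        scores <- vapply(cand, function(i)
          option_point(state, i) * option_sd(state, i), numeric(1))
        cand[which.max(scores)]
      } else if (kind == "accept") {
        cand <- which(state$revealed)
        pts <- vapply(cand, function(i) option_point(state, i), numeric(1))
        cand[which.max(pts)]
      } else NA_integer_
      row <- list(participant = participant, trial = tr, phase = phase,
                  choice = kind, target = target,
                  v_internal = v$v_internal, v_external = v$v_external,
                  v_accept = v$v_accept, cost = v$cost)
      if (!is.null(registry)) {
        for (slot in c("internal", "external", "accept")) {
          for (nm in names(registry[[slot]])) {
            row[[paste0("alt_", slot, "_", nm)]] <-
              registry[[slot]][[nm]](state)
          }
        }
      }
      if (!is.null(timing)) {
        rt <- sample_rt(timing, kind)
        row$onset_s <- clock
        row$rt_s <- rt
        clock <- clock + rt +
          if (kind == "accept")
            stats::runif(1, timing$outcome[1], timing$outcome[2]) +
              stats::runif(1, timing$iti[1], timing$iti[2])
          else stats::runif(1, timing$isi[1], timing$isi[2])
      }
      nrow_used <- nrow_used + 1L
      rows[[nrow_used]] <- row
      state <- apply_action(state, kind, target)
    }
  }
  do.call(rbind, lapply(rows[seq_len(nrow_used)], function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Calibrate fixed standardization statistics for a softmax agent
#'
#' Plays an unrecorded calibration session under the same parameters and
#' returns the population mean and SD of the four raw predictors over its
#' decision phases. Passing the result as `norm_stats` to
#' [simulate_choices()] makes the agent's z-scale agree closely with the
#' post-hoc re-standardization applied before fitting, so simulate-and-refit
#' exercises are not distorted by a drifting within-session scale.
#'
#' @inheritParams simulate_choices
#' @return List with `mu` and `sd` (length-4).
#' @export
calibrate_norm_stats <- function(beta, config = task_config(),
                                 n_trials = config$n_trials) {
  ev <- simulate_choices(beta, config, n_trials = n_trials)
  raw <- as.matrix(ev[, c("v_internal", "v_external", "v_accept", "cost")])
  list(mu = colMeans(raw),
       sd = apply(raw, 2, function(v) sqrt(mean((v - mean(v))^2))))
}

#' Standardize predictors against fixed statistics
#'
#' Z-scores the four predictor columns with supplied moments instead of the
#' table's own (used in simulate-and-refit studies, where the generating
#' parameters are defined on the agent's calibrated z-scale).
#'
#' @param events Event table.
#' @param norm_stats List with `mu` and `sd` as returned by
#'   [calibrate_norm_stats()].
#' @return The event table with standardized predictor columns.
#' @export
standardize_with <- function(events, norm_stats) {
  cols <- c("v_internal", "v_external", "v_accept", "cost")
  for (k in seq_along(cols)) {
    events[[cols[k]]] <- if (norm_stats$sd[k] > 0)
      (events[[cols[k]]] - norm_stats$mu[k]) / norm_stats$sd[k] else 0
  }
  events
}
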