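#' Bayesian information criterion of a choice-model fit
#'
#' @param fit A `choice_fit` (or any list with `log_likelihood` and
#'   `n_events`).
#' @param k Number of free parameters (default 10).
#' @return `k * log(n_events) - 2 * log_likelihood`; lower is better.
#' @export
bic <- function(fit, k = 10L) {
  stopifnot(fit$n_events >= 1L)
  k * log(fit$n_events) - 2 * fit$log_likelihood
}

#' Predicted-choice accuracy of a fit
#'
#' The predicted category is the argmax of the three fitted probabilities,
#' with ties broken by the fixed category order internal, external, accept.
#'
#' @param fit A `choice_fit`.
#' @param rows Standardized event table with a `choice` column.
#' @return Fraction of events whose observed choice equals the prediction.
#' @export
prediction_accuracy <- function(fit, rows) {
  stopifnot(nrow(rows) > 0L)
  X <- choice_design(rows)
  eta1 <- drop(X %*% fit$beta[1:5])
  eta2 <- drop(X %*% fit$beta[6:10])
  pred <- c("internal", "external", "accept")[
    max.col(cbind(eta1, eta2, 0), ties.method = "first")]
  mean(pred == rows$choice)
}

#' Random-effects Bayesian model selection with exceedance probabilities
#'
#' Variational scheme over model frequencies: with log evidences
#' \eqn{L_{nk}} (here typically \eqn{-BIC/2}), iterate
#' \eqn{u_{nk} \propto \exp(L_{nk} + \psi(\alpha_k) - \psi(\sum\alpha))}
#' with rows normalized and \eqn{\alpha_k = \alpha_0 + \sum_n u_{nk}} until
#' the concentrations change by less than `tol`. Exceedance probabilities —
#' the posterior probability that each model is the most frequent in the
#' population — are estimated by Monte-Carlo draws from the Dirichlet
#' posterior, counting argmax frequencies.
#'
#' @param log_evidence Numeric matrix, participants by models.
#' @param alpha0 Symmetric Dirichlet prior concentration (default 1).
#' @param n_samples Dirichlet Monte-Carlo draws (default 1e6).
#' @param tol Convergence tolerance on max |delta alpha| (default 1e-6).
#' @param max_iter Iteration cap (default 10000).
#' @return Object of class `bms_result`: `alpha`, `expected_prob`,
#'   `exceedance_prob`, `n_samples`, `iterations`.
#' @export
bms_exceedance <- function(log_evidence, alpha0 = 1, n_samples = 1e6,
                           tol = 1e-6, max_iter = 10000L) {
  log_evidence <- as.matrix(log_evidence)
  K <- ncol(log_evidence)
  if (K < 2L) stop("need >= 2 models", call. = FALSE)
  if (any(!is.finite(log_evidence))) stop("non-finite evidence", call. = FALSE)
  ids <- colnames(log_evidence)
  if (is.null(ids)) ids <- paste0("m", seq_len(K))
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lu <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
    if (it == max_iter)
      stop("BMS did not converge after ", max_iter, " iterations", call. = FALSE)
  }
  # Dirichlet draws via independent gammas
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              nrow = n_samples)
  xp <- tabulate(max.col(g, ties.method = "first"), nbins = K) / n_samples
  structure(list(alpha = stats::setNames(alpha, ids),
                 expected_prob = stats::setNames(alpha / sum(alpha), ids),
                 exceedance_prob = stats::setNames(xp, ids),
                 n_samples = n_samples, iterations = it),
            class = "bms_result")
}

#' Per-participant best-model counts
#'
#' For each participant, the model with the highest log evidence (lowest
#' BIC); exact ties are assigned to the first model id.
#'
#' @inheritParams bms_exceedance
#' @return Data frame with `model`, `count`, `percent` (percent of
#'   participants, summing to 100).
#' @export
best_fit_counts <- function(log_evidence) {
  log_evidence <- as.matrix(log_evidence)
  ids <- colnames(log_evidence)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(log_evidence)))
  best <- max.col(log_evidence, ties.method = "first")
  counts <- tabulate(best, nbins = ncol(log_evidence))
  data.frame(model = ids, count = counts,
             percent = 100 * counts / nrow(log_evidence))
}

#' Plausible group-level choice-model parameters
#'
#' Group means used as the centre of the generating distribution in
#' parameter-recovery simulations: the value and cost coefficients reflect
#' typical group estimates under standardized predictors (strong positive
#' weight of each decision's own value, strong negative weight of the accept
#' value on both exploratory branches, negative cost weights), and the
#' intercepts are set so a simulated group produces roughly a 30/40/30 split
#' of internal exploration, external exploration and accept decisions.
#'
#' @return Named numeric 10-vector.
#' @export
default_group_betas <- function() {
  stats::setNames(
    c(0.45, 2.558, 0.784, -3.540, -0.819,
      0.90, 0.450, 2.125, -5.193, -1.222),
    beta_names())
}

#' Parameter-recovery simulation
#'
#' For each synthetic participant: draw a generating 10-vector, simulate a
#' session with [simulate_choices()], re-standardize the emitted table with
#' [standardize_predictors()], refit with [fit_mle()], and correlate
#' generating with recovered values per parameter across participants
#' (Pearson r with two-sided p). A generating parameter with zero variance
#' across participants is flagged and its r reported as `NA`.
#'
#' @param gen_betas Matrix participants x 10 of generating parameters, or
#'   `NULL` to draw them as Normal(`group_betas`, `0.5*|group_betas| + 0.2`).
#' @param config A [task_config()].
#' @param n_trials Trials per simulated participant (default 100).
#' @param n_participants Number of participants when drawing (default 24).
#' @param group_betas Centre of the generating distribution.
#' @param standardization `"two_pass"` (default): each agent first plays an
#'   unrecorded calibration session to fix its standardization statistics
#'   ([calibrate_norm_stats()]), so the generating z-scale matches the
#'   post-hoc re-standardization used at fit time; `"running"`: the agent
#'   standardizes against its running statistics.
#' @param ridge,restarts Passed to [fit_mle()].
#' @return Object of class `recovery_report`: `generating`, `recovered`
#'   (matrices), `r`, `p` (length-10), `degenerate` (logical).
#' @export
parameter_recovery <- function(gen_betas = NULL, config = task_config(),
                               n_trials = 100L, n_participants = 24L,
                               group_betas = default_group_betas(),
                               standardization = c("two_pass", "running"),
                               ridge = 1e-6, restarts = 5L) {
  standardization <- match.arg(standardization)
  if (is.null(gen_betas)) {
    disp <- 0.5 * abs(group_betas) + 0.2
    gen_betas <- t(replicate(n_participants,
                             stats::rnorm(10, group_betas, disp)))
  }
  gen_betas <- as.matrix(gen_betas)
  stopifnot(ncol(gen_betas) == 10L, nrow(gen_betas) >= 3L)
  colnames(gen_betas) <- beta_names()
  recovered <- matrix(NA_real_, nrow(gen_betas), 10L,
                      dimnames = list(NULL, beta_names()))
  for (i in seq_len(nrow(gen_betas))) {
    ns <- if (standardization == "two_pass")
      calibrate_norm_stats(gen_betas[i, ], config, n_trials = n_trials)
    else NULL
    ev <- simulate_choices(gen_betas[i, ], config, n_trials = n_trials,
                           participant = sprintf("sim%02d", i),
                           norm_stats = ns)
    # refit on the same z-scale the generating parameters are defined on:
    # the agent's calibrated moments under two_pass, the session's own
    # moments otherwise
    rows <- if (standardization == "two_pass") standardize_with(ev, ns)
            else standardize_predictors(ev)
    # scope the optimizer's restart draws so the simulated sessions depend
    # only on the master seed, not on the number of restarts
    fit_seed <- sample.int(.Machine$integer.max, 1L)
    sim_state <- get(".Random.seed", envir = globalenv())
    set.seed(fit_seed)
    fit <- fit_mle(rows, ridge = ridge, restarts = restarts)
    assign(".Random.seed", sim_state, envir = globalenv())
    recovered[i, ] <- fit$beta
  }
  r <- p <- rep(NA_real_, 10L)
  degenerate <- rep(FALSE, 10L)
  for (j in 1:10) {
    if (stats::sd(gen_betas[, j]) == 0 || stats::sd(recovered[, j]) == 0) {
      degenerate[j] <- TRUE
      next
    }
    ct <- stats::cor.test(gen_betas[, j], recovered[, j])
    r[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  structure(list(generating = gen_betas, recovered = recovered,
                 r = stats::setNames(r, beta_names()),
                 p = stats::setNames(p, beta_names()),
                 degenerate = degenerate),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", nrow(x$generating), "participants\n")
  print(round(x$r, 3))
  cat("min r =", format(min(x$r, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Build the predictor table of a model variant
#'
#' Selects the variant's value definitions from the `alt_*` columns emitted
#' by [simulate_choices()] with a registry, maps them onto the canonical
#' predictor columns, and zeroes the cost column when the variant excludes
#' cost (the two cost coefficients are then pinned to zero by the ridge and
#' the variant has 8 effective parameters).
#'
#' @param events Event table carrying `alt_<slot>_<name>` columns.
#' @param variant One row of [enumerate_model_family()].
#' @return Event table on the canonical predictor columns, ready for
#'   [standardize_predictors()] and [fit_mle()].
#' @export
variant_rows <- function(events, variant) {
  cols <- c(internal = paste0("alt_internal_", variant$internal_def),
            external = paste0("alt_external_", variant$external_def),
            accept = paste0("alt_accept_", variant$accept_def))
  missing <- setdiff(cols, names(events))
  if (length(missing))
    stop("event table lacks variant column(s): ",
         paste(missing, collapse = ", "),
         " (simulate with a registry)", call. = FALSE)
  events$v_internal <- events[[cols["internal"]]]
  events$v_external <- events[[cols["external"]]]
  events$v_accept <- events[[cols["accept"]]]
  if (!variant$includes_cost) events$cost <- 0
  events
}

#' Fit every variant of a model family to every participant
#'
#' @param events Event table with `alt_*` columns covering all
#'   participants.
#' @param family Data frame from [enumerate_model_family()].
#' @param ridge,restarts Passed to [fit_mle()].
#' @return List with `bic` and `accuracy` matrices (participants x
#'   variants), `log_evidence` (`-bic/2`), and `k` per variant.
#' @export
compare_variants <- function(events, family, ridge = 1e-6, restarts = 1L) {
  pids <- unique(events$participant)
  k <- ifelse(family$includes_cost, 10L, 8L)
  bicm <- acc <- matrix(NA_real_, length(pids), nrow(family),
                        dimnames = list(pids, family$variant_id))
  for (v in seq_len(nrow(family))) {
    rows_all <- standardize_predictors(variant_rows(events, family[v, ]))
    for (p in seq_along(pids)) {
      rows <- rows_all[rows_all$participant == pids[p], , drop = FALSE]
      fit <- fit_mle(rows, ridge = ridge, restarts = restarts)
      bicm[p, v] <- bic(fit, k = k[v])
      acc[p, v] <- prediction_accuracy(fit, rows)
    }
  }
  list(bic = bicm, accuracy = acc, log_evidence = -bicm / 2, k = k)
}
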