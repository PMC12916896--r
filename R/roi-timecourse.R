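#' Construct an ROI time series
#'
#' @param signal Numeric vector sampled uniformly at `tr` seconds.
#' @param tr Repetition time in seconds (default 2).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param roi_id,participant Labels.
#' @return Object of class `roi_series`.
#' @export
roi_series <- function(signal, tr = 2, start_time = 0,
                       roi_id = "roi", participant = "p1") {
  stopifnot(is.numeric(signal), all(is.finite(signal)), tr > 0)
  structure(list(signal = signal, tr = tr, start_time = start_time,
                 roi_id = roi_id, participant = participant),
            class = "roi_series")
}

#' Configuration for event-locked beta time-course analysis
#'
#' @param window Event-relative window in seconds (default `c(-5, 13)`).
#' @param grid_dt Grid step in seconds (default 0.01, so sub-TR peak times
#'   are expressible).
#' @param regressors Event-table columns entered (simultaneously) in the
#'   per-timepoint GLM, besides the intercept.
#' @param standardize Z-score the regressors (population SD) across the
#'   epoched events before regression (default TRUE).
#' @return Object of class `timecourse_config`.
#' @export
timecourse_config <- function(window = c(-5, 13), grid_dt = 0.01,
                              regressors = c("v_internal", "v_external",
                                             "v_accept", "cost"),
                              standardize = TRUE) {
  stopifnot(window[1] <= 0, window[2] >= 0, grid_dt > 0)
  structure(list(window = window, grid_dt = grid_dt, regressors = regressors,
                 standardize = standardize), class = "timecourse_config")
}

#' Event-locked beta time course for one participant
#'
#' The tr-sampled ROI series is interpolated (cubic spline) onto the
#' event-relative grid; at each grid time, the interpolated amplitudes
#' across events are regressed by ordinary least squares on the standardized
#' regressors plus an intercept. The per-timepoint GLM makes no assumption
#' about the response waveform. Events whose epoch extends beyond the
#' sampled span are dropped with a warning.
#'
#' @param series An [roi_series()].
#' @param events Event table with `onset_s` and the regressor columns.
#' @param config A [timecourse_config()].
#' @return Matrix `length(times) x (1 + n regressors)` of beta weights with
#'   attributes `times` and `n_events`.
#' @export
epoch_betas <- function(series, events, config = timecourse_config()) {
  stopifnot(inherits(series, "roi_series"))
  t_series <- series$start_time + (seq_along(series$signal) - 1) * series$tr
  span <- range(t_series)
  keep <- events$onset_s + config$window[1] >= span[1] &
          events$onset_s + config$window[2] <= span[2]
  if (!all(keep)) {
    warning(sum(!keep), " event(s) dropped at series edges", call. = FALSE)
    events <- events[keep, , drop = FALSE]
  }
  n_ev <- nrow(events)
  p <- length(config$regressors)
  if (n_ev < p + 2L) stop("fewer events than regressors + intercept",
                          call. = FALSE)
  Z <- as.matrix(events[, config$regressors, drop = FALSE])
  if (config$standardize) {
    Z <- apply(Z, 2, function(v) {
      s <- sqrt(mean((v - mean(v))^2))
      if (s > 0) (v - mean(v)) / s else rep(0, length(v))
    })
  }
  X <- cbind(`(Intercept)` = 1, Z)
  times <- seq(config$window[1], config$window[2], by = config$grid_dt)
  f <- stats::splinefun(t_series, series$signal, method = "fmm")
  Y <- matrix(f(outer(events$onset_s, times, "+")), nrow = n_ev)
  xtx <- crossprod(X)
  if (qr(xtx)$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)
  beta <- t(solve(xtx, crossprod(X, Y)))  # times x regressors
  colnames(beta) <- colnames(X)
  attr(beta, "times") <- times
  attr(beta, "n_events") <- n_ev
  beta
}

#' Group beta time course across participants
#'
#' Runs [epoch_betas()] per participant and stacks the results.
#'
#' @param series_list List of [roi_series()], one per participant.
#' @param events Event table covering all participants (matched on the
#'   `participant` column).
#' @param config A [timecourse_config()].
#' @return Object of class `beta_timecourse`: `times`, `beta` array
#'   `[time, regressor, participant]`, `n_events`.
#' @export
group_timecourse <- function(series_list, events, config = timecourse_config()) {
  per <- lapply(series_list, function(s)
    tryCatch(
      epoch_betas(s, events[events$participant == s$participant, ,
                            drop = FALSE], config),
      error = function(e) {
        warning("participant ", s$participant, " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      }))
  ok <- !vapply(per, is.null, logical(1))
  if (sum(ok) < 3L)
    stop("fewer than 3 participants with estimable time courses",
         call. = FALSE)
  per <- per[ok]
  series_list <- series_list[ok]
  times <- attr(per[[1]], "times")
  beta <- array(unlist(per), dim = c(length(times), ncol(per[[1]]), length(per)),
                dimnames = list(NULL, colnames(per[[1]]),
                                vapply(series_list, `[[`, "", "participant")))
  structure(list(times = times, beta = beta,
                 n_events = vapply(per, attr, 0L, "n_events")),
            class = "beta_timecourse")
}

# signed extremum of a course: index of max |value|, sign of that value
signed_peak_index <- function(course) {
  i <- which.max(abs(course))
  list(index = i, sign = if (course[i] == 0) 1 else sign(course[i]),
       flat = all(course == course[1]))
}

#' Leave-one-subject-out peak time
#'
#' For each left-out participant, the peak time is the signed extremum (the
#' time of the largest absolute value, carrying its sign) of the remaining
#' participants' mean beta course within the search window; the final peak
#' time is the mean of the leave-one-out peak times (one iteration per
#' participant). Flat courses tie-break to the earliest time and are
#' flagged.
#'
#' @param tc A `beta_timecourse` (>= 3 participants).
#' @param regressor Regressor name.
#' @param search_window Seconds relative to onset (default `c(-5, 13)`).
#' @return List with `peak_time`, `loso_times`, `sign`, `flat`.
#' @export
loso_peak <- function(tc, regressor, search_window = c(-5, 13)) {
  n <- dim(tc$beta)[3]
  stopifnot(n >= 3L)
  inw <- tc$times >= search_window[1] & tc$times <= search_window[2]
  B <- tc$beta[inw, regressor, , drop = FALSE]
  tt <- tc$times[inw]
  loso <- signs <- numeric(n)
  flat <- FALSE
  for (i in seq_len(n)) {
    m <- rowMeans(B[, 1, -i, drop = FALSE])
    pk <- signed_peak_index(m)
    if (pk$flat) flat <- TRUE
    loso[i] <- tt[pk$index]
    signs[i] <- pk$sign
  }
  sgn <- sign(sum(signs))
  list(peak_time = mean(loso), loso_times = loso,
       sign = if (sgn == 0) 1 else sgn, flat = flat)
}

# FWHM window around the signed peak of the group mean course
fwhm_window <- function(times, course, peak_time, sgn) {
  g <- course * sgn
  ip <- which.min(abs(times - peak_time))
  # walk to the nearest local max of g around the nominal peak time
  pv <- g[ip]
  half <- pv / 2
  clipped <- c(FALSE, FALSE)
  lo <- times[1]
  if (ip > 1) {
    for (i in ip:2) {
      if (g[i - 1] < half) {
        lo <- times[i - 1] + (times[i] - times[i - 1]) *
          (half - g[i - 1]) / (g[i] - g[i - 1])
        break
      }
      if (i == 2) clipped[1] <- TRUE
    }
  } else clipped[1] <- TRUE
  nt <- length(times)
  hi <- times[nt]
  if (ip < nt) {
    for (i in ip:(nt - 1)) {
      if (g[i + 1] < half) {
        hi <- times[i] + (times[i + 1] - times[i]) *
          (half - g[i]) / (g[i + 1] - g[i])
        break
      }
      if (i == nt - 1) clipped[2] <- TRUE
    }
  } else clipped[2] <- TRUE
  list(window = c(lo, hi), clipped = clipped)
}

#' Peak size estimate with FWHM window, t test and Bayes factor
#'
#' The peak window is the full width at half maximum of the (signed) peak in
#' the group mean time course: the period between the two crossings of half
#' the peak value (linearly interpolated; clipped to the search window edge
#' and flagged if a crossing is absent). The per-participant peak size is
#' the mean beta within that window; a one-sample t test against zero is
#' supplemented by a JZS Bayesian t test.
#'
#' @param tc A `beta_timecourse`.
#' @param regressor Regressor name.
#' @param peak_time Peak time in seconds; defaults to [loso_peak()].
#' @param search_window Seconds (default `c(-5, 13)`).
#' @return Object of class `peak_estimate`: `peak_time`, `fwhm_window`,
#'   `sizes`, `mean_size`, `t`, `df`, `p`, `bf10`, `sign`, `clipped`,
#'   `degenerate`.
#' @export
peak_sizes <- function(tc, regressor, peak_time = NULL,
                       search_window = c(-5, 13)) {
  lp <- loso_peak(tc, regressor, search_window)
  if (is.null(peak_time)) peak_time <- lp$peak_time
  inw <- tc$times >= search_window[1] & tc$times <= search_window[2]
  tt <- tc$times[inw]
  gmean <- rowMeans(tc$beta[inw, regressor, , drop = FALSE], dims = 1)
  fw <- fwhm_window(tt, gmean, peak_time, lp$sign)
  sel <- tc$times >= fw$window[1] & tc$times <= fw$window[2]
  if (!any(sel)) sel[which.min(abs(tc$times - peak_time))] <- TRUE
  sizes <- apply(tc$beta[sel, regressor, , drop = FALSE], 3, mean)
  n <- length(sizes)
  s <- stats::sd(sizes)
  degenerate <- !is.finite(s) || s == 0
  tstat <- if (degenerate) NA_real_ else mean(sizes) / (s / sqrt(n))
  p <- if (degenerate) NA_real_ else 2 * stats::pt(-abs(tstat), n - 1)
  bf <- if (degenerate) NA_real_ else jzs_bayes_factor(tstat, n)
  structure(list(peak_time = peak_time, fwhm_window = fw$window,
                 sizes = sizes, mean_size = mean(sizes), t = tstat,
                 df = n - 1, p = p, bf10 = bf, sign = lp$sign,
                 clipped = fw$clipped, degenerate = degenerate),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("Peak %.2f s, FWHM [%.2f, %.2f] s: mean size %.4f, t(%d) = %.3f, p = %.4g, BF10 = %.3g\n",
              x$peak_time, x$fwhm_window[1], x$fwhm_window[2], x$mean_size,
              x$df, x$t, x$p, x$bf10))
  invisible(x)
}

#' Benjamini-Hochberg FDR-adjusted p values
#'
#' Standard step-up adjustment (monotone, capped at 1).
#'
#' @param p_values Vector of p values in (0, 1].
#' @param q Nominal FDR level, recorded for reporting (default 0.05); the
#'   adjusted values themselves do not depend on it.
#' @return Adjusted p values in the input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values > 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Drop the first of repeated internal explorations of the same option
#'
#' Marks, within each participant and trial, the first internal-exploration
#' event targeting each option; repeat internal explorations of the same
#' option are kept. Used to sharpen analyses of signals that ramp over
#' repeated sampling of one option.
#'
#' @param events Event table with `participant`, `trial`, `target`,
#'   `choice`.
#' @return Logical vector: `TRUE` for events to keep.
#' @export
keep_repeat_internal <- function(events) {
  keep <- rep(TRUE, nrow(events))
  is_int <- events$choice == "internal"
  key <- paste(events$participant, events$trial, events$target)
  keep[is_int] <- duplicated(key[is_int])
  keep
}

#' Decision-conditioned beta time courses
#'
#' Splits the events by the impending decision (the action executed on that
#' phase), runs the three value regressors simultaneously within each
#' subset, and extracts one peak estimate per value signal and subset. The
#' three decision-wise tests of each signal are jointly FDR-adjusted. An
#' optional filter leaves out the first of repeated internal explorations of
#' the same option (applied to the internal-decision subset).
#'
#' @param series_list List of [roi_series()] (one ROI, all participants).
#' @param events Event table.
#' @param config A [timecourse_config()]; its regressors are replaced by the
#'   three values.
#' @param drop_first_internal Apply the repeat-internal filter to the
#'   internal-decision subset (default FALSE).
#' @param search_window Peak search window (default `c(-5, 13)`).
#' @return List: `peaks[[signal]][[decision]]` peak estimates, and `fdr`, a
#'   data frame with `signal`, `decision`, `mean_size`, `t`, `p`,
#'   `fdr_adjusted_p`.
#' @export
decision_conditioned_betas <- function(series_list, events,
                                       config = timecourse_config(),
                                       drop_first_internal = FALSE,
                                       search_window = c(-5, 13)) {
  config$regressors <- c("v_internal", "v_external", "v_accept")
  decisions <- c("internal", "external", "accept")
  signals <- c("v_internal", "v_external", "v_accept")
  peaks <- stats::setNames(vector("list", 3), signals)
  rowsout <- list()
  for (d in decisions) {
    sub <- events[events$choice == d, , drop = FALSE]
    if (d == "internal" && drop_first_internal)
      sub <- sub[keep_repeat_internal(sub), , drop = FALSE]
    tc <- group_timecourse(series_list, sub, config)
    for (sg in signals) {
      pe <- peak_sizes(tc, sg, search_window = search_window)
      peaks[[sg]][[d]] <- pe
      rowsout[[length(rowsout) + 1L]] <-
        data.frame(signal = sg, decision = d, mean_size = pe$mean_size,
                   t = pe$t, p = pe$p)
    }
  }
  fdr <- do.call(rbind, rowsout)
  fdr$fdr_adjusted_p <- NA_real_
  for (sg in signals) {
    i <- fdr$signal == sg
    fdr$fdr_adjusted_p[i] <- bh_fdr(fdr$p[i])
  }
  list(peaks = peaks, fdr = fdr)
}

#' Chosen- and unchosen-value beta time courses
#'
#' Re-codes each event's three decision values (z-scored within
#' participant) into the *chosen* value — the value matching the impending
#' decision — and the *unchosen* value — the best of the two alternatives —
#' then runs both regressors simultaneously within each decision subset and
#' extracts peak estimates.
#'
#' @inheritParams decision_conditioned_betas
#' @return List: `peaks[[regressor]][[decision]]` and a summary data frame
#'   `table`.
#' @export
chosen_unchosen_betas <- function(series_list, events,
                                  config = timecourse_config(),
                                  search_window = c(-5, 13)) {
  ev <- standardize_predictors(events)
  V <- as.matrix(ev[, c("v_internal", "v_external", "v_accept")])
  ci <- match(ev$choice, c("internal", "external", "accept"))
  ev$v_chosen <- V[cbind(seq_len(nrow(V)), ci)]
  ev$v_unchosen <- vapply(seq_len(nrow(V)), function(i) max(V[i, -ci[i]]),
                          numeric(1))
  config$regressors <- c("v_chosen", "v_unchosen")
  decisions <- c("internal", "external", "accept")
  peaks <- list(v_chosen = list(), v_unchosen = list())
  rowsout <- list()
  for (d in decisions) {
    sub <- ev[ev$choice == d, , drop = FALSE]
    tc <- group_timecourse(series_list, sub, config)
    for (rg in c("v_chosen", "v_unchosen")) {
      pe <- peak_sizes(tc, rg, search_window = search_window)
      peaks[[rg]][[d]] <- pe
      rowsout[[length(rowsout) + 1L]] <-
        data.frame(regressor = rg, decision = d, mean_size = pe$mean_size,
                   t = pe$t, p = pe$p)
    }
  }
  list(peaks = peaks, table = do.call(rbind, rowsout))
}

#' Brain-behaviour correlation
#'
#' Pearson correlation between per-participant peak sizes and behavioural
#' decision proportions.
#'
#' @param sizes Numeric vector of per-participant peak sizes.
#' @param proportions Numeric vector of per-participant decision
#'   proportions.
#' @return List with `r`, `p`, `n`, `degenerate`.
#' @export
brain_behavior_correlation <- function(sizes, proportions) {
  stopifnot(length(sizes) == length(proportions), length(sizes) >= 3L)
  if (stats::sd(sizes) == 0 || stats::sd(proportions) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(sizes),
                degenerate = TRUE))
  ct <- stats::cor.test(sizes, proportions)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(sizes),
       degenerate = FALSE)
}

#' Three-way fixed-effects ANOVA on peak sizes
#'
#' Region (3) by Decision (3) by Signal (3) ANOVA over the 27 cells measured
#' in every participant; the three-way interaction has 8 numerator df and
#' 27(n - 1) error df (621 at n = 24).
#'
#' @param peak_table Data frame with columns `region`, `decision`, `signal`
#'   (each 3 levels), `participant`, `size`; the 3x3x3 design must be
#'   complete.
#' @return List with `F`, `df1`, `df2`, `p`, and the full `aov` table.
#' @export
threeway_anova <- function(peak_table) {
  req <- c("region", "decision", "signal", "participant", "size")
  stopifnot(all(req %in% names(peak_table)))
  for (f in c("region", "decision", "signal"))
    peak_table[[f]] <- factor(peak_table[[f]])
  cells <- table(peak_table$region, peak_table$decision, peak_table$signal)
  if (any(cells == 0)) stop("incomplete 3x3x3 design", call. = FALSE)
  fit <- stats::aov(size ~ region * decision * signal, data = peak_table)
  tab <- summary(fit)[[1]]
  i <- grep("region:decision:signal", rownames(tab))
  list(F = tab$`F value`[i], df1 = tab$Df[i],
       df2 = tab$Df[nrow(tab)], p = tab$`Pr(>F)`[i], table = tab)
}

#' JZS Bayes factor for a one-sample t test
#'
#' Jeffreys-Zellner-Siow Bayes factor (alternative over null) with a Cauchy
#' prior of scale `rscale` on the standardized effect, by numerical
#' integration.
#'
#' @param t Observed t statistic.
#' @param n Sample size (>= 2).
#' @param rscale Cauchy prior scale (default 0.707).
#' @return BF10.
#' @export
jzs_bayes_factor <- function(t, n, rscale = sqrt(2) / 2) {
  stopifnot(n >= 2)
  nu <- n - 1
  marg <- function(g) {
    a <- 1 + n * g * rscale^2
    a^(-0.5) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }
  num <- stats::integrate(marg, 0, Inf, rel.tol = 1e-8)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}
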