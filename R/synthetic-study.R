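#' Session timing configuration
#'
#' Inter-event intervals are uniform; reaction times are truncated normal
#' (at `rt_min`) with decision-type-specific moments. Defaults: ISI 1-3 s
#' after each exploration, an outcome phase of 1-3 s plus an ITI of 3-6 s
#' after each accept, and RT moments of 3.76/1.56 s (internal), 2.75/1.19 s
#' (external) and 3.06/1.50 s (accept).
#'
#' @param isi,iti,outcome Uniform ranges in seconds.
#' @param rt Named list of `c(mean, sd)` per decision type, seconds.
#' @param rt_min Truncation floor for RTs in seconds (default 0.3).
#' @return Object of class `timing_config`.
#' @export
timing_config <- function(isi = c(1, 3), iti = c(3, 6), outcome = c(1, 3),
                          rt = list(internal = c(3.76, 1.56),
                                    external = c(2.75, 1.19),
                                    accept = c(3.06, 1.50)),
                          rt_min = 0.3) {
  stopifnot(all(c(isi, iti, outcome) >= 0), rt_min > 0)
  structure(list(isi = isi, iti = iti, outcome = outcome, rt = rt,
                 rt_min = rt_min), class = "timing_config")
}

sample_rt <- function(timing, kind) {
  m <- timing$rt[[kind]]
  repeat {
    rt <- stats::rnorm(1, m[1], m[2])
    if (rt >= timing$rt_min) return(rt)
  }
}

#' Canonical two-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peaking near `peak` seconds,
#' undershoot near `undershoot` seconds with relative amplitude `1/ratio`),
#' normalized to a peak of 1. The kernel is 0 at t = 0.
#'
#' @param dt Sampling step in seconds.
#' @param peak Gamma shape of the response component (default 6).
#' @param undershoot Gamma shape of the undershoot component (default 16).
#' @param ratio Response/undershoot amplitude ratio (default 6).
#' @param length Kernel duration in seconds (default 32).
#' @return Numeric kernel sampled at `dt` with attribute `times`.
#' @export
two_gamma_hrf <- function(dt, peak = 6, undershoot = 16, ratio = 6,
                          length = 32) {
  stopifnot(dt > 0)
  if (peak <= 1 || undershoot <= 1 || ratio <= 0)
    stop("invalid HRF shape parameters", call. = FALSE)
  t <- seq(0, length, by = dt)
  k <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  k <- k / max(k)
  attr(k, "times") <- t
  k
}

#' Encoding rule mapping decision events to neural amplitudes
#'
#' Three planted regional codes: `invariant_internal` responds
#' `gain * z(v_internal)` on every event regardless of the impending
#' decision; `invariant_external` responds `gain * z(v_external)`;
#' `flexible_chosen` responds `gain * z(chosen value) - suppression *
#' z(best alternative)`, i.e. a general decision-value code that tracks
#' whichever value matches the impending decision. The per-participant gain
#' is `gain * (1 + behavior_coupling * z(proportion of the corresponding
#' decision)) + Normal(0, gain_sd)`, which plants a between-participant
#' association between signal strength and behaviour.
#'
#' @param rule One of `"invariant_internal"`, `"invariant_external"`,
#'   `"flexible_chosen"`.
#' @param gain Mean amplitude per z-unit of value.
#' @param suppression Amplitude of the unchosen-value term
#'   (`flexible_chosen` only).
#' @param gain_sd Between-participant gain SD.
#' @param behavior_coupling Slope linking gain to the z-scored proportion of
#'   the rule's corresponding decision type (default 0.4).
#' @param noise_sd White-noise SD of the BOLD series.
#' @param ar1 AR(1) coefficient of the noise (default 0.3).
#' @return Object of class `encoding_spec`.
#' @export
encoding_spec <- function(rule = c("invariant_internal", "invariant_external",
                                   "flexible_chosen"),
                          gain = 1, suppression = 0.5, gain_sd = 1,
                          behavior_coupling = 0.4, noise_sd = 4,
                          ar1 = 0.3) {
  rule <- match.arg(rule)
  stopifnot(is.finite(gain), is.finite(suppression), abs(ar1) < 1)
  structure(list(rule = rule, gain = gain, suppression = suppression,
                 gain_sd = gain_sd, behavior_coupling = behavior_coupling,
                 noise_sd = noise_sd, ar1 = ar1), class = "encoding_spec")
}

# per-event neural amplitudes for one participant under an encoding rule
encoding_amplitudes <- function(events, encoding, gain) {
  ev <- standardize_predictors(events)
  V <- as.matrix(ev[, c("v_internal", "v_external", "v_accept")])
  switch(encoding$rule,
    invariant_internal = gain * V[, 1],
    invariant_external = gain * V[, 2],
    flexible_chosen = {
      ci <- match(ev$choice, c("internal", "external", "accept"))
      chosen <- V[cbind(seq_len(nrow(V)), ci)]
      unchosen <- vapply(seq_len(nrow(V)), function(i) max(V[i, -ci[i]]),
                         numeric(1))
      gain * chosen - encoding$suppression * unchosen
    })
}

#' Simulate one participant's task session with onsets
#'
#' Thin wrapper over [simulate_choices()] with a [timing_config()], so the
#' event table carries decision-phase onsets and reaction times suitable for
#' BOLD synthesis.
#'
#' @param beta Generating 10-vector.
#' @param config A [task_config()].
#' @param timing A [timing_config()].
#' @param participant Participant label.
#' @return Event table with `onset_s` and `rt_s`.
#' @export
generate_participant <- function(beta, config = task_config(),
                                 timing = timing_config(),
                                 participant = "p1") {
  simulate_choices(beta, config, n_trials = config$n_trials,
                   timing = timing, participant = participant)
}

#' Synthesize an ROI BOLD series from an event table
#'
#' Places an impulse of the encoding amplitude at each decision-phase onset
#' on a fine grid, convolves with the two-gamma HRF, samples at `tr`, and
#' adds AR(1) + white noise (innovations scaled so the marginal noise SD is
#' `encoding$noise_sd`).
#'
#' @param events Event table with `onset_s` (one participant).
#' @param encoding An [encoding_spec()].
#' @param tr Repetition time in seconds (default 2).
#' @param gain Realized participant gain (default `encoding$gain`).
#' @param fine_dt Convolution grid step in seconds (default 0.1).
#' @param pad Seconds of series kept after the last onset (default 32).
#' @param roi_id Label for the series.
#' @return An [roi_series()].
#' @export
generate_bold <- function(events, encoding, tr = 2, gain = encoding$gain,
                          fine_dt = 0.1, pad = 32, roi_id = "roi") {
  stopifnot(nrow(events) > 0)
  amp <- encoding_amplitudes(events, encoding, gain)
  t_end <- max(events$onset_s) + pad
  n_fine <- ceiling(t_end / fine_dt) + 1L
  train <- numeric(n_fine)
  idx <- pmin(n_fine, floor(events$onset_s / fine_dt) + 1L)
  for (i in seq_along(idx)) train[idx[i]] <- train[idx[i]] + amp[i]
  hrf <- two_gamma_hrf(fine_dt)
  neural <- stats::convolve(train, rev(hrf), type = "open")[seq_len(n_fine)]
  samp_t <- seq(0, t_end, by = tr)
  sig <- neural[floor(samp_t / fine_dt) + 1L]
  if (encoding$noise_sd > 0) {
    innov <- stats::rnorm(length(sig), 0,
                          encoding$noise_sd * sqrt(1 - encoding$ar1^2))
    sig <- sig + as.numeric(stats::filter(innov, encoding$ar1,
                                          method = "recursive"))
  }
  roi_series(sig, tr = tr, start_time = 0, roi_id = roi_id,
             participant = events$participant[1])
}

#' Generate a complete synthetic study
#'
#' Draws per-participant generating betas from the population distribution
#' (Normal around `group_betas` with dispersion `0.5 |beta| + 0.2`),
#' simulates each participant's 100-trial session with onsets, and
#' synthesizes three ROI series with planted codes: IPS =
#' `invariant_internal`, ACC = `invariant_external`, mPFC =
#' `flexible_chosen`. The manifest records every configuration and the
#' master seed, so regenerating from the manifest reproduces the bundle
#' bit-for-bit.
#'
#' @param n Number of participants (default 24).
#' @param master_seed Integer seed controlling the whole bundle.
#' @param config,timing Task and timing configurations.
#' @param encodings Named list of [encoding_spec()]s, one per ROI.
#' @param group_betas Centre of the generating-beta distribution.
#' @param tr Repetition time in seconds.
#' @return Object of class `study_bundle`: `events` (combined table),
#'   `betas` (n x 10), `gains` (n x ROI), `roi` (list of per-ROI lists of
#'   [roi_series()]), `manifest`.
#' @export
generate_study <- function(n = 24L, master_seed = 1L,
                           config = task_config(),
                           timing = timing_config(),
                           encodings = list(
                             IPS = encoding_spec("invariant_internal"),
                             ACC = encoding_spec("invariant_external"),
                             mPFC = encoding_spec("flexible_chosen")),
                           group_betas = default_group_betas(),
                           tr = 2) {
  stopifnot(n >= 2L)
  set.seed(master_seed)
  if (n < 3L) warning("group tests underpowered at n < 3", call. = FALSE)
  disp <- 0.5 * abs(group_betas) + 0.2
  betas <- t(vapply(seq_len(n), function(i) stats::rnorm(10, group_betas, disp),
                    numeric(10)))
  colnames(betas) <- beta_names()
  pids <- sprintf("sub%02d", seq_len(n))
  ev_list <- lapply(seq_len(n), function(i)
    generate_participant(betas[i, ], config, timing, participant = pids[i]))
  # decision proportions drive the planted between-participant gain scaling
  props <- t(vapply(ev_list, function(ev)
    vapply(c("internal", "external", "accept"),
           function(k) mean(ev$choice == k), numeric(1)), numeric(3)))
  zprop <- apply(props, 2, function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  })
  roi <- list()
  gains <- matrix(NA_real_, n, length(encodings),
                  dimnames = list(pids, names(encodings)))
  for (r in names(encodings)) {
    enc <- encodings[[r]]
    zp <- switch(enc$rule,
                 invariant_internal = zprop[, 1],
                 invariant_external = zprop[, 2],
                 flexible_chosen = zprop[, 3])
    gains[, r] <- enc$gain * (1 + enc$behavior_coupling * zp) +
      stats::rnorm(n, 0, enc$gain_sd)
    roi[[r]] <- lapply(seq_len(n), function(i)
      generate_bold(ev_list[[i]], enc, tr = tr, gain = gains[i, r],
                    roi_id = r))
  }
  manifest <- list(n = n, master_seed = master_seed,
                   task_config = unclass(config),
                   timing_config = unclass(timing),
                   encodings = lapply(encodings, unclass),
                   group_betas = as.list(group_betas), tr = tr)
  structure(list(events = do.call(rbind, ev_list), betas = betas,
                 gains = gains, proportions = props, roi = roi,
                 manifest = manifest),
            class = "study_bundle")
}
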