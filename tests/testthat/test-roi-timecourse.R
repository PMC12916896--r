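# build a series whose response to each event is a known bump, so the
# event-locked GLM has an analytic expected beta course
bump_series <- function(z, onsets, gain = 2, lag = 6, width = 1.5, tr = 0.5,
                        t_end = max(onsets) + 30) {
  tt <- seq(0, t_end, by = tr)
  sig <- rep(0, length(tt))
  for (i in seq_along(onsets))
    sig <- sig + gain * z[i] * exp(-((tt - onsets[i] - lag)^2) / (2 * width^2))
  roi_series(sig, tr = tr, participant = "p1")
}

planted_events <- function(n = 40, seed = 30, spacing = 30) {
  set.seed(seed)
  data.frame(participant = "p1", trial = seq_len(n), phase = 1,
             choice = sample(c("internal", "external", "accept"), n, TRUE),
             target = 1L,
             v_internal = rnorm(n), v_external = rnorm(n),
             v_accept = rnorm(n), cost = rnorm(n),
             onset_s = 10 + spacing * (seq_len(n) - 1), rt_s = 3)
}

test_that("a constant series yields zero value betas everywhere", {
  ev <- planted_events(20)
  ser <- roi_series(rep(3.5, 400), tr = 2, participant = "p1")
  b <- epoch_betas(ser, ev, timecourse_config(grid_dt = 0.5))
  expect_true(all(abs(b[, -1]) < 1e-10))
  expect_true(all(abs(b[, 1] - 3.5) < 1e-10))
})

test_that("a planted linear effect is recovered at its lag and gain", {
  ev <- planted_events(40)
  z <- (ev$v_internal - mean(ev$v_internal)) /
    sqrt(mean((ev$v_internal - mean(ev$v_internal))^2))
  ser <- bump_series(z, ev$onset_s, gain = 2, lag = 6)
  b <- epoch_betas(ser, ev, timecourse_config(grid_dt = 0.1))
  times <- attr(b, "times")
  i_peak <- which.max(b[, "v_internal"])
  expect_equal(times[i_peak], 6, tolerance = 0.15)
  expect_equal(max(b[, "v_internal"]), 2, tolerance = 0.05)
  # other regressors stay near zero (independent draws)
  expect_lt(max(abs(b[, "v_accept"])), 0.5)
})

test_that("duplicating every event leaves the betas unchanged", {
  ev <- planted_events(25)
  ser <- bump_series(rnorm(25), ev$onset_s)
  cfg <- timecourse_config(grid_dt = 0.5)
  b1 <- epoch_betas(ser, ev, cfg)
  b2 <- epoch_betas(ser, rbind(ev, ev), cfg)
  expect_equal(unclass(b1)[, ], unclass(b2)[, ], tolerance = 1e-8)
})

test_that("edge events are dropped with a warning; rank errors are raised", {
  ev <- planted_events(10)
  ev$onset_s[1] <- 2  # epoch would start before the series
  ser <- bump_series(rnorm(10), ev$onset_s)
  expect_warning(b <- epoch_betas(ser, ev, timecourse_config(grid_dt = 0.5)),
                 "dropped")
  expect_equal(attr(b, "n_events"), 9L)
  expect_error(epoch_betas(ser, ev[1:4, ], timecourse_config(grid_dt = 0.5)),
               "fewer events")
})

make_tc <- function(courses, times) {
  # courses: list of per-participant vectors for one regressor "x"
  beta <- array(unlist(courses),
                dim = c(length(times), 1, length(courses)),
                dimnames = list(NULL, "x", NULL))
  structure(list(times = times, beta = beta,
                 n_events = rep(50L, length(courses))),
            class = "beta_timecourse")
}

test_that("LOSO peak time equals the max for identical unimodal courses", {
  times <- seq(-5, 13, by = 0.01)
  course <- exp(-((times - 6.42)^2) / 2)
  tc <- make_tc(replicate(5, course, simplify = FALSE), times)
  lp <- loso_peak(tc, "x")
  expect_equal(lp$peak_time, 6.42, tolerance = 1e-9)
  expect_equal(lp$sign, 1)

  # an outlier participant pulls the mean between the two modes
  shifted <- exp(-((times - 10)^2) / 2)
  tc2 <- make_tc(c(replicate(4, course, simplify = FALSE), list(5 * shifted)),
                 times)
  lp2 <- loso_peak(tc2, "x")
  expect_gt(lp2$peak_time, 6.42)
  expect_lt(lp2$peak_time, 10)

  # search window excluding the true max returns the in-window max
  lp3 <- loso_peak(tc, "x", search_window = c(-5, 3))
  expect_lte(lp3$peak_time, 3)
})

test_that("negative deflections are found as signed peaks", {
  times <- seq(-5, 13, by = 0.01)
  course <- -exp(-((times - 4)^2) / 2)
  tc <- make_tc(replicate(4, course, simplify = FALSE), times)
  lp <- loso_peak(tc, "x")
  expect_equal(lp$peak_time, 4, tolerance = 1e-9)
  expect_equal(lp$sign, -1)
})

test_that("FWHM of a triangular peak is the half-maximum interval", {
  times <- seq(-5, 13, by = 0.01)
  tri <- pmax(0, 1 - abs(times - 6) / 2)  # peak 1 at 6 s, support [4, 8]
  tc <- make_tc(list(tri, tri, tri), times)
  pe <- peak_sizes(tc, "x")
  expect_equal(pe$peak_time, 6, tolerance = 1e-9)
  expect_equal(pe$fwhm_window, c(5, 7), tolerance = 0.02)
  # identical participants -> zero variance flagged
  expect_true(pe$degenerate)
  expect_true(is.na(pe$t))
  # mean size: mean of the triangle over [5, 7] = 0.75
  expect_equal(pe$mean_size, 0.75, tolerance = 0.01)
})

test_that("BH adjustment equals a brute-force step-up oracle", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- Inf
    for (i in m:1) {
      prev <- min(prev, m * p[o[i]] / i)
      adj[o[i]] <- min(1, prev)
    }
    adj
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.20)), c(0.03, 0.03, 0.20))
  expect_equal(bh_fdr(rep(0.07, 4)), rep(0.07, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(31)
  for (i in 1:100) {
    p <- runif(sample(1:5, 1))
    expect_equal(bh_fdr(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("repeat-internal filter drops only first internal visits", {
  ev <- data.frame(participant = "a", trial = c(1, 1, 1, 1, 2),
                   target = c(3, 3, 3, 5, 3),
                   choice = c("internal", "internal", "internal", "internal",
                              "internal"))
  keep <- keep_repeat_internal(ev)
  expect_equal(keep, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # non-internal events always kept
  ev2 <- data.frame(participant = "a", trial = 1, target = NA,
                    choice = c("external", "accept"))
  expect_true(all(keep_repeat_internal(ev2)))
})

test_that("chosen/unchosen coding picks the impending and best other value", {
  ev <- data.frame(participant = "a",
                   v_internal = c(1.2, 0.5), v_external = c(0.3, 0.9),
                   v_accept = c(0.8, 0.7), cost = c(0, 0),
                   choice = c("internal", "accept"))
  # reproduce the internal coding path on already-standardized values
  V <- as.matrix(ev[, c("v_internal", "v_external", "v_accept")])
  ci <- match(ev$choice, c("internal", "external", "accept"))
  chosen <- V[cbind(1:2, ci)]
  unchosen <- vapply(1:2, function(i) max(V[i, -ci[i]]), numeric(1))
  expect_equal(chosen, c(1.2, 0.7))
  expect_equal(unchosen, c(0.8, 0.9))
})

test_that("brain-behaviour correlation is exact on linear data, flags ties", {
  sizes <- c(0.1, 0.4, 0.2, 0.9, 0.5)
  bb <- brain_behavior_correlation(sizes, 2 * sizes + 3)
  expect_equal(bb$r, 1, tolerance = 1e-12)
  expect_true(brain_behavior_correlation(sizes, rep(0.3, 5))$degenerate)
})

test_that("three-way ANOVA df match the complete-design arithmetic", {
  set.seed(32)
  grid <- expand.grid(region = c("IPS", "ACC", "mPFC"),
                      decision = c("internal", "external", "accept"),
                      signal = c("internal", "external", "accept"),
                      participant = sprintf("s%02d", 1:24))
  grid$size <- rnorm(nrow(grid))
  res <- threeway_anova(grid)
  expect_equal(res$df1, 8)
  expect_equal(res$df2, 621)
  # equal cell means (participant-only variation) -> interaction F of 0
  grid0 <- grid
  grid0$size <- rnorm(24)[as.integer(factor(grid0$participant))]
  res0 <- threeway_anova(grid0)
  expect_lt(res0$F, 1e-10)
  # a missing cell is a design error
  miss <- grid[!(grid$region == "IPS" & grid$decision == "internal" &
                   grid$signal == "internal"), ]
  expect_error(threeway_anova(miss), "incomplete")
})

test_that("2x2x2 interaction F matches a hand-computed oracle", {
  set.seed(33)
  r <- 6
  grid <- expand.grid(region = c("A", "B"), decision = c("x", "y"),
                      signal = c("u", "v"), participant = seq_len(r))
  grid$size <- rnorm(nrow(grid))
  res <- threeway_anova(grid)
  # balanced 2x2x2: SS_ABC = r * L^2 / 8 with the +/- product contrast
  cm <- aggregate(size ~ region + decision + signal, grid, mean)
  sgn <- with(cm, ifelse(region == "A", 1, -1) * ifelse(decision == "x", 1, -1) *
                ifelse(signal == "u", 1, -1))
  L <- sum(sgn * cm$size)
  ss_abc <- r * L^2 / 8
  fitted <- merge(grid, cm, by = c("region", "decision", "signal"))
  ss_err <- sum((fitted$size.x - fitted$size.y)^2)
  f_oracle <- ss_abc / (ss_err / (8 * (r - 1)))
  expect_equal(res$F, f_oracle, tolerance = 1e-8)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 8 * (r - 1))
})

test_that("JZS Bayes factor behaves across the t range", {
  expect_lt(jzs_bayes_factor(0, 24), 1)
  expect_gt(jzs_bayes_factor(5, 24), 100)
  bf <- vapply(c(0, 1, 2, 3, 4), function(t) jzs_bayes_factor(t, 24),
               numeric(1))
  expect_true(all(diff(bf) > 0))
  # symmetric in the sign of t
  expect_equal(jzs_bayes_factor(2.3, 24), jzs_bayes_factor(-2.3, 24),
               tolerance = 1e-10)
})
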