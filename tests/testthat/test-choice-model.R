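test_that("choice probabilities follow the two-logit softmax", {
  row0 <- list(v_internal = 0.3, v_external = -1.1, v_accept = 0.7, cost = 0.2)
  expect_equal(unname(choice_probabilities(rep(0, 10), row0)), rep(1 / 3, 3))

  # a huge internal intercept saturates P(internal)
  b <- c(10, rep(0, 9))
  p <- choice_probabilities(b, row0)
  sm <- exp(c(10, 0, 0)) / sum(exp(c(10, 0, 0)))
  expect_equal(unname(p), sm, tolerance = 1e-12)

  # log-odds of ln 2 on both branches -> 2:2:1
  b2 <- rep(0, 10); b2[1] <- log(2); b2[6] <- log(2)
  expect_equal(unname(choice_probabilities(b2, row0)), c(0.4, 0.4, 0.2),
               tolerance = 1e-12)

  # numerically stable at |eta| ~ 700
  b3 <- rep(0, 10); b3[1] <- 700
  p3 <- choice_probabilities(b3, row0)
  expect_true(all(is.finite(p3)))
  expect_equal(sum(p3), 1)
})

test_that("probabilities sum to one for random beta/row pairs", {
  set.seed(7)
  for (i in 1:200) {
    beta <- rnorm(10, 0, 3)
    row <- list(v_internal = rnorm(1), v_external = rnorm(1),
                v_accept = rnorm(1), cost = rnorm(1))
    expect_equal(sum(choice_probabilities(beta, row)), 1, tolerance = 1e-12)
  }
})

test_that("predictor standardization is population-SD z-scoring, idempotent", {
  ev <- data.frame(participant = "a", v_internal = c(1, 2, 3),
                   v_external = c(5, 5, 5), v_accept = c(0, 1, 2),
                   cost = c(0, 1, 2), choice = "accept")
  z <- standardize_predictors(ev)
  expect_equal(z$v_internal, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(z$v_external, c(0, 0, 0))
  expect_equal(standardize_predictors(z)$v_internal, z$v_internal,
               tolerance = 1e-12)
  # z-scoring is within participant
  ev2 <- rbind(ev, transform(ev, participant = "b", v_internal = c(10, 20, 30)))
  z2 <- standardize_predictors(ev2)
  expect_equal(z2$v_internal[4:6], z$v_internal, tolerance = 1e-10)
  expect_error(standardize_predictors(ev[0, ]), "empty")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(8)
  rows <- sim_rows(rnorm(10), n = 60)
  X <- cbind(1, rows$v_internal, rows$v_external, rows$v_accept, rows$cost)
  y_int <- as.numeric(rows$choice == "internal")
  y_ext <- as.numeric(rows$choice == "external")
  for (k in 1:5) {
    beta <- rnorm(10)
    g <- dialexplore:::choice_negloglik_grad(beta, X, y_int, y_ext, 0.01)
    num <- vapply(1:10, function(j) {
      h <- 1e-6; e <- rep(0, 10); e[j] <- h
      (dialexplore:::choice_negloglik(beta + e, X, y_int, y_ext, 0.01) -
       dialexplore:::choice_negloglik(beta - e, X, y_int, y_ext, 0.01)) / (2 * h)
    }, numeric(1))
    expect_equal(g, num, tolerance = 1e-5)
  }
})

test_that("MLE recovers a known beta from a large simulated row set", {
  truth <- c(0.5, 1.2, -0.4, -1.5, -0.3, 0.2, 0.3, 1.0, -1.8, -0.5)
  rows <- sim_rows(truth, n = 5000, seed = 9)
  set.seed(10)
  fit <- fit_mle(rows, restarts = 2)
  expect_true(fit$converged)
  expect_lte(fit$log_likelihood, 0)
  expect_true(all(abs(fit$beta - truth) < 0.1))
})

test_that("fitted likelihood beats the zero vector and handles separation", {
  set.seed(11)
  rows <- sim_rows(rnorm(10, 0, 2), n = 300)
  fit <- fit_mle(rows, restarts = 2)
  ll0 <- -dialexplore:::choice_negloglik(
    rep(0, 10), cbind(1, rows$v_internal, rows$v_external, rows$v_accept,
                      rows$cost),
    as.numeric(rows$choice == "internal"),
    as.numeric(rows$choice == "external"), 0)
  expect_gte(fit$log_likelihood, ll0)

  # all-accept data: ridge tames separation, intercepts go strongly negative
  rows2 <- sim_rows(rep(0, 10), n = 40, seed = 12)
  rows2$choice <- "accept"
  fit2 <- fit_mle(rows2, ridge = 1e-3, restarts = 1)
  expect_true(all(is.finite(fit2$beta)))
  expect_lt(fit2$beta[1], -1)
  expect_lt(fit2$beta[6], -1)
  expect_true(fit2$converged)
})

test_that("two-event toy fit matches a coarse grid-search oracle", {
  # both predictors zero, so only the two intercepts matter and the
  # 10-parameter optimum is exactly the intercept-grid optimum
  rows <- data.frame(participant = "t", v_internal = 0, v_external = 0,
                     v_accept = 0, cost = 0,
                     choice = c("internal", "accept"))
  set.seed(13)
  fit <- fit_mle(rows, ridge = 0.05, restarts = 2)
  grid <- seq(-3, 3, by = 0.02)
  ll <- function(b1, b6) {
    p <- exp(c(b1, b6, 0)); p <- p / sum(p)
    log(p[1]) + log(p[3]) - 0.05 * (b1^2 + b6^2)
  }
  best <- max(outer(grid, grid, Vectorize(ll)))
  pen <- fit$log_likelihood - 0.05 * sum(fit$beta^2)
  expect_gte(pen, best - 1e-8)        # optimizer at least as good as the grid
  expect_lte(abs(pen - best), 0.005)  # and within grid resolution
})

test_that("simulated choices are uniform under beta = 0 where all legal", {
  set.seed(14)
  ev <- do.call(rbind, lapply(1:4, function(i)
    simulate_choices(rep(0, 10), task_config(), n_trials = 60,
                     participant = paste0("p", i))))
  # restrict to phases where every action was certainly legal
  free <- ev$cost < 8  # external cap is the only binding constraint early
  tab <- table(ev$choice[free])
  n <- sum(tab)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  for (k in c("internal", "external", "accept"))
    expect_lt(abs(tab[[k]] / n - 1 / 3), 3 * se + 0.02)
})

test_that("simulation is deterministic given the seed and starves accept", {
  cfg <- task_config()
  set.seed(15); a <- simulate_choices(default_group_betas(), cfg, n_trials = 10)
  set.seed(15); b <- simulate_choices(default_group_betas(), cfg, n_trials = 10)
  expect_identical(a, b)

  # a -50 accept-intercept surrogate makes accept vanish until caps bind
  set.seed(16)
  bet <- rep(0, 10); bet[1] <- 25; bet[6] <- 25
  ev <- simulate_choices(bet, cfg, n_trials = 5)
  per_trial <- split(ev$choice, ev$trial)
  for (tr in per_trial) expect_true(all(tr[-length(tr)] != "accept"))
})

test_that("fixed-moment standardization matches its definition", {
  ev <- data.frame(participant = "a", v_internal = c(1, 3), v_external = c(2, 2),
                   v_accept = c(0, 4), cost = c(1, 2), choice = "accept")
  ns <- list(mu = c(2, 2, 2, 1), sd = c(1, 0, 2, 1))
  z <- standardize_with(ev, ns)
  expect_equal(z$v_internal, c(-1, 1))
  expect_equal(z$v_external, c(0, 0))  # zero-SD guard
  expect_equal(z$v_accept, c(-1, 1))
  expect_equal(z$cost, c(0, 1))
})

test_that("the ML estimator agrees with an independent multinomial fitter", {
  set.seed(17)
  ev <- simulate_choices(default_group_betas(), task_config(), n_trials = 40,
                         participant = "x")
  rows <- standardize_predictors(ev)
  fit <- fit_mle(rows, restarts = 1)
  rows$choice <- factor(rows$choice,
                        levels = c("accept", "internal", "external"))
  ref <- nnet::multinom(choice ~ v_internal + v_external + v_accept + cost,
                        rows, trace = FALSE, maxit = 500, reltol = 1e-12)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(c(t(stats::coef(ref)))),
               tolerance = 1e-3)
})
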