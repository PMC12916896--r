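test_that("BIC follows k ln n - 2 logL", {
  f <- list(log_likelihood = -100, n_events = 300)
  expect_equal(bic(f, k = 10), 10 * log(300) + 200)
  expect_equal(bic(list(log_likelihood = 0, n_events = 1), k = 0), 0)
  # linear in logL at fixed n, k
  f2 <- list(log_likelihood = -50, n_events = 300)
  expect_equal(bic(f, 10) - bic(f2, 10), 2 * 50)
})

test_that("prediction accuracy counts argmax matches with fixed tie order", {
  rows <- data.frame(participant = "a",
                     v_internal = rep(0, 9), v_external = rep(0, 9),
                     v_accept = rep(0, 9), cost = rep(0, 9),
                     choice = rep(c("internal", "external", "accept"), 3))
  fit0 <- list(beta = setNames(rep(0, 10), dialexplore:::beta_names()))
  # all ties -> first category (internal) predicted -> accuracy = 1/3
  expect_equal(prediction_accuracy(fit0, rows), 1 / 3)
  # strong internal intercept -> all predicted internal
  b <- rep(0, 10); b[1] <- 5
  expect_equal(prediction_accuracy(list(beta = b), rows), 1 / 3)
  # 7 of 10 correct
  rows2 <- data.frame(participant = "a", v_internal = 0, v_external = 0,
                      v_accept = 0, cost = 0,
                      choice = c(rep("internal", 7), rep("accept", 3)))
  expect_equal(prediction_accuracy(list(beta = b), rows2), 0.7)
})

test_that("BMS returns the symmetric answer under flat evidence", {
  set.seed(17)
  ev <- matrix(0, nrow = 12, ncol = 4)
  res <- bms_exceedance(ev, n_samples = 2e5)
  mc_se <- sqrt(0.25 * 0.75 / 2e5)
  expect_true(all(abs(res$exceedance_prob - 0.25) < 3 * mc_se + 0.002))
  expect_equal(sum(res$exceedance_prob), 1, tolerance = 1e-6)
  expect_equal(sum(res$expected_prob), 1, tolerance = 1e-10)
})

test_that("a uniformly dominant model takes essentially all exceedance mass", {
  set.seed(18)
  ev <- matrix(0, nrow = 24, ncol = 3)
  ev[, 2] <- 10
  res <- bms_exceedance(ev, n_samples = 2e5)
  expect_gt(res$exceedance_prob[2], 0.999)
})

test_that("BMS is invariant to per-participant evidence shifts", {
  set.seed(19)
  ev <- matrix(rnorm(24 * 3, sd = 2), 24, 3)
  shifts <- rnorm(24, 0, 50)
  set.seed(100)
  r1 <- bms_exceedance(ev, n_samples = 1e5)
  set.seed(100)
  r2 <- bms_exceedance(sweep(ev, 1, shifts, "+"), n_samples = 1e5)
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-8)
  expect_equal(r1$exceedance_prob, r2$exceedance_prob, tolerance = 1e-8)
})

test_that("single participant with no evidence gap gives alpha (1.5, 1.5)", {
  set.seed(20)
  res <- bms_exceedance(matrix(0, 1, 2), n_samples = 2e5)
  expect_equal(unname(res$alpha), c(1.5, 1.5), tolerance = 1e-6)
  expect_equal(unname(res$exceedance_prob), c(0.5, 0.5), tolerance = 0.01)
})

test_that("best-fit counts use argmin BIC with first-id ties", {
  lev <- matrix(0, 24, 3, dimnames = list(NULL, c("A", "B", "C")))
  lev[1:5, 1] <- 1    # A best for 5 participants
  lev[6:24, 3] <- 1   # C best for the rest
  bf <- best_fit_counts(lev)
  expect_equal(bf$count, c(5L, 0L, 19L))
  expect_equal(bf$percent[1], 100 * 5 / 24, tolerance = 1e-12)
  expect_equal(sum(bf$percent), 100)
  # exact tie row -> first model id
  tie <- matrix(0, 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(best_fit_counts(tie)$count, c(1L, 0L, 0L))
  # dominance -> 100%
  dom <- matrix(rep(c(5, 0, 0), each = 6), 6, 3)
  expect_equal(best_fit_counts(dom)$percent, c(100, 0, 0))
})

test_that("parameter recovery flags degenerate generating parameters", {
  set.seed(21)
  gb <- matrix(rep(default_group_betas(), each = 4), nrow = 4)
  rec <- parameter_recovery(gen_betas = gb, n_trials = 5, restarts = 1)
  expect_true(all(rec$degenerate))
  expect_true(all(is.na(rec$r)))
})

test_that("recovery r improves with session length and is affine-invariant", {
  set.seed(22)
  disp <- 0.5 * abs(default_group_betas()) + 0.2
  gb <- t(replicate(8, rnorm(10, default_group_betas(), disp)))
  set.seed(23)
  rec_short <- parameter_recovery(gen_betas = gb, n_trials = 25, restarts = 1)
  set.seed(23)
  rec_long <- parameter_recovery(gen_betas = gb, n_trials = 250, restarts = 1)
  expect_gt(mean(rec_long$r), mean(rec_short$r))
  # affine rescaling of a generating column leaves its r unchanged
  expect_equal(cor(2 * gb[, 2] + 3, rec_long$recovered[, 2]),
               unname(rec_long$r[2]), tolerance = 1e-12)
})

test_that("variant comparison favours the generating value functions", {
  set.seed(50)
  reg <- value_registry()
  small <- list(internal = reg$internal[c("best_point_sd", "max_sd")],
                external = reg$external["environment_mean"],
                accept = reg$accept["best_point"])
  fam <- enumerate_model_family(small, include_cost = TRUE)
  expect_equal(nrow(fam), 2L)
  ev <- do.call(rbind, lapply(1:4, function(i)
    simulate_choices(default_group_betas(), task_config(), n_trials = 50,
                     participant = paste0("p", i), registry = small)))
  expect_true("alt_internal_max_sd" %in% names(ev))
  # the best-fit columns duplicate the canonical values
  expect_equal(ev$alt_internal_best_point_sd, ev$v_internal)
  cmp <- compare_variants(ev, fam, restarts = 1)
  expect_equal(dim(cmp$bic), c(4L, 2L))
  # generating variant (m001) wins BIC for most participants
  bf <- best_fit_counts(cmp$log_evidence)
  expect_gte(bf$count[bf$model == "m001"], 3L)
  res <- bms_exceedance(cmp$log_evidence, n_samples = 1e5)
  expect_equal(sum(res$exceedance_prob), 1, tolerance = 1e-6)
  expect_gt(res$exceedance_prob["m001"], 0.5)
  # cost-free variants zero the cost column and use k = 8
  fam2 <- enumerate_model_family(small, include_cost = FALSE)
  rows <- variant_rows(ev, fam2[1, ])
  expect_true(all(rows$cost == 0))
  expect_error(variant_rows(ev[, 1:9], fam2[1, ]), "lacks variant column")
})
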