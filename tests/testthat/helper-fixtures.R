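# Small deterministic fixtures used across test files.

# a trial state with known dials (bypasses random generation)
make_state <- function(dials, true_dial, revealed, removed = NULL,
                       cost = 0, external_count = 0L,
                       config = task_config(n_positions = nrow(dials),
                                            n_dials = ncol(dials))) {
  if (is.null(removed)) removed <- matrix(FALSE, nrow(dials), ncol(dials))
  structure(list(
    config = config, dials = dials, true_dial = true_dial,
    removed = removed, revealed = revealed,
    internal_count = rowSums(removed), external_count = external_count,
    cumulated_cost = cost, terminated = FALSE,
    accepted_option = NA_integer_, net_gain = NA_real_
  ), class = "trial_state")
}

# a two-option state: A has dials {20,40,60,80} (point 50, SD 22.3607),
# B has four equal dials b (point b, SD 0)
two_option_state <- function(b = 80) {
  dials <- rbind(c(20, 40, 60, 80), rep(b, 4), matrix(50, 7, 4))
  make_state(dials, true_dial = rep(1L, 9),
             revealed = c(TRUE, TRUE, rep(FALSE, 7)))
}

# small standardized event table simulated from a known beta
sim_rows <- function(beta, n = 500, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("v_internal", "v_external",
                                      "v_accept", "cost")))
  eta1 <- beta[1] + v %*% beta[2:5]
  eta2 <- beta[6] + v %*% beta[7:10]
  p <- cbind(exp(eta1), exp(eta2), 1)
  p <- p / rowSums(p)
  choice <- apply(p, 1, function(pr)
    sample(c("internal", "external", "accept"), 1, prob = pr))
  data.frame(participant = "p1", v, choice = choice)
}
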