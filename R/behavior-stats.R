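#' Group-level one-sample tests on per-participant coefficients
#'
#' For each of the ten choice-model coefficients: the group mean across
#' participants, a one-sample t statistic against zero with df = n - 1, and
#' the two-sided p value. A coefficient with zero between-participant
#' variance is flagged (`t` and `p` set to `NA`).
#'
#' @param fits List of per-participant `choice_fit` objects (>= 2).
#' @return Data frame with `coefficient`, `mean`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
group_coefficient_tests <- function(fits) {
  if (length(fits) < 2L) stop("need >= 2 participants", call. = FALSE)
  B <- t(vapply(fits, function(f) f$beta, numeric(10)))
  n <- nrow(B)
  out <- data.frame(coefficient = beta_names(), mean = colMeans(B),
                    t = NA_real_, df = n - 1L, p = NA_real_,
                    degenerate = FALSE)
  for (j in 1:10) {
    s <- stats::sd(B[, j])
    if (s == 0) {
      out$degenerate[j] <- TRUE
      next
    }
    out$t[j] <- out$mean[j] / (s / sqrt(n))
    out$p[j] <- 2 * stats::pt(-abs(out$t[j]), n - 1L)
  }
  rownames(out) <- NULL
  out
}

#' Sliding-window choice-proportion curves
#'
#' Per participant, events are ranked by one of the decision values into
#' `n_classes` equal-count classes (stable tie order; remainder events go to
#' the lowest classes), then consolidated into `n_classes - window + 1`
#' levels by a `window`-rank sliding window (30 classes with an 11-rank
#' window give exactly 20 levels). Within each window, events of the third
#' decision type are excluded and the two-way proportion of `pair[1]` among
#' `pair` is computed. The group curve is the unweighted mean over
#' participants; participants with fewer than `n_classes` events are
#' skipped with a warning.
#'
#' @param events Event table (raw or standardized) with `participant`,
#'   `choice`, and the value columns.
#' @param value_kind Which value ranks the events: `"internal"`,
#'   `"external"` or `"accept"`.
#' @param pair The two decision types to compare; default pairs the ranking
#'   value's own decision against accept (accept value: accept vs external).
#' @param n_classes Number of probability classes (default 30).
#' @param window Sliding-window width in classes (default 11).
#' @return Object of class `choice_curve`: data frame `curve` with `level`,
#'   `proportion` (group mean of P(pair[1])), `n_events` (mean events per
#'   level), plus `per_participant` matrix and settings.
#' @export
sliding_window_curves <- function(events,
                                  value_kind = c("internal", "external", "accept"),
                                  pair = NULL, n_classes = 30L, window = 11L) {
  value_kind <- match.arg(value_kind)
  vcol <- paste0("v_", value_kind)
  if (is.null(pair))
    pair <- switch(value_kind,
                   internal = c("internal", "accept"),
                   external = c("external", "accept"),
                   accept = c("accept", "external"))
  stopifnot(length(pair) == 2L, window <= n_classes)
  n_levels <- n_classes - window + 1L
  pids <- unique(events$participant)
  per <- matrix(NA_real_, length(pids), n_levels)
  cnt <- matrix(NA_real_, length(pids), n_levels)
  kept <- rep(TRUE, length(pids))
  for (k in seq_along(pids)) {
    ev <- events[events$participant == pids[k], ]
    n <- nrow(ev)
    if (n < n_classes) {
      warning("participant ", pids[k], " skipped: ", n, " events < ",
              n_classes, " classes", call. = FALSE)
      kept[k] <- FALSE
      next
    }
    rk <- order(ev[[vcol]])  # stable: ties keep input order
    # equal-count classes, remainder to the lowest classes
    base <- n %/% n_classes
    sizes <- rep(base, n_classes) + (seq_len(n_classes) <= n %% n_classes)
    cls <- integer(n)
    cls[rk] <- rep(seq_len(n_classes), sizes)
    for (w in seq_len(n_levels)) {
      idx <- cls >= w & cls <= w + window - 1L
      ch <- ev$choice[idx]
      ch <- ch[ch %in% pair]
      cnt[k, w] <- length(ch)
      per[k, w] <- if (length(ch)) mean(ch == pair[1]) else NA_real_
    }
  }
  if (!any(kept)) stop("no participant has enough events", call. = FALSE)
  per <- per[kept, , drop = FALSE]
  cnt <- cnt[kept, , drop = FALSE]
  structure(list(
    curve = data.frame(level = seq_len(n_levels),
                       proportion = colMeans(per, na.rm = TRUE),
                       n_events = colMeans(cnt)),
    per_participant = per, value_kind = value_kind, pair = pair,
    n_classes = n_classes, window = window), class = "choice_curve")
}
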