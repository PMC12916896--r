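#!/usr/bin/env Rscript
# Simulate the behavioural study: 24 softmax agents play 100 trials of the
# nine-option dial task. Writes the combined event log and reports the
# headline descriptives (decision-type proportions and the shares of trials
# without internal / external exploration).

suppressPackageStartupMessages(library(dialexplore))
dir.create("results", showWarnings = FALSE)

seed <- 20260920L
set.seed(seed)

cfg <- task_config()
disp <- 0.5 * abs(default_group_betas()) + 0.2
betas <- t(replicate(24, rnorm(10, default_group_betas(), disp)))
events <- do.call(rbind, lapply(1:24, function(i)
  simulate_choices(betas[i, ], cfg, participant = sprintf("sub%02d", i),
                   timing = timing_config())))

write_event_log(events, "results/behavior_events.tsv", config = cfg,
                seed = seed)
write_manifest(list(step = "simulate_behavior", seed = seed,
                    n_participants = 24, config = unclass(cfg)),
               "results/behavior_manifest.json")

props <- 100 * prop.table(table(events$choice))
cat(sprintf("%d decision phases from 24 agents x %d trials\n",
            nrow(events), cfg$n_trials))
cat(sprintf("decisions: internal %.2f%%  external %.2f%%  accept %.2f%%\n",
            props[["internal"]], props[["external"]], props[["accept"]]))
per_trial <- split(events$choice, paste(events$participant, events$trial))
cat(sprintf("trials without internal exploration: %.2f%%\n",
            100 * mean(vapply(per_trial, function(ch) !any(ch == "internal"),
                              logical(1)))))
cat(sprintf("trials without external exploration: %.2f%%\n",
            100 * mean(vapply(per_trial, function(ch) !any(ch == "external"),
                              logical(1)))))
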