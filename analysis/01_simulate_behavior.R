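#!/usr/bin/env Rscript
# Stage 1 — simulate the behavioral experiment.
#
# Two groups of six mice: "trained" animals earn 30 pellets on FR1 with a
# 1-s timeout, pressing in bouts; "yoked" animals receive 30 noncontingent
# VT60 deliveries and press sparsely.  One event log per animal is written
# under results/behavior/, in the tab-delimited dialect the rest of the
# workflow reads.

library(striatlearn)

seed <- 20260927L
out_dir <- "results/behavior"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

groups <- list(
  trained = list(schedule = schedule_config("FR1", criterion_rewards = 30,
                                            session_cap = 7200),
                 bout_rate = 1.2, ppb = 4, iri = 1.2, solitary = 0.4),
  yoked = list(schedule = schedule_config("VT", criterion_rewards = 30,
                                          session_cap = 7200),
               bout_rate = 0.15, ppb = 2.5, iri = 1.5, solitary = 0.3))

n_per_group <- 6
for (g in names(groups)) {
  gp <- groups[[g]]
  for (i in seq_len(n_per_group)) {
    id <- sprintf("%s_%02d", g, i)
    bp <- bout_process_params(gp$bout_rate, gp$ppb, gp$iri, gp$solitary,
                              duration = gp$schedule$session_cap,
                              seed = seed + 100L * i +
                                1000L * match(g, names(groups)))
    ses <- simulate_operant_session(gp$schedule, bp, subject_id = id,
                                    group = g, seed = seed + i +
                                      10L * match(g, names(groups)))
    write_event_log(ses, file.path(out_dir, paste0("events_", id, ".tsv")))
    cat(sprintf("%s: %d presses, %d rewards, session %.0f s\n", id,
                sum(ses$events$event_type == "press"), ses$n_rewards,
                ses$session_end))
  }
}
cat("event logs written to", out_dir, "\n")
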