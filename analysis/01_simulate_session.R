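#!/usr/bin/env Rscript
# Generate one ground-truthed synthetic closed-loop session and write it
# (plus a trial/event summary) under results/. All later analysis steps
# read this session directory.

library(swrloop)

seed <- 20260926L
dir.create("results", showWarnings = FALSE)

cfg <- session_config(n_tetrodes = 4, rng_seed = seed)
tcfg <- task_config(threshold_start = 7, threshold_max = 8)
ses <- gen_session(cfg, tcfg, day = 20, n_trials = 16,
                   rates = list(pre = c(nf = 0.4, delay = 0.4,
                                        control = 0.4),
                                post = c(nf = 0.4, delay = 0.4,
                                         control = 0.4),
                                travel = 0.02),
                   seed = seed)

write_session(ses, "results/session")

cat(sprintf("session: %.1f s, %d trials, %d ground-truth SWRs (%d with replay)\n",
            ses$duration, nrow(ses$trials), nrow(ses$events),
            sum(ses$events$replay_kind != "none")))
cat(sprintf("NF latencies (s): %s\n",
            paste(round(ses$nf_latencies, 2), collapse = " ")))

summ <- data.frame(
  duration_s = ses$duration,
  n_trials = nrow(ses$trials),
  n_nf = sum(ses$trials$type == "neurofeedback"),
  n_events = nrow(ses$events),
  n_replay = sum(ses$events$replay_kind != "none"),
  mean_nf_latency_s = mean(ses$nf_latencies))
write.table(summ, "results/01_session_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/session/ and results/01_session_summary.tsv\n")
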