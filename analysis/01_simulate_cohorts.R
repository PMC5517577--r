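#!/usr/bin/env Rscript

## Simulate the synthetic EEG-fMRI cohorts used by the downstream analyses
## and record their basic statistics.
##
## Cohorts (all 52-minute sessions, TR 2.08 s, 20 regions):
##   sleep      -- 58 subjects, four-stage hypnograms (~48/23/19/10% W/N1/N2/N3),
##                 two planted connectivity states (wake vs sleep)
##   wake_n1    -- 58 subjects, two-stage W/N1 hypnograms with front-loaded
##                 sleep pressure (short-scan analyses)
##   narcolepsy -- 9 subjects, five-stage hypnograms including REM
##
## Writes: results/cohort_prevalences.tsv, results/wake_probability.tsv and
## the cohorts themselves under results/cohorts/<name>/ (TSV + sidecars).

library(sleepstates)

seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cohorts <- list(
  sleep = default_sleep_cohort(n_subjects = 58, R = 20, seed = seed),
  wake_n1 = generate_cohort(58, stage_model_preset("wake_n1"),
                            covariance_preset(20, "wake_n1", seed = seed),
                            seed = seed),
  narcolepsy = generate_cohort(9, stage_model_preset("narcolepsy"),
                               covariance_preset(20, "narcolepsy", seed = seed),
                               seed = seed)
)

prev <- do.call(rbind, lapply(names(cohorts), function(nm) {
  stg <- unlist(lapply(cohorts[[nm]], function(s) s$hypnogram$stages))
  tab <- table(factor(stg, stage_levels())) / length(stg)
  data.frame(cohort = nm, stage = names(tab), prevalence = as.numeric(tab))
}))
write.table(prev, file.path(out_dir, "cohort_prevalences.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Stage prevalences (sleep cohort should be near 48/23/19/10):")
print(subset(prev, cohort == "sleep" & prevalence > 0))

## cohort-mean wakefulness probability over the session (epoch resolution)
pw <- rowMeans(vapply(cohorts$sleep, function(s) s$hypnogram$stages == "W",
                      logical(104)))
write.table(data.frame(epoch = seq_along(pw), minutes = (seq_along(pw) - 0.5) / 2,
                       p_wake = pw),
            file.path(out_dir, "wake_probability.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("Wakefulness probability falls from %.2f (first 5 min) to %.2f (last 5 min).",
                mean(pw[1:10]), mean(pw[95:104])))

for (nm in names(cohorts)) {
  write_cohort(cohorts[[nm]], file.path(out_dir, "cohorts", nm))
}
message("Cohorts written under ", file.path(out_dir, "cohorts"))
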