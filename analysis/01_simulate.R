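#!/usr/bin/env Rscript
# Simulate a small synthetic N2 cohort (cases with reduced fast-spindle
# density and more negative chirp, per the case/control contrasts the
# pipeline is built to detect) and export one subject as EDF + stage TSV.
#
# Outputs: results/cohort_covariates.tsv, results/subject01.edf,
#          results/subject01_stages.tsv, results/truth_counts.tsv

suppressMessages(library(sleepmicro))
dir.create("results", showWarnings = FALSE)
seed <- 20240901

template <- list(
  background = background_spec(1, 1200, fs = 200, one_over_f_slope = 2,
                               rms = 20),
  so = so_spec(density = 5, neg_peak_amp = -60, pos_peak_amp = 40),
  slow = spindle_spec(11, density = 2.0, amplitude = 25, chirp = -0.3),
  fast = spindle_spec(15, density = 2.7, amplitude = 25, chirp = -0.4,
                      coupling_phase = 240, coupling_kappa = 5),
  n2_fraction = 0.9)
template_case <- list(
  fast = spindle_spec(15, density = 1.9, amplitude = 23, chirp = -0.7,
                      coupling_phase = 240, coupling_kappa = 5))

cohort <- simulate_cohort_signals(
  cohort_spec(6, 6, effect_sizes = c(unused = 0), seed = seed),
  template, template_case)

write.table(cbind(subject = seq_len(nrow(cohort$covariates)),
                  cohort$covariates),
            "results/cohort_covariates.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

sub1 <- cohort$subjects[[1]]
write_edf(sub1$rec, "results/subject01.edf")
write_stage_tsv(sub1$stages, "results/subject01_stages.tsv")

counts <- do.call(rbind, lapply(seq_along(cohort$subjects), function(i) {
  tr <- cohort$subjects[[i]]$truth
  data.frame(subject = i, group = cohort$covariates$group[i],
             n2_minutes = cohort$subjects[[i]]$n2_minutes,
             so = nrow(tr$so), slow = nrow(tr$slow), fast = nrow(tr$fast))
}))
write.table(counts, "results/truth_counts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

dir.create("scratch", showWarnings = FALSE)
saveRDS(cohort, "scratch/cohort.rds")  # bulky intermediate, regenerated by this script
cat("Simulated", length(cohort$subjects), "subjects;",
    "true FS density (case vs control):",
    round(mean(counts$fast[counts$group == "case"] / counts$n2_minutes[counts$group == "case"]), 2),
    "vs",
    round(mean(counts$fast[counts$group == "control"] / counts$n2_minutes[counts$group == "control"]), 2),
    "per minute\n")
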