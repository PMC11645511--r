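#!/usr/bin/env Rscript
# Stage 1: simulate the two respondent cohorts.
#
# A convenience-panel cohort (strong selection bias, 14.4% misrepresenters,
# planted straight-liners/copiers, 3.5% incompletes) and a probability-panel
# cohort (mild bias, 0.5% misrepresenters) are generated with known ground
# truth and written as CSV tables. All later stages regenerate the same
# cohorts deterministically from the shared seed, so this stage's outputs are
# for inspection and external reuse.

library(panelqc)

seed <- 314  # analysis-wide seed; every stage derives its streams from it
cfg <- pipeline_config(seed = seed)

message("simulating convenience cohort (n = ", cfg$convenience$n, ") ...")
conv <- generate_cohort(cfg$convenience)
message("simulating probability cohort (n = ", cfg$probability$n, ") ...")
prob <- generate_cohort(cfg$probability)

write_cohort(conv, "results/cohorts/convenience")
write_cohort(prob, "results/cohorts/probability")

cat("\nPersona composition (ground truth):\n")
print(rbind(convenience = table(conv$truth$persona),
            probability = table(factor(prob$truth$persona,
                                       levels = sort(unique(conv$truth$persona))))))
cat("\nOverlaid incompletes: convenience ", sum(conv$truth$incomplete),
    ", probability ", sum(prob$truth$incomplete), "\n", sep = "")
cat("Cohort tables written under results/cohorts/\n")
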