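#!/usr/bin/env Rscript
# Step 3: apply the +/-2 kg and +/-5 kg referral tests at every visit.
#
# Each woman's cumulative gain from her reported pre-pregnancy weight is
# compared to the weekly expected range at her actual gestational age; a
# test is positive when gain falls strictly more than the margin outside the
# range. Writes the per-visit screen results and the zone distribution
# (counts and percentages by BMI category, visit and margin).

suppressPackageStartupMessages(library(gwgscreen))

cohort <- read_cohort("results/cohort.csv")
screens <- screen_cohort(cohort)
write_cohort(screens, "results/screen_results.csv")
write_cohort(distribution_table(screens), "results/distribution.csv")

cat("Screen results:", nrow(screens), "participant-visit-margin rows\n")
cat("Referral burden (screen positives):\n")
for (m in c(2, 5)) {
  for (v in c(19, 24, 30, 36)) {
    cat(sprintf(
      "  visit %2d wk, +/-%d kg: %3d of %d\n",
      v, m, count_positives(screens, v, m),
      length(unique(screens$participant_id))
    ))
  }
}
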