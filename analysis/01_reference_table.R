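#!/usr/bin/env Rscript
# Step 1: build the weekly expected-GWG reference table.
#
# The IOM total-gain recommendations (underweight 12.5-18 kg, normal
# 11.5-16 kg, overweight 7-11.5 kg, obese 5-9 kg) are spread linearly from a
# 0.5-2 kg first-trimester allowance at 13 weeks to the total at 40 weeks,
# giving a minimum/maximum expected cumulative gain for every week 13-40 and
# BMI category.

suppressPackageStartupMessages(library(gwgscreen))

ref <- reference_table()
dir.create("results", showWarnings = FALSE)
write_reference_csv(ref, "results/reference_table.csv")

cat("Reference table:", nrow(ref), "category-weeks ->",
  "results/reference_table.csv\n")
cat("Example ranges (min-max kg of cumulative gain):\n")
for (v in c(19, 24, 30, 36)) {
  r <- weekly_range(v, bmi_levels())
  for (i in 1:4) {
    cat(sprintf(
      "  %2d wk %-11s %5.2f - %5.2f\n",
      v, as.character(r$bmi_category[i]), r$min_kg[i], r$max_kg[i]
    ))
  }
}
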