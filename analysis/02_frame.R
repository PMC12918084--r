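#!/usr/bin/env Rscript
# Build the target-population post-stratification frame from the inputs
# written by 01_simulate.R: estimate the residents-survey joint, rake the
# auxiliary joint to the target-area margins, pool deprivation deciles
# into quintiles, and combine the three blocks under independence.
# Also writes the source-vs-target demographic comparison that motivates
# post-stratification.

suppressMessages(library(hlmrp))

inputs <- hlmrp:::read_pipeline_inputs(list(
  source_survey = "results/inputs/source_survey.csv",
  target_microdata = "results/inputs/target_microdata.csv",
  lfs_microdata = "results/inputs/lfs_microdata.csv",
  lfs_target_margins = "results/inputs/lfs_target_margins.json",
  lsoa_table = "results/inputs/lsoa_imd.csv",
  schema = "results/inputs/schema.yaml"))

frame <- build_poststrat_frame(
  inputs$schema, inputs$target_microdata,
  c("age", "sex", "ethnicity", "working", "ownhome"),
  inputs$lfs_microdata,
  c("qualification", "english", "ukborn", "job", "income"),
  inputs$lfs_margins, inputs$lsoa_table)

write_frame_csv(frame, "results/poststrat_frame.csv")
print(frame)

cmp <- compare_demographics(inputs$source_survey, frame)
write.csv(cmp, "results/demographic_comparison.csv", row.names = FALSE)

cat("\nLargest source-vs-target divergences (literacy subsample):\n")
lit <- cmp[cmp$outcome == "literacy", ]
lit <- lit[order(-abs(lit$difference)), ]
print(head(lit[c("variable", "level", "source_prop", "target_prop",
                 "difference")], 8), row.names = FALSE, digits = 3)
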