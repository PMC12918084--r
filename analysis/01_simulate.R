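#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a source skills survey (three
# graded outcomes on nested subsamples), target-area residents microdata,
# auxiliary labour-force-style microdata with the target margins raking
# must hit, and the small-area deprivation table.  All inputs derive from
# one master seed; ground-truth parameters are written alongside so later
# steps can check recovery.

suppressMessages(library(hlmrp))

seed <- 2026
out <- "results/inputs"

bundle <- make_default_bundle(seed, n_source = 4000, n_target = 3000,
                              n_lfs = 3000, n_lsoa = 164)
write_bundle_csv(bundle, out)

print(bundle)
cat("\nObserved (crude) source prevalences of not meeting the threshold:\n")
for (oc in names(bundle$source_survey$outcomes)) {
  y <- bundle$source_survey$outcomes[[oc]]$y
  cat(sprintf("  %-9s %.3f  (n = %d)\n", oc, mean(y), length(y)))
}
cat("\nInputs written to", out, "\n")
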