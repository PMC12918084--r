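#!/usr/bin/env Rscript
# Post-stratify the posterior cell predictions over the target frame and
# compute the counterfactual MRP-ATE for every non-reference covariate
# level: the change in probability of not being health literate if the
# whole target population were assigned that level instead of the
# reference, averaging over all other covariates.

suppressMessages(library(hlmrp))

schema <- read_schema("results/inputs/schema.yaml")
frame <- read_frame_csv("results/poststrat_frame.csv", schema)

ate_all <- list()
prev <- list()
for (oc in c("literacy", "numeracy", "ict")) {
  fit <- read_posterior_csv(sprintf("results/draws/%s.csv", oc), schema)
  preds <- predict_cells(fit, frame$cells)
  pi_mrp <- poststratify(preds, frame)
  prev[[oc]] <- data.frame(outcome = oc, mean = mean(pi_mrp),
                           lower95 = quantile(pi_mrp, 0.025, type = 7),
                           upper95 = quantile(pi_mrp, 0.975, type = 7))
  at <- ate_table(preds, frame, outcome = oc)
  ate_all[[oc]] <- at$summary
  write.csv(at$draws, sprintf("results/draws/ate_%s.csv", oc),
            row.names = FALSE)
}
ate <- do.call(rbind, ate_all)
write.csv(ate, "results/ate_table.csv", row.names = FALSE)
write.csv(do.call(rbind, prev), "results/mrp_prevalence.csv",
          row.names = FALSE)

cat("Post-stratified prevalence of not being health literate:\n")
print(do.call(rbind, prev), row.names = FALSE, digits = 3)
cat("\nStrongest effects per outcome (|mean| MRP-ATE):\n")
for (oc in names(ate_all)) {
  s <- ate_all[[oc]]
  s <- s[order(-abs(s$mean)), ]
  print(head(s[c("outcome", "variable", "level", "mean_r", "lower95_r",
                 "upper95_r")], 3), row.names = FALSE)
}
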