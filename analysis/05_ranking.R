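#!/usr/bin/env Rscript
# Convert per-draw absolute MRP-ATEs into probabilistic priority
# rankings: cumulative rank probabilities, the filtered rankogram (first
# four positions, cumulative probability >= 0.25), and SUCRA / expected
# rank per determinant and outcome.

suppressMessages(library(hlmrp))

sucra_all <- list()
ranko <- list()
ranko_full <- list()
for (oc in c("literacy", "numeracy", "ict")) {
  draws <- as.matrix(read.csv(sprintf("results/draws/ate_%s.csv", oc),
                              check.names = FALSE))
  prof <- cumulative_rank_probs(rank_draws(draws))
  su <- sucra(prof)
  su$outcome <- oc
  sucra_all[[oc]] <- su
  r <- rankogram_table(prof, top_ranks = 4, min_prob = 0.25)
  r$outcome <- oc
  ranko[[oc]] <- r
  rf <- rankogram_table(prof, top_ranks = prof$n, min_prob = 0)
  rf$outcome <- oc
  ranko_full[[oc]] <- rf
}
write.csv(do.call(rbind, sucra_all), "results/sucra_table.csv",
          row.names = FALSE)
write.csv(do.call(rbind, ranko), "results/rankogram.csv",
          row.names = FALSE)
write.csv(do.call(rbind, ranko_full), "results/rankogram_full.csv",
          row.names = FALSE)

cat("Top-3 determinants by SUCRA:\n")
for (oc in names(sucra_all)) {
  s <- sucra_all[[oc]][order(-sucra_all[[oc]]$sucra), ]
  cat(sprintf("  %s: %s\n", oc,
              paste(sprintf("%s (%d%%)", head(s$item, 3),
                            head(s$sucra_pct, 3)), collapse = ", ")))
}
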