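#!/usr/bin/env Rscript
# Model-free hierarchical distances: for each pair of injected areas, fit a
# unit-slope line to the logit ODRs toward their common target areas (and,
# separately, from their common source areas); the intercept magnitude is
# the hierarchical distance.

library(hierODR)

cat10 <- read_area_catalog("results/sim/areas.json")
obs <- read_edge_table("results/sim/edge_table.tsv", cat10)
m <- build_odr_matrix(obs, cat10)

for (mode in c("targets", "sources")) {
  d <- distance_matrix(m, mode)
  write.table(round(d$intercepts, 6),
              sprintf("results/pairs_intercepts_%s.tsv", mode),
              sep = "\t", quote = FALSE, col.names = NA)
  far <- which(d$distances == max(d$distances, na.rm = TRUE), arr.ind = TRUE)[1, ]
  message(sprintf("[%s] most separated pair: %s - %s (distance %.2f)",
                  mode, rownames(d$distances)[far[1]],
                  colnames(d$distances)[far[2]],
                  max(d$distances, na.rm = TRUE)))
}
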