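#!/usr/bin/env Rscript
# Desert-bird diversity from the impact run: retention through AOH
# refinement and the >= 90%-in-desert rule, rarity-weighted richness, and
# how diversity co-varies with projected impact.

library(desertrefugia)
if (!file.exists("results/run/impact_surface.csv"))
  stop("run analysis/03_impact.R first")

surf <- read.csv("results/run/impact_surface.csv")
birds <- read.csv("results/run/desert_birds.csv")
log <- read.csv("results/run/retention_log.csv")

cat("Species funnel:\n")
cat("  generated:", nrow(log),
    "| non-empty AOH:", sum(log$retained),
    "| desert birds (>=90% of AOH in desert):", nrow(birds), "\n")
cat("  size classes:", paste(names(table(birds$size_class)),
                             table(birds$size_class), collapse = ", "), "\n")
cat("RWR: map total", round(sum(surf$rwr), 3),
    "(= retained desert birds, by construction)\n")
cat("  top-decile RWR pixels hold",
    round(100 * sum(sort(surf$rwr, decreasing = TRUE)[
      seq_len(ceiling(0.1 * nrow(surf)))]) / sum(surf$rwr)),
    "% of total rarity weight\n")
cat("Pearson r, RWR ~ TEWL overlap:",
    round(pearson_r(surf$rwr, surf$tewl_overlap), 3), "\n")

agg <- aggregate(cbind(rwr, tewl_overlap, adr_overlap) ~ realm, surf, mean)
write.csv(agg, "results/diversity_by_realm.csv", row.names = FALSE)
cat("wrote results/diversity_by_realm.csv\n")
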