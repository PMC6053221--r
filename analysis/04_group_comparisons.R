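#!/usr/bin/env Rscript
# Condition comparisons on the simulated dataset: pairwise Fisher's exact
# tests on near-membrane contingency tables, and Kruskal-Wallis with
# Dunn's post hoc on per-terminal metrics and apposition gaps.

suppressPackageStartupMessages(library(presynmorph))

ct <- read.delim("results/tables/contingency.tsv")
cat("pairwise Fisher tests (vesicles <50 nm vs beyond):\n")
for (i in seq_len(nrow(ct))) {
  cat(sprintf("  %-13s %-13s vs %-13s %.3f vs %.3f  p = %.4f\n",
              ct$compartment[i], ct$condition_a[i], ct$condition_b[i],
              ct$fraction_a[i], ct$fraction_b[i], ct$p_two_sided[i]))
}

gs <- read.delim("results/tables/group_stats.tsv")
cat("\nKruskal-Wallis + Dunn (per-terminal metrics):\n")
for (m in unique(gs$metric)) {
  sub <- gs[gs$metric == m, ]
  cat(sprintf("  %-22s H = %6.2f  omnibus p = %.4f\n",
              m, sub$H[1], sub$p_omnibus[1]))
  for (i in seq_len(nrow(sub)))
    cat(sprintf("      %s vs %s: z = %6.2f, adjusted p = %.4f\n",
                sub$group1[i], sub$group2[i], sub$z[i], sub$p_adj[i]))
}
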