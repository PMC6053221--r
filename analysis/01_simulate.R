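#!/usr/bin/env Rscript
# Generate a three-condition synthetic EM-annotation dataset with ground
# truth. A scaled-down study (30/50/50 terminals instead of the full
# 167/295/287) keeps the downstream scripts quick while leaving every
# per-condition pool large enough for density estimation.

suppressPackageStartupMessages(library(presynmorph))

presets <- condition_presets()
presets$unstimulated$n_terminals <- 30
presets$low_freq$n_terminals <- 50
presets$high_freq$n_terminals <- 50

out_dir <- "results/synthetic"
ds <- generate_dataset(presets, seed = 20260925, out_dir = out_dir)

for (cond in names(ds$annotations)) {
  anns <- ds$annotations[[cond]]
  nv <- sum(vapply(anns, function(a) nrow(a$vesicles), 0L))
  cat(sprintf("%-13s %3d terminals, %5d vesicles, pools at %s nm\n",
              cond, length(anns), nv,
              paste(presets[[cond]]$az_pools$mean_nm, collapse = "/")))
}
cat("bundles + ground truth written to", out_dir, "\n")
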