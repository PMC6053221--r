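#!/usr/bin/env Rscript
# Pool vesicle distances per condition and compartment, fit the
# Gaussian-kernel density (Silverman bandwidth) and identify vesicle-pool
# peaks with their probability mass; count near-membrane (<50 nm) vesicles.

suppressPackageStartupMessages(library(presynmorph))

dist_file <- "results/tables/pooled_distances.tsv"
stopifnot(file.exists(dist_file))
distances <- read.delim(dist_file)

cat("vesicle-pool peaks (KDE, Silverman bandwidth):\n")
for (cond in unique(distances$condition)) {
  for (cmp in c(d_active_zone = "active zone", d_glial = "glial facing")) {
    col <- names(which(c(d_active_zone = "active zone",
                         d_glial = "glial facing") == cmp))
    d <- distances[distances$condition == cond, col]
    d <- d[!is.na(d)]
    if (length(d) < 50) next
    pd <- pool_distribution(d, compartment = cmp, condition = cond)
    nm <- near_membrane_fraction(d)
    cat(sprintf("  %-13s %-13s n=%5d  bw %4.1f nm  peaks: %s  <50 nm: %.3f\n",
                cond, cmp, length(d), pd$bandwidth,
                paste(sprintf("%.0f nm (%.1f%%)", pd$peaks$peak_nm,
                              pd$peaks$probability_pct), collapse = ", "),
                nm$fraction))
  }
}
cat("\n(peak table already in results/tables/pool_peaks.tsv)\n")
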