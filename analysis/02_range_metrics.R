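#!/usr/bin/env Rscript
# Stage 2: gridded range metrics.
#
# Range size (km^2, spherical cell areas), range centroid and diversity
# field per host from the presence-absence matrix written by stage 1.

library(ectofauna)

indir <- "results/analysis/input"
outdir <- "results/analysis"
grid <- grid_spec(-10, 10, -10, 10, 1)

pam <- read_matrix_csv(file.path(indir, "presence_absence.csv"))
rs <- range_summary(pam, grid)
write.csv(rs, file.path(outdir, "range_summary.csv"), row.names = FALSE)

cat(sprintf("range size: median %.0f km^2 (IQR %.0f-%.0f)\n",
            median(rs$range_size_km2), quantile(rs$range_size_km2, 0.25),
            quantile(rs$range_size_km2, 0.75)))
cat(sprintf("diversity field: median %.1f co-occurring species\n",
            median(rs$diversity_field)))
cat("wrote", file.path(outdir, "range_summary.csv"), "\n")
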