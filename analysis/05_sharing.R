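#!/usr/bin/env Rscript
# Stage 5: probability of parasite sharing between hosts.
#
# For each distance type: per-parasite logistic regressions of incidence
# cases on the normalized distance (parasites on >= 6 hosts), a 200-draw
# species bootstrap of the pooled intercept/slope, the proportion of
# negative slopes (PNS) and the pooled probability curve
# P(D) = 1 / (1 + exp(-(a + b D))).

library(ectofauna)

indir <- "results/analysis/input"
outdir <- "results/analysis"

inc <- read_matrix_csv(file.path(indir, "incidence.csv"))

pooled <- list()
for (k in c("PD", "TD", "GD", "ED")) {
  d <- read_dist_csv(file.path(outdir, paste0("distance_", k, ".csv")),
                     kind = k)
  attr(d, "normalized") <- TRUE
  fit <- pooled_coefficients(inc, d, n_iter = 200, seed = 44L)
  write.csv(fit$per_parasite,
            file.path(outdir, paste0("per_parasite_", k, ".csv")),
            row.names = FALSE)
  write.csv(data.frame(iteration = seq_len(fit$n_iter),
                       mean_a = fit$boot_a, mean_b = fit$boot_b),
            file.path(outdir, paste0("bootstrap_", k, ".csv")),
            row.names = FALSE)
  write.csv(sharing_probability(fit$a, fit$b),
            file.path(outdir, paste0("curve_", k, ".csv")), row.names = FALSE)
  pooled[[k]] <- data.frame(distance = k, mean_intercept = fit$a,
                            mean_slope = fit$b, pns = fit$pns)
  cat(sprintf("%s: a = %6.3f, b = %6.3f, PNS = %.2f (%d parasites)\n",
              k, fit$a, fit$b, fit$pns, nrow(fit$per_parasite)))
}
write.csv(do.call(rbind, pooled), file.path(outdir, "pooled_sharing.csv"),
          row.names = FALSE)
cat("sharing outputs written to", outdir, "\n")
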