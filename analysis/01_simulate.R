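#!/usr/bin/env Rscript
# Stage 1: simulate a synthetic realm with planted sharing coefficients.
#
# 60 host species on a 20 x 20 degree grid (1-degree cells), 30 parasite
# species generated in sharing mode around the normalized trait distance
# (a_true = 2, b_true = -6). Writes the raw inputs every later stage
# consumes; the planted truth goes into the JSON sidecar.

library(ectofauna)

seed <- 42L
outdir <- "results/analysis/input"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- world_config(n_hosts = 60, n_parasites = 30,
                    grid = grid_spec(-10, 10, -10, 10, 1), seed = seed,
                    mode = "sharing", sharing_coefs = c(2, -6),
                    sharing_distance = "trait", range_median_cells = 25)
world <- simulate_world(cfg)

ape::write.tree(world$tree, file.path(outdir, "tree.nwk"))
write_traits_csv(world$traits, file.path(outdir, "traits.csv"))
write_matrix_csv(world$pam, file.path(outdir, "presence_absence.csv"))
write_matrix_csv(world$env, file.path(outdir, "environment.csv"),
                 label = "cell_id")
write_matrix_csv(world$incidence, file.path(outdir, "incidence.csv"),
                 label = "parasite_id")
write_world_sidecar(cfg, file.path(outdir, "world_config.json"))

cat(sprintf("simulated %d hosts x %d parasites; %d parasites on >= 6 hosts\n",
            nrow(world$pam), nrow(world$incidence),
            length(eligible_parasites(world$incidence))))
cat("inputs written to", outdir, "\n")
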