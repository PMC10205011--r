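#!/usr/bin/env Rscript
# Step 4 — how the stimulation effects relate to the structural degree of
# the stimulated site, and how noise modulates that relation.
#
# Per (noise amplitude, realization): Pearson r between the per-site effect
# and the site's weighted degree, the OLS adjusted R^2, and
# Benjamini-Hochberg FDR q-values across all noise amplitudes and
# realizations (per effect family). Writes degree_association_cells.csv
# and degree_association_ensemble.csv.

library(stimnet)

conn <- load_connectome("results/connectome/weights.csv",
                        "results/connectome/distances.csv",
                        "results/connectome/regions.csv")
effects <- read.csv("results/effects.csv")

da <- degree_association(effects, structural_degree(conn))
write.csv(da$cells, "results/degree_association_cells.csv",
          row.names = FALSE)
write.csv(da$ensemble, "results/degree_association_ensemble.csv",
          row.names = FALSE)

fun <- da$ensemble[da$ensemble$effect == "functional", ]
fun <- fun[order(fun$sigma), ]
cat("r(fe, degree) by noise amplitude:\n")
print(fun[, c("sigma", "r_mean", "r_sd", "r2_adj_mean")])
cat(sprintf("maximum association at sigma = %.0e (interior: %s)\n",
            fun$sigma[which.max(fun$r_mean)],
            which.max(fun$r_mean) %in% c(1, nrow(fun)) == FALSE))
str <- da$ensemble[da$ensemble$effect == "structural", ]
str <- str[order(str$sigma), ]
cat("r(se, degree) by noise amplitude:\n")
print(str[, c("sigma", "r_mean", "r_sd")])
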