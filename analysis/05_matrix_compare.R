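#!/usr/bin/env Rscript
# Stage 5: do genetic or geographic structure explain immune structure?
#
# Mantel permutation tests of site-level immunological distance against
# geographic distance (raw and log(d+1)) and against genetic distance
# (pairwise F_ST), plus UPGMA trees of each matrix for tanglegram-style
# comparison.

suppressPackageStartupMessages(library(ecoimmune))
imm <- read_distance_matrix("results/immune_distance_matrix.csv")
geo <- read_distance_matrix("results/data/geographic_km.csv")
fstm <- read_distance_matrix("results/fst_matrix.csv")

common <- sort(intersect(rownames(imm), rownames(geo)))
imm <- distance_matrix(imm[common, common], common, tol = 1e-6)
geo <- distance_matrix(geo[common, common], common, tol = 1e-6)
fstm <- distance_matrix(fstm[common, common], common, tol = 1e-6)

tests <- list(
  immune_vs_geographic = mantel(imm, geo, n_perm = 999, seed = 1),
  immune_vs_log_geographic = mantel(imm, geo, n_perm = 999, seed = 1,
                                    transform = "log1p"),
  immune_vs_genetic = mantel(imm, fstm, n_perm = 999, seed = 1))
tab <- do.call(rbind, lapply(names(tests), function(nm) {
  data.frame(comparison = nm, r = tests[[nm]]$r, p = tests[[nm]]$p,
             n_perm = tests[[nm]]$n_perm, n_sites = tests[[nm]]$n_entities)
}))
write.csv(tab, "results/mantel_tests.csv", row.names = FALSE)
print(tab, row.names = FALSE)
for (i in seq_len(nrow(tab))) {
  cat(sprintf("-> %s: %s association (r = %.2f, p = %.3f)\n",
              tab$comparison[i],
              if (tab$p[i] <= 0.05) "significant" else "no",
              tab$r[i], tab$p[i]))
}

write_tree(upgma(imm), "results/upgma_immune.nwk")
write_tree(upgma(geo), "results/upgma_geographic.nwk")
write_tree(upgma(fstm), "results/upgma_genetic.nwk")
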