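#!/usr/bin/env Rscript
# Stage 3: immunological distance.
#
# Standardized PCA of the ten immune measures, Euclidean distance among
# mice over the first three components, within/among-site summaries, the
# within-distance-vs-sample-size check, and a two-dimensional MDS of the
# among-site distances.

suppressPackageStartupMessages(library(ecoimmune))
cohort <- read_cohort("results/cohort_condition.csv", "canonical")

pca <- immune_pca(cohort[c("mouse_id", "cd4", "cd8", "cd19", "nk",
                           "neutrophil", "dc", "macrophage",
                           "igg", "ige", "iga")])
cat(sprintf("PCA variance explained: %s%% (%d mice excluded)\n",
            paste(round(100 * pca$variance_explained, 1), collapse = "/"),
            pca$n_excluded))

dm <- immune_distance(pca)
sites <- setNames(cohort$site, cohort$mouse_id)
summ <- site_distance_summary(dm, sites)
wvn <- within_distance_vs_n(summ, seed = 1)
asd <- among_site_distance(dm, sites)
mds <- classical_mds(asd, k = 2)

write.csv(summ$per_site, "results/immune_distance_sites.csv",
          row.names = FALSE)
write_distance_matrix(asd, "results/immune_distance_matrix.csv")
write.csv(data.frame(site = rownames(mds), mds1 = mds[, 1],
                     mds2 = mds[, 2]),
          "results/immune_mds_coordinates.csv", row.names = FALSE)

cat(sprintf("within-site distance %.2f +/- %.3f; among-site %.2f +/- %.3f\n",
            summ$overall$mean[1], summ$overall$se[1],
            summ$overall$mean[2], summ$overall$se[2]))
cat(sprintf("within-distance vs site size: r = %.3f, p = %.2f, n = %d\n",
            wvn$r, wvn$p, wvn$n_sites))
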