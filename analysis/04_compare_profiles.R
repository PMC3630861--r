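#!/usr/bin/env Rscript
# Stage 4 — cross-protein profile comparison.
#
# Pearson correlations between the z-score profiles, complete-linkage
# hierarchical clustering on Euclidean distances (newick export), and
# the heat-map ordering of the z matrix. The nv-like profile should sit
# closest to the p52-like one and farthest from the relA-like one, with
# the relA-like dimer joining the dendrogram last.

library(kappaBarray)

profiles <- load_zscore_table("results/zscores.tsv")
cm <- correlation_matrix(profiles)
print(cm)
write_correlations(cm, "results/correlations.tsv")

dend <- cluster_profiles(profiles)
print(dend)
cat(sprintf("outermost (last-joining) profile: %s\n", outermost_leaf(dend)))
write_newick(dend, "results/dendrogram.nwk")

hm <- heatmap_matrix(profiles, dend)
cat(sprintf("heat-map matrix: %d probes x %d proteins, columns %s\n",
            nrow(hm$matrix), ncol(hm$matrix),
            paste(hm$col_order, collapse = ", ")))
# the ordered matrix itself is bulky; keep it in scratch/
write.table(data.frame(probe = rownames(hm$matrix), hm$matrix,
                       check.names = FALSE),
            "scratch/heatmap_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ord <- cm$values["nv_p50_like", c("hs_p52_like", "hs_p50_like", "relA_like")]
cat(sprintf("correlation ordering nv vs (p52, p50, relA): %.3f > %.3f > %.3f : %s\n",
            ord[1], ord[2], ord[3],
            ifelse(ord[1] > ord[2] && ord[2] > ord[3], "as expected", "UNEXPECTED")))
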