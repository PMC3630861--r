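#!/usr/bin/env Rscript
# Stage 1 — array design.
#
# Expands the kappaB consensus RGGRNNHHYYB into its 6,912-string k-mer
# space, embeds a seeded subsample by principal coordinates on Hamming
# distances, selects 803 representative cores by k-medoids, and
# assembles the 803 x 4 flanks x 3 replicates = 9,636-feature design
# for a 15K array. The full design table is bulky and goes to scratch/;
# a summary lands in results/.

library(kappaBarray)

seed <- 20260923L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

space <- expand_iupac("RGGRNNHHYYB")
cat(sprintf("k-mer space: %d unique %d-mers for %s\n",
            length(space$kmers), space$motif$length, space$motif$consensus))

# embed a 2,000-k-mer seeded subsample (the Hamming geometry of the
# space is highly redundant; the subsample keeps the eigendecomposition
# and medoid search tractable on one core)
cfg <- run_config(k = 803L, subsample = 2000L, seed = seed,
                  outdir = "scratch")
t0 <- Sys.time()
design <- design_array(cfg)
cat(sprintf("selected %d representative cores in %.0f s\n",
            length(design$cores), as.numeric(Sys.time() - t0, units = "secs")))

emb <- attr(design, "embedding")
cat(sprintf("PCoA: %d axes retain %.1f%% of positive eigenvalue mass; negative mass %.1f%%\n",
            ncol(emb$coordinates), 100 * emb$retained_fraction,
            100 * emb$negative_mass))

write_design(design, "scratch/design.tsv")
summary_tab <- data.frame(
  quantity = c("kmer_space_size", "cores_selected", "flank_variants",
               "replicates", "features", "capacity"),
  value = c(length(space$kmers), length(design$cores), nrow(design$flanks),
            design$replicates, nrow(design$features), design$capacity))
write.table(summary_tab, "results/design_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary_tab)
cat("design written to scratch/design.tsv\n")
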