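#!/usr/bin/env Rscript
# Stage 5 — DNA binding barcodes.
#
# For each dimer, the top-20 highest-z cores are summarised as a
# position frequency matrix with per-position information content
# (bits), exported in minimal MEME format, and scored for kappaB
# half-site symmetry (5' GG at positions 2-3 vs 3' CC at positions
# 9-10). The hs-p50-like barcode is expected to lose the GG..CC
# symmetry relative to the p52-like and nv-like ones.

library(kappaBarray)

design <- read_design("scratch/design.tsv")
profiles <- load_zscore_table("results/zscores.tsv")

barcodes <- lapply(profiles, function(p)
  position_frequency_matrix(top_n_probes(p, design, 20), p$protein))

for (bc in barcodes) {
  print(bc)
  write_meme(bc, sprintf("results/barcode_%s.meme", bc$protein))
}

ic <- data.frame(position = seq_len(ncol(barcodes[[1]]$pfm)),
                 vapply(barcodes, `[[`,
                        numeric(ncol(barcodes[[1]]$pfm)), "information_content"),
                 check.names = FALSE)
write.table(ic, "results/information_content.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sym <- vapply(barcodes, half_site_symmetry, numeric(1))
write.table(data.frame(protein = names(sym), symmetry = unname(sym)),
            "results/half_site_symmetry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("half-site symmetry scores:\n")
print(round(sym, 3))
cat(sprintf("p50-like symmetry below p52-like: %s\n",
            ifelse(sym["hs_p50_like"] < sym["hs_p52_like"],
                   "as expected", "UNEXPECTED")))
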