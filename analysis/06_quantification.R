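#!/usr/bin/env Rscript
# Stage 6 — plate-level quantification statistics.
#
# Applies the three fold-change statistics to the bundled synthetic
# example plates (labelled synthetic; values chosen to echo the
# qualitative interaction pattern: HsIkB-zeta pairs with human p50
# only, NvBcl3 with Nematostella p50 only, IkB-alpha with both).

library(kappaBarray)

extdata <- function(f) system.file("extdata", f, package = "kappaBarray")
dir.create("results", showWarnings = FALSE)

lum <- read_plate_records(extdata("synthetic_lumier_plate.tsv"), "lumier")
fold <- lumier_fold_binding(lum)
cat("LUMIER fold-binding over the BAP control:\n")
print(round(fold, 2))
write.table(data.frame(pair_id = names(fold), fold_binding = unname(fold)),
            "results/quantification_lumier.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rep_recs <- read_plate_records(extdata("synthetic_reporter_plate.tsv"), "reporter")
ind <- reporter_fold_induction(rep_recs)
cat("\nreporter fold-induction over empty vector (mean +/- sd):\n")
print(transform(ind, fold = round(fold, 2), sd = round(sd, 3)))
write.table(ind, "results/quantification_reporter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

chip <- read_plate_records(extdata("synthetic_chip_plate.tsv"), "chip")
chip$fold_over_IgG <- chip_fold_enrichment(chip$antibody_ct, chip$control_ct,
                                           chip$efficiency)
cat("\nChIP-qPCR fold-enrichment over IgG:\n")
print(transform(chip[, c("target_region", "fold_over_IgG")],
                fold_over_IgG = round(fold_over_IgG, 2)))
write.table(chip, "results/quantification_chip.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
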