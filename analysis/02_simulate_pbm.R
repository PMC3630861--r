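#!/usr/bin/env Rscript
# Stage 2 — synthetic PBM hybridisation.
#
# Simulates two-channel (Cy3/Cy5) intensities for the four-dimer PWM
# suite on the stage-1 design: occupancy ground truth per probe, a
# shared per-spot double-stranding efficiency, and log-normal
# measurement noise per row. The long intensity table is large and is
# kept in scratch/.

library(kappaBarray)

seed <- 20260923L
design <- read_design("scratch/design.tsv")
print(design)

suite <- default_dimer_suite()
cat("PWM divergence from nv_p50_like (Frobenius):\n")
for (nm in c("hs_p52_like", "hs_p50_like", "relA_like"))
  cat(sprintf("  %-12s %.2f\n", nm, pwm_distance(suite$nv_p50_like, suite[[nm]])))

t0 <- Sys.time()
tab <- simulate_intensities(design, suite, noise_model(seed = seed))
cat(sprintf("simulated %d intensity rows (%d proteins x 2 channels) in %.0f s\n",
            nrow(tab), length(suite),
            as.numeric(Sys.time() - t0, units = "secs")))
write_intensities(tab, "scratch/intensities.tsv")
cat("intensities written to scratch/intensities.tsv\n")
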