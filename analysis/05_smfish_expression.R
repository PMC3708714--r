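#!/usr/bin/env Rscript
# smFISH transcript counting: simulate quantized spot intensities for the
# four expressing strains at their measured relative levels, estimate the
# single-transcript unit from the intensity distribution, count
# transcripts per cell, and normalize to wild-type lambda units (WLU).

suppressPackageStartupMessages(library(smloop))
dir.create("results", showWarnings = FALSE)
seed <- 5005

wt_mean <- 4  # transcripts/cell in the wild type
wlu_true <- c(WT = 1.00, dOL = 1.38, OR3m = 2.50, OL3m = 2.51)
d <- gen_smfish_dataset(wt_mean * wlu_true, n_cells = 3000, seed = seed)

unit <- single_transcript_intensity(d$spots$intensity[d$spots$strain == "WT"])
cat(sprintf("single-transcript intensity unit: %.0f a.u. (generator mu1 = 1000)\n", unit))

counts <- lapply(names(wlu_true), function(s)
  transcripts_per_cell(d$spots[d$spots$strain == s, ], unit = unit,
                       n_cells = 3000)$counts$n_transcripts)
names(counts) <- names(wlu_true)

rows <- lapply(names(wlu_true), function(s) {
  wl <- expression_wlu(counts[[s]], counts$WT, n_boot = 1000, seed = seed + 7)
  data.frame(strain = s, mean_per_cell = wl$mean_per_cell,
             wlu = wl$wlu, sem = wl$sem, wlu_true = wlu_true[[s]])
})
tab <- do.call(rbind, rows)
print(tab, digits = 3)
cat("-> recovered WLU track the generating ratios within error;\n",
    "   the O_R3/O_L3 mutants sit at ~2.5x wild type, the O_L deletion at ~1.4x\n")
write.csv(tab, "results/05_smfish_wlu.csv", row.names = FALSE)
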