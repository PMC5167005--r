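#!/usr/bin/env Rscript
# Qualitative pattern reproduction: with both pressure conditions carrying
# equal moderate amplitudes and brushing null (scalp component largest for
# painful pressure), the group analysis should find the pressure conditions
# significant against zero after FDR, brushing not, pressure-vs-brush post
# hoc contrasts significant, and pain-vs-nonpainful not.

library(nirspine)

seed <- 20260928L
n_runs <- 10
rows <- list()
for (r in seq_len(n_runs)) {
  st <- run_study(n_subjects = 20, seed = seed + r,
                  params = pattern_sim_params(), tracks = "All")
  vz <- st$group$All$vs_zero
  ph <- st$group$All$posthoc
  vz <- vz[vz$chromophore == "O2Hb", ]
  ph <- ph[ph$chromophore == "O2Hb", ]
  nsig <- function(df, sel) sum(df$significant[sel] %in% TRUE)
  rows[[r]] <- data.frame(
    run = r,
    papain_vs_zero = nsig(vz, vz$condition == "PAPain"),
    pa30_vs_zero = nsig(vz, vz$condition == "PA30"),
    brush_vs_zero = nsig(vz, vz$condition == "Brush"),
    papain_vs_brush = nsig(ph, ph$pair == "PAPain vs Brush"),
    pa30_vs_brush = nsig(ph, ph$pair == "PA30 vs Brush"),
    papain_vs_pa30 = nsig(ph, ph$pair == "PAPain vs PA30"))
}
tab <- do.call(rbind, rows)
tab$pattern_ok <- tab$papain_vs_zero >= 1 & tab$pa30_vs_zero >= 1 &
  tab$brush_vs_zero == 0 & tab$papain_vs_brush >= 1 &
  tab$pa30_vs_brush >= 1 & tab$papain_vs_pa30 == 0
print(tab, row.names = FALSE)
cat(sprintf("study effect structure reproduced in %d / %d cohorts of 20 subjects\n",
            sum(tab$pattern_ok), n_runs))
dir.create("results", showWarnings = FALSE)
utils::write.table(tab, "results/pattern_reproduction.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
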