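#!/usr/bin/env Rscript
# Step 1 — simulate the three synthetic NSCLC comparator arms.
#
# Three arms are generated from the calibrated presets (second-line
# docetaxel-like and erlotinib-like arms, first-line paclitaxel/
# carboplatin-like arm) at the published arm sizes, and written as the
# assessment/survival CSV pair each later step reads. Ground-truth kinetic
# parameters are stored alongside for recovery diagnostics.

library(tgmetrics)

seed0 <- 20260901L
outdir <- "results/cohorts"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

arms <- c("docetaxel", "erlotinib", "paclitaxel_carboplatin")
for (i in seq_along(arms)) {
  spec <- nsclc_arm_spec(arms[i])
  coh <- generate_cohort(spec, seed = seed0 + i)
  write_assessments(coh$assessments,
                    file.path(outdir, paste0(arms[i], "_assessments.csv")),
                    seed = seed0 + i, config = spec)
  write_survival(coh$survival,
                 file.path(outdir, paste0(arms[i], "_survival.csv")),
                 seed = seed0 + i, config = spec)
  write.csv(coh$params_true,
            file.path(outdir, paste0(arms[i], "_params_true.csv")),
            row.names = FALSE)
  cat("==", arms[i], "==\n")
  print(coh)
}
cat("cohorts written to", outdir, "\n")
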