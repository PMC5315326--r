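#!/usr/bin/env Rscript
# Step 3: cue interactions — conditional dependence vs linear separability.
#
# The 2x2 factorial: reward gated by AND or XOR of cues X and Y, gate
# paying 0.6 or 0.1 (A = 0.2, B = 0.4 independent). 5 training sets and
# 100 networks per cell. The question: is it the logical form of the
# interaction (XOR is linearly nonseparable, AND is not) or the sheer
# amount of conditional dependence between X and Y (reward-stratified
# chi-square sum) that predicts how badly matching degrades?
# Pass --fast for the 250-epoch profile.

suppressPackageStartupMessages(library(cuematch))

fast <- "--fast" %in% commandArgs(trailingOnly = TRUE)
cfg <- training_config(epochs = if (fast) 250 else 2500)
out_dir <- "results/sim2"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

res <- run_simulation2(sets_per_condition = 5, nets_per_set = 20,
                       config = cfg, master_seed = 56202)
write_experiment_result(res, out_dir)

cat("Mean matching R2 (SD) per cell:\n")
print(res$summary[, c("condition", "mean_matching_r2", "sd_matching_r2")])
dep <- tapply(res$sets$dependence_total, res$sets$condition, mean)
cat("\nMean X-Y conditional-dependence score per condition:\n")
print(round(dep, 2))

cat("\nTwo-way ANOVA on per-network matching R2:\n")
aov_tab <- two_way_anova(res$networks)
print(aov_tab)
write.csv(aov_tab, file.path(out_dir, "anova.csv"), row.names = FALSE)

cont <- regress_fit(res$networks$matching_r2,
                    res$networks$dependence_total)
dich <- regress_fit(res$networks$matching_r2,
                    as.numeric(res$networks$gate_kind == "xor"))
cat(sprintf(paste0(
  "\nPredicting matching R2 from:\n",
  "  conditional dependence (continuous): R2 = %.3f, F(%d,%d) = %.0f\n",
  "  AND/XOR dichotomy:                   R2 = %.3f, F(%d,%d) = %.1f\n"),
  cont$r_squared, cont$df1, cont$df2, cont$F,
  dich$r_squared, dich$df1, dich$df2, dich$F))
cat("Degree of conditional dependence, not linear separability,\n",
    "carries almost all of the predictable variance.\n")
jsonlite::write_json(
  list(continuous = cont, dichotomy = dich),
  file.path(out_dir, "dependence_regressions.json"),
  auto_unbox = TRUE, digits = NA)
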