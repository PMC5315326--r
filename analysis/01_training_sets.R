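#!/usr/bin/env Rscript
# Step 1: build and inspect the training sets.
#
# Five independent-cue sets (cues A, B, X, Y paying 0.2/0.4/0.6/0.8, 16
# configurations x 100 replicates) and one set per gate condition
# (AND/XOR x 0.6/0.1). Each set is validated configuration-by-
# configuration against its generating model and written as CSV with a
# JSON sidecar under results/training_sets/.

suppressPackageStartupMessages(library(cuematch))

out_dir <- "results/training_sets"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
master_seed <- 20260921L
seeds <- withr::with_seed(master_seed, sample.int(2^31 - 2, 9))

report <- list()
save_set <- function(ts, name) {
  write_training_set(ts, file.path(out_dir, paste0(name, ".csv")))
  v <- validate_training_set(ts)
  dep <- conditional_dependence(ts)
  report[[name]] <<- data.frame(
    set = name, configs_pass = sum(v$pass), max_chi2 = max(v$chi2),
    dependence_total = dep$total)
}

# accept/reject: with 16 tests per set at alpha = 0.05, a fresh draw often
# trips one test by chance, so redraw until a set passes everywhere
for (i in 1:5) {
  save_set(generate_valid_training_set(sim1_model(), 100, seeds[i]),
           sprintf("sim1_set%d", i))
}
save_set(generate_valid_training_set(sim2_model("and", 0.6), 100, seeds[6]),
         "and_06")
save_set(generate_valid_training_set(sim2_model("and", 0.1), 100, seeds[7]),
         "and_01")
save_set(generate_valid_training_set(sim2_model("xor", 0.6), 100, seeds[8]),
         "xor_06")
save_set(generate_valid_training_set(sim2_model("xor", 0.1), 100, seeds[9]),
         "xor_01")

report <- do.call(rbind, report)
write.csv(report, file.path(out_dir, "validation_summary.csv"),
          row.names = FALSE)
print(report, row.names = FALSE)
cat("\nAll sets validated:", all(report$configs_pass == 16), "\n")
cat("The X-Y dependence score separates the strong-gate conditions by an\n",
    "order of magnitude; note it is not zero even for independent-cue\n",
    "sets, since conditioning on the reward outcome itself induces some\n",
    "association between the cue lotteries that pay most often.\n")
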