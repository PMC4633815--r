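#!/usr/bin/env Rscript
# Type-I error calibration of the temporal cluster permutation test: the
# family-wise false-positive rate over null datasets at the nominal 0.05
# Monte-Carlo significance rule, for both white and 1/f noise.

suppressPackageStartupMessages(library(erpcue))

dir.create("results", showWarnings = FALSE)
rows <- list()
for (nz in c("white", "pink")) {
  res <- fwer_simulation(n_datasets = 500, n_subjects = 28,
                         n_samples = length(epoch_times()), n_perm = 1000,
                         threshold_p = 0.05, alpha = 0.05, seed = 20151013,
                         noise = nz)
  rows[[nz]] <- data.frame(noise = nz, fwer = res$fwer, se = res$se,
                           n_false_positive = res$n_false_positive,
                           n_datasets = res$n_datasets,
                           n_perm = res$n_perm)
  cat(sprintf("%s noise: FWER = %.4f +/- %.4f (%d/%d)\n", nz, res$fwer,
              res$se, res$n_false_positive, res$n_datasets))
}
write.table(do.call(rbind, rows), "results/fwer.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
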