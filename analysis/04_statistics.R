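#!/usr/bin/env Rscript
# Inference layer over the extracted amplitudes and ROI series: three-way
# repeated-measures ANOVA (component x category x validity), two-tailed
# post-hoc paired comparisons, and pairwise temporal cluster-based
# permutation tests (3000 permutations, cluster-forming sample p 0.05,
# Monte-Carlo significance p < 0.05).

suppressPackageStartupMessages(library(erpcue))

cfg <- validate_config("scratch/cohort/config.yaml")
montage <- synthetic_montage(cfg$n_channels)
roi <- roi_definition()
times <- epoch_times()

amp <- read.delim("results/amplitudes.tsv")
anova <- rm_anova_3way(amp)
write.table(as.data.frame(anova), "results/anova.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Three-way repeated-measures ANOVA (LSW sign-inverted):\n")
print(anova)

subjects <- sort(unique(amp$subject))
series <- list()
for (sid in subjects) {
  e <- average_epochs_by_condition(
    read_synthetic_dataset(file.path("scratch/cleaned", sid))$epochs)
  series[[sid]] <- lapply(e, roi_average, roi = roi,
                          channel_names = montage$name)
}
cue_mat <- function(cc) t(sapply(subjects, function(sid)
  (series[[sid]][[paste0("face.", cc)]] +
     series[[sid]][[paste0("flower.", cc)]]) / 2))

# post-hoc window comparisons on the amplitude table
get_amp <- function(comp, cue) {
  x <- amp[amp$component == comp & amp$cue == cue, ]
  tapply(x$amplitude_uv, x$subject, mean)[subjects]
}
ph <- list()
for (comp in c("P1", "P400", "LSW"))
  for (pr in list(c("valid", "invalid"), c("valid", "nocue"),
                  c("invalid", "nocue")))
    ph[[length(ph) + 1]] <- paired_t_two_tailed(
      get_amp(comp, pr[1]), get_amp(comp, pr[2]),
      paste0(comp, ": ", pr[1], " vs ", pr[2]))
ph <- do.call(rbind, ph)
write.table(ph, "results/posthoc.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nPost-hoc paired comparisons (LSW on the inverted scale):\n")
print(ph)

# temporal cluster tests on the cue contrasts
cl_rows <- list()
for (pr in list(c("valid", "invalid"), c("valid", "nocue"),
                c("invalid", "nocue"))) {
  res <- cluster_permutation_test(cue_mat(pr[1]), cue_mat(pr[2]),
                                  threshold_p = cfg$threshold_p,
                                  n_perm = cfg$n_permutations,
                                  seed = cfg$seed, times = times)
  d <- res$clusters
  if (nrow(d) > 0)
    cl_rows[[length(cl_rows) + 1]] <-
      cbind(contrast = paste(pr, collapse = "_vs_"), d)
}
clusters <- do.call(rbind, cl_rows)
write.table(clusters, "results/clusters.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nSignificant temporal clusters:\n")
print(clusters[clusters$significant, ])
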