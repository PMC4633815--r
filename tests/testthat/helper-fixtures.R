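# shared fixture builders; everything is generated in code at test time

make_epoch_set <- function(data, channel_names = NULL, times = epoch_times(),
                           labels = NULL) {
  n_tr <- dim(data)[1]
  if (is.null(channel_names))
    channel_names <- paste0("E", seq_len(dim(data)[2]))
  if (is.null(labels))
    labels <- data.frame(block = 1L, trial = seq_len(n_tr), cue = "nocue",
                         category = "face", duration_ms = 100,
                         lookaway = FALSE)
  structure(list(data = data, channel_names = channel_names, srate_hz = 250,
                 times = times, labels = labels, subject_id = "T01"),
            class = "epoch_set")
}

# tiny 3-electrode line montage: B sits exactly between A and C
line_montage <- function() {
  data.frame(name = c("A", "B", "C"),
             x = c(-1, 0, 1), y = 0, z = 0, stringsAsFactors = FALSE)
}

# a small cohort processed through the module chain, cached per test run
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function(n_subjects = 5, seed = 402, n_channels = 64) {
  key <- paste("cohort", n_subjects, seed, n_channels)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  montage <- synthetic_montage(n_channels)
  kspec <- erp_kernel_spec()
  nspec <- noise_artifact_spec()
  erps <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    des <- generate_session_design(design_spec(), seed = seed + 7 * s,
                                   subject_id = sid)
    eps <- simulate_subject_epochs(des, kspec, nspec, seed = seed + 7 * s + 1,
                                   montage = montage)
    pp <- run_preprocessing(eps, preproc_config(), montage)
    if (pp$qc$excluded) next
    erps[[sid]] <- average_epochs_by_condition(pp$epochs)
  }
  out <- list(erps = erps, montage = montage, channel_names = montage$name)
  .cohort_cache[[key]] <- out
  out
}

# hand-coded repeated-measures sums-of-squares oracle (all-within design):
# for each effect, the ANOVA estimate of a term T is the alternating sum of
# marginal means over subsets of T; SS multiplies by the count of collapsed
# cells; the error term is the effect x subject interaction
rm_anova_oracle <- function(d) {
  facs <- c("component", "category", "cue")
  d$subject <- factor(d$subject)
  for (f in facs) d[[f]] <- factor(d[[f]])
  lev <- vapply(c(facs, "subject"), function(f) nlevels(d[[f]]), integer(1))
  names(lev) <- c(facs, "subject")
  mean_over <- function(by) {
    if (length(by) == 0) return(mean(d$amplitude_uv))
    tapply(d$amplitude_uv, d[by], mean)
  }
  # alternating-sum effect estimate at each cell of the factors in `by`
  effect_ss <- function(by) {
    grids <- expand.grid(lapply(d[by], levels), stringsAsFactors = FALSE)
    names(grids) <- by
    est <- numeric(nrow(grids))
    subsets <- lapply(0:(2^length(by) - 1), function(m)
      by[bitwAnd(m, 2^(seq_along(by) - 1)) > 0])
    for (sub in subsets) {
      mm <- mean_over(sub)
      sgn <- (-1)^(length(by) - length(sub))
      if (length(sub) == 0) est <- est + sgn * mm
      else {
        idx <- as.matrix(grids[sub])
        est <- est + sgn * mm[idx]
      }
    }
    mult <- prod(lev[setdiff(c(facs, "subject"), by)])
    sum(mult * est^2)
  }
  out <- list()
  for (k in 1:3) for (cmb in utils::combn(facs, k, simplify = FALSE)) {
    eff <- paste(cmb, collapse = ":")
    df1 <- prod(lev[cmb] - 1)
    df2 <- df1 * (lev["subject"] - 1)
    ss_e <- effect_ss(cmb)
    ss_err <- effect_ss(c(cmb, "subject"))
    out[[eff]] <- data.frame(effect = eff, df1 = df1, df2 = unname(df2),
                             F = (ss_e / df1) / (ss_err / df2),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# balanced random amplitude table for ANOVA tests
random_amplitude_table <- function(n_subjects, seed = 1) {
  set.seed(seed)
  g <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   component = c("P1", "P400", "LSW"),
                   category = c("face", "flower"),
                   cue = c("valid", "invalid"),
                   stringsAsFactors = FALSE)
  g$amplitude_uv <- stats::rnorm(nrow(g))
  g
}
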