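#' Full pipeline configuration
#'
#' Bundles every nested specification with the cohort size, master seed and
#' statistics settings. The master seed drives a documented per-subject
#' splitting rule (`seed + 10007 * subject_index`, reduced modulo the
#' integer maximum), so runs are reproducible end to end.
#'
#' @param n_subjects cohort size (default 28)
#' @param design a [design_spec()]
#' @param kernel an [erp_kernel_spec()]
#' @param noise a [noise_artifact_spec()]
#' @param preproc a [preproc_config()]
#' @param roi a [roi_definition()]
#' @param windows data.frame as [component_windows()]
#' @param invert_lsw sign-invert the LSW for the omnibus ANOVA
#' @param threshold_p cluster-forming per-sample p (default 0.05)
#' @param n_permutations Monte-Carlo permutations (default 3000)
#' @param alpha cluster significance level (default 0.05)
#' @param seed master seed
#' @param n_channels montage size (default 128)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(n_subjects = 28,
                            design = design_spec(),
                            kernel = erp_kernel_spec(),
                            noise = noise_artifact_spec(),
                            preproc = preproc_config(),
                            roi = roi_definition(),
                            windows = component_windows(),
                            invert_lsw = TRUE,
                            threshold_p = 0.05,
                            n_permutations = 3000,
                            alpha = 0.05,
                            seed = 1,
                            n_channels = 128) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_design_spec(cfg$design)
  validate_kernel_spec(cfg$kernel)
  if (cfg$n_subjects < 2)
    stop("pipeline_config: `n_subjects` must be >= 2", call. = FALSE)
  if (cfg$threshold_p <= 0 || cfg$threshold_p >= 1)
    stop("pipeline_config: `threshold_p` must lie in (0, 1)", call. = FALSE)
  cfg
}

#' Load and validate a pipeline configuration from YAML
#'
#' Reads a (possibly partial) YAML file; recognised keys override the
#' defaults, which carry all the study constants (250 Hz, 0.2-20 Hz band,
#' +/-400 uV and +/-120 uV thresholds, 35% trial rule, nine-electrode ROI,
#' the three component windows, 3000 permutations at threshold p 0.05).
#' Nested blocks `design`, `kernel`, `noise`, `preproc` take the matching
#' constructor arguments. Errors name the offending key path.
#'
#' @param path YAML file
#' @return a validated [pipeline_config()]
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_nested <- function(block, ctor, path_name) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    known <- names(formals(ctor))
    bad <- setdiff(names(args), known)
    if (length(bad) > 0)
      stop("validate_config: unknown key(s) ", path_name, ".",
           paste(bad, collapse = paste0(", ", path_name, ".")),
           call. = FALSE)
    tryCatch(do.call(ctor, args),
             error = function(e) stop("validate_config: in `", path_name,
                                      "`: ", conditionMessage(e),
                                      call. = FALSE))
  }
  top <- c("n_subjects", "invert_lsw", "threshold_p", "n_permutations",
           "alpha", "seed", "n_channels")
  bad <- setdiff(names(raw),
                 c(top, "design", "kernel", "noise", "preproc", "roi"))
  if (length(bad) > 0)
    stop("validate_config: unknown top-level key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  args <- raw[top[top %in% names(raw)]]
  args$design <- build_nested("design", design_spec, "design")
  args$kernel <- build_nested("kernel", erp_kernel_spec, "kernel")
  args$noise <- build_nested("noise", noise_artifact_spec, "noise")
  args$preproc <- build_nested("preproc", preproc_config, "preproc")
  if (!is.null(raw$roi)) args$roi <- roi_definition(unlist(raw$roi))
  do.call(pipeline_config, args)
}

#' Serialize a pipeline configuration to YAML
#'
#' Round-trips through [validate_config()].
#' @param config a [pipeline_config()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  out <- list(
    n_subjects = config$n_subjects,
    invert_lsw = config$invert_lsw,
    threshold_p = config$threshold_p,
    n_permutations = config$n_permutations,
    alpha = config$alpha,
    seed = config$seed,
    n_channels = config$n_channels,
    design = unclass(config$design),
    kernel = unclass(config$kernel),
    noise = unclass(config$noise),
    preproc = unclass(config$preproc),
    roi = config$roi$names
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run the full simulate-preprocess-extract-test pipeline
#'
#' For each subject: generate a session design, simulate epoched EEG, run
#' the preprocessing chain, average per condition, and keep the ROI series
#' and window amplitudes. Subjects without at least two surviving trials in
#' every one of the six conditions are excluded (and logged). The group
#' stage then runs the three-way repeated-measures ANOVA, the post-hoc
#' paired comparisons (per component: valid/invalid, valid/no-cue,
#' invalid/no-cue, and face/flower collapsed over cues), and the pairwise
#' temporal cluster permutation tests on the ROI series (cue contrasts
#' collapsed over category, plus face vs flower).
#'
#' @param config a [pipeline_config()]
#' @param verbose print progress
#' @return object of class `run_report`: list with `config`, `qc` (one
#'   `qc_report` per subject), `excluded_subjects`, `amplitude_table`,
#'   `grand_averages` (per-condition mean ROI series across subjects),
#'   `anova`, `posthoc` (data.frame), `cluster_tests` (named list of
#'   `cluster_test_result`), `times`
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  montage <- synthetic_montage(config$n_channels)
  times <- epoch_times()
  conds <- c("face.valid", "face.nocue", "face.invalid",
             "flower.valid", "flower.nocue", "flower.invalid")

  qc <- list()
  erps_by_subject <- list()
  roi_series <- list()  # subject -> condition -> ROI series
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    des <- generate_session_design(config$design,
                                   seed = subject_seed(config$seed, s),
                                   subject_id = sid)
    eps <- simulate_subject_epochs(des, config$kernel, config$noise,
                                   seed = subject_seed(config$seed, s) + 1L,
                                   montage = montage)
    pp <- run_preprocessing(eps, config$preproc, montage)
    qc[[sid]] <- pp$qc
    if (pp$qc$excluded) {
      if (verbose) message(sid, ": excluded (<2 trials in some condition)")
      next
    }
    erps <- average_epochs_by_condition(pp$epochs)
    erps_by_subject[[sid]] <- erps
    roi_series[[sid]] <- lapply(erps, roi_average, roi = config$roi,
                                channel_names = montage$name)
    if (verbose) message(sid, ": ", pp$qc$n_surviving, " surviving trials")
  }
  excluded <- names(qc)[vapply(qc, function(q) q$excluded, logical(1))]
  if (length(erps_by_subject) < 2)
    stop("run_pipeline: fewer than 2 includable subjects", call. = FALSE)

  amp <- build_amplitude_table(erps_by_subject, config$roi, montage$name,
                               config$windows, config$invert_lsw, times)
  anova <- rm_anova_3way(amp)

  subjects <- names(erps_by_subject)
  # subject x samples matrices per cue condition (mean of face/flower ROI
  # series) and per category (mean over cues)
  cue_mat <- function(cc) t(vapply(subjects, function(sid)
    (roi_series[[sid]][[paste0("face.", cc)]] +
       roi_series[[sid]][[paste0("flower.", cc)]]) / 2, numeric(length(times))))
  cat_mat <- function(cat) t(vapply(subjects, function(sid)
    Reduce(`+`, roi_series[[sid]][paste0(cat, c(".valid", ".nocue",
                                                ".invalid"))]) / 3,
    numeric(length(times))))
  mats <- list(valid = cue_mat("valid"), nocue = cue_mat("nocue"),
               invalid = cue_mat("invalid"),
               face = cat_mat("face"), flower = cat_mat("flower"))

  # post-hoc window comparisons
  posthoc <- list()
  amp_raw <- amp
  if (config$invert_lsw) {
    flip <- amp_raw$component == "LSW"
    amp_raw$amplitude_uv[flip] <- -amp_raw$amplitude_uv[flip]
  }
  get_amp <- function(comp, cue = NULL, category = NULL, inverted = TRUE) {
    a <- if (inverted) amp else amp_raw
    sel <- a$component == comp
    if (!is.null(cue)) sel <- sel & a$cue == cue
    if (!is.null(category)) sel <- sel & a$category == category
    x <- a[sel, ]
    # average over the collapsed factor within subject
    tapply(x$amplitude_uv, x$subject, mean)[subjects]
  }
  for (comp in config$windows$component) {
    for (pr in list(c("valid", "invalid"), c("valid", "nocue"),
                    c("invalid", "nocue"))) {
      posthoc[[length(posthoc) + 1]] <- paired_t_two_tailed(
        get_amp(comp, cue = pr[1]), get_amp(comp, cue = pr[2]),
        label = paste0(comp, ": ", pr[1], " vs ", pr[2]))
    }
    posthoc[[length(posthoc) + 1]] <- paired_t_two_tailed(
      get_amp(comp, category = "face"), get_amp(comp, category = "flower"),
      label = paste0(comp, ": face vs flower"))
  }
  posthoc <- do.call(rbind, posthoc)
  attr(posthoc, "sign_inverted_lsw") <- config$invert_lsw

  # pairwise temporal cluster tests
  contrasts <- list(valid_vs_invalid = c("valid", "invalid"),
                    valid_vs_nocue = c("valid", "nocue"),
                    invalid_vs_nocue = c("invalid", "nocue"),
                    face_vs_flower = c("face", "flower"))
  cluster_tests <- lapply(contrasts, function(pr)
    cluster_permutation_test(mats[[pr[1]]], mats[[pr[2]]],
                             threshold_p = config$threshold_p,
                             n_perm = config$n_permutations,
                             seed = config$seed, alpha = config$alpha,
                             times = times))

  grand <- lapply(conds, function(cc)
    colMeans(t(vapply(subjects, function(sid) roi_series[[sid]][[cc]],
                      numeric(length(times))))))
  names(grand) <- conds

  structure(list(config = config, qc = qc, excluded_subjects = excluded,
                 amplitude_table = amp, grand_averages = grand,
                 anova = anova, posthoc = posthoc,
                 cluster_tests = cluster_tests, times = times,
                 version = as.character(utils::packageVersion("erpcue"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", length(x$qc), "subjects simulated,",
      length(x$excluded_subjects), "excluded\n")
  cat("\nThree-way repeated-measures ANOVA",
      "(component x category x validity):\n")
  print(x$anova)
  cat("\nPost-hoc paired comparisons:\n")
  print(x$posthoc)
  cat("\nCluster tests:\n")
  for (nm in names(x$cluster_tests)) {
    cl <- x$cluster_tests[[nm]]$clusters
    sig <- cl[cl$significant, , drop = FALSE]
    cat("  ", nm, ": ", nrow(sig), " significant cluster(s)",
        if (nrow(sig) > 0) paste0(" [",
          paste(sprintf("%d-%d ms (p=%.4f)", sig$start_ms, sig$end_ms,
                        sig$p), collapse = "; "), "]"), "\n", sep = "")
  }
  invisible(x)
}

#' Write the tabular pieces of a run report to TSV files
#'
#' Writes `amplitudes.tsv`, `anova.tsv`, `posthoc.tsv`, `clusters.tsv`,
#' `qc.tsv` and a `config.yaml` snapshot into `dir`.
#'
#' @param report a `run_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                         row.names = FALSE, quote = FALSE)
  w(report$amplitude_table, "amplitudes.tsv")
  w(as.data.frame(report$anova), "anova.tsv")
  w(as.data.frame(report$posthoc), "posthoc.tsv")
  cl <- do.call(rbind, lapply(names(report$cluster_tests), function(nm) {
    d <- report$cluster_tests[[nm]]$clusters
    if (nrow(d) == 0) return(NULL)
    cbind(contrast = nm, d)
  }))
  if (is.null(cl))
    cl <- data.frame(contrast = character(0), start = integer(0),
                     end = integer(0), sign = integer(0), sum_t = numeric(0),
                     p = numeric(0), significant = logical(0))
  w(cl, "clusters.tsv")
  qc <- do.call(rbind, lapply(names(report$qc), function(sid) {
    q <- report$qc[[sid]]
    data.frame(subject = sid, n_generated = q$n_generated,
               n_lookaway = q$n_lookaway_rejected,
               n_artifact_rejected = q$n_trials_rejected,
               n_surviving = q$n_surviving,
               t(q$surviving_per_condition), excluded = q$excluded)
  }))
  w(qc, "qc.tsv")
  write_config(report$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
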