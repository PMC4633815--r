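#' Three-way repeated-measures ANOVA on component amplitudes
#'
#' Omnibus test of component (P1/P400/LSW) x target category (face/flower)
#' x cue validity (valid/invalid) on the subject-level window-mean
#' amplitudes, all three factors within-subject. The table is expected to
#' carry sign-inverted LSW values so the negative component is comparable
#' with the positive ones. Classical (uncorrected) F tests by default —
#' with n subjects the component main effect has df (2, 2(n-1)) —
#' with optional Greenhouse-Geisser correction of the p values.
#'
#' No-cue rows, if present, are dropped: validity contrasts valid against
#' invalid.
#'
#' @param table amplitude data.frame from [build_amplitude_table()]
#' @param sphericity `"none"` (classical F) or `"GG"` (Greenhouse-Geisser
#'   corrected p values)
#' @return data.frame of class `anova_result`: one row per effect with
#'   `effect`, `df1`, `df2`, `F`, `p` (and `eps`, `p_gg` under `"GG"`)
#' @export
rm_anova_3way <- function(table, sphericity = c("none", "GG")) {
  sphericity <- match.arg(sphericity)
  d <- table[table$cue %in% c("valid", "invalid"), ]
  d$subject <- factor(d$subject)
  d$component <- factor(d$component, levels = c("P1", "P400", "LSW"))
  d$category <- factor(d$category)
  d$cue <- factor(d$cue)
  full <- expand.grid(subject = levels(d$subject),
                      component = levels(d$component),
                      category = levels(d$category), cue = levels(d$cue))
  have <- paste(d$subject, d$component, d$category, d$cue)
  want <- paste(full$subject, full$component, full$category, full$cue)
  if (any(!(want %in% have))) {
    miss <- full[!(want %in% have), ]
    stop("rm_anova_3way: missing cells: ",
         paste(utils::head(paste(miss$subject, miss$component, miss$category,
                                 miss$cue, sep = "/"), 5), collapse = ", "),
         if (sum(!(want %in% have)) > 5) " ...", call. = FALSE)
  }
  if (nrow(d) != nrow(full))
    stop("rm_anova_3way: expected one row per subject x component x ",
         "category x cue cell", call. = FALSE)

  fit <- stats::aov(amplitude_uv ~ component * category * cue +
                      Error(subject / (component * category * cue)),
                    data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    effs <- trimws(rownames(tab))
    for (i in seq_along(effs)) {
      if (effs[i] == "Residuals") next
      rows[[length(rows) + 1]] <- data.frame(
        effect = gsub("cue", "validity", effs[i]),
        df1 = tab$Df[i],
        df2 = tab$Df[effs == "Residuals"],
        F = tab$`F value`[i],
        p = tab$`Pr(>F)`[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (sphericity == "GG") {
    out$eps <- NA_real_
    out$p_gg <- out$p
    for (i in seq_len(nrow(out))) {
      if (out$df1[i] < 2) { out$eps[i] <- 1; next }
      eps <- gg_epsilon(d, out$effect[i])
      out$eps[i] <- eps
      out$p_gg[i] <- stats::pf(out$F[i], eps * out$df1[i], eps * out$df2[i],
                               lower.tail = FALSE)
    }
  }
  attr(out, "sphericity") <- sphericity
  class(out) <- c("anova_result", "data.frame")
  out
}

# Greenhouse-Geisser epsilon for a within-subject effect: computed from the
# covariance of the subject-level contrast scores for that effect
gg_epsilon <- function(d, effect) {
  facs <- strsplit(gsub("validity", "cue", effect), ":")[[1]]
  cellf <- interaction(d[facs], drop = TRUE, sep = ":")
  # subject x cell matrix of scores averaged over the other factors
  m <- tapply(d$amplitude_uv, list(d$subject, cellf), mean)
  k <- ncol(m)
  # effect contrast space: successive differences per factor, crossed
  cmat <- Reduce(kronecker, lapply(facs, function(f) {
    l <- nlevels(factor(d[[f]]))
    diff(diag(l))
  }))
  # align contrast columns with cell order (expand.grid ordering)
  lev <- lapply(facs, function(f) levels(factor(d[[f]])))
  cells <- do.call(expand.grid, rev(lev))[, rev(seq_along(facs)), drop = FALSE]
  names(cells) <- facs
  key <- apply(cells, 1, paste, collapse = ":")
  scores <- m[, match(key, colnames(m)), drop = FALSE] %*% t(cmat)
  S <- stats::cov(scores)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  sum(ev)^2 / (length(ev) * sum(ev^2))
}

#' Two-tailed paired t test
#'
#' Classical paired t on per-subject differences; df = n - 1.
#'
#' @param a,b per-subject values (same subjects, same order)
#' @param label contrast label carried in the result
#' @return data.frame of class `posthoc_result`: `contrast`, `t`, `df`,
#'   `p`, `mean_diff`
#' @export
paired_t_two_tailed <- function(a, b, label = "a vs b") {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate difference vector: identical pairs give t = 0, p = 1; a
    # constant nonzero shift is infinitely significant
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    res <- data.frame(contrast = label, t = t, df = length(a) - 1,
                      p = if (mean(d) == 0) 1 else 0, mean_diff = mean(d),
                      stringsAsFactors = FALSE)
    return(structure(res, class = c("posthoc_result", "data.frame")))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(data.frame(contrast = label,
                       t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value, mean_diff = unname(tt$estimate),
                       stringsAsFactors = FALSE),
            class = c("posthoc_result", "data.frame"))
}

# per-sample paired t statistics from a subjects x samples difference matrix;
# zero-variance samples get t = 0 (conservative: they cannot enter a cluster)
tseries_from_diffs <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  t <- ifelse(v <= 1e-24, 0, m / sqrt(v / n))
  t
}

# maximal runs of consecutive supra-threshold samples, positive and negative
# t handled as separate signed clusters
find_clusters <- function(tseries, t_thresh) {
  state <- ifelse(tseries > t_thresh, 1L, ifelse(tseries < -t_thresh, -1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  if (length(keep) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      sign = integer(0), sum_t = numeric(0)))
  data.frame(
    start = starts[keep], end = ends[keep], sign = r$values[keep],
    sum_t = vapply(keep, function(k)
      sum(tseries[starts[k]:ends[k]]), numeric(1)))
}

# max |cluster sum| for each row of a permutations x samples t matrix
null_max_stats <- function(tmat, t_thresh) {
  apply(tmat, 1, function(ts) {
    cl <- find_clusters(ts, t_thresh)
    if (nrow(cl) == 0) 0 else max(abs(cl$sum_t))
  })
}

# t matrix for a signs (n_perm x n) x diffs (n x samples) pair; exploits the
# fact that sign flips leave per-sample sums of squares unchanged
perm_t_matrix <- function(S, D) {
  n <- ncol(S)
  M <- (S %*% D) / n
  ss <- colSums(D^2)
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  V[V < 1e-24] <- Inf  # zero-variance -> t = 0
  M / sqrt(V / n)
}

#' Temporal cluster-based permutation test
#'
#' Paired two-condition test over a time series with family-wise error
#' control by the max-statistic permutation method. Per-sample paired t
#' statistics are thresholded at the two-tailed critical value for
#' `threshold_p`; maximal runs of consecutive supra-threshold samples form
#' clusters (positive and negative t separately), each scored by the sum of
#' its t values. The null distribution is the maximum absolute cluster
#' statistic over random within-subject condition relabelings — implemented
#' as sign flips of the per-subject difference series, which is equivalent
#' for a paired design. The Monte-Carlo p of a cluster is N/n_perm, the
#' fraction of null maxima at least as large (in absolute value) as the
#' observed statistic; a cluster is significant when p < `alpha`.
#'
#' @param condA,condB subjects x samples matrices (same subjects, same order)
#' @param threshold_p cluster-forming per-sample two-tailed p (default 0.05)
#' @param n_perm number of random permutations (default 3000)
#' @param seed RNG seed for the permutation draws
#' @param alpha cluster significance level on the Monte-Carlo p (0.05)
#' @param times optional time axis (ms) to report cluster extents in ms
#' @return object of class `cluster_test_result`: list with `tseries`,
#'   `t_thresh`, `clusters` (data.frame: `start`, `end`, `sign`, `sum_t`,
#'   `p`, `significant`, and ms extents when `times` given), `n_perm`,
#'   `threshold_p`, `seed`, `method = "montecarlo"`
#' @export
cluster_permutation_test <- function(condA, condB, threshold_p = 0.05,
                                     n_perm = 3000, seed = 1, alpha = 0.05,
                                     times = NULL) {
  stopifnot(all(dim(condA) == dim(condB)), n_perm >= 1)
  n <- nrow(condA)
  if (n < 2)
    stop("cluster_permutation_test: need at least 2 subjects", call. = FALSE)
  D <- condA - condB
  t_thresh <- stats::qt(1 - threshold_p / 2, df = n - 1)
  tseries <- tseries_from_diffs(D)
  clusters <- find_clusters(tseries, t_thresh)

  if (nrow(clusters) > 0) {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    tmat <- perm_t_matrix(S, D)
    nullmax <- null_max_stats(tmat, t_thresh)
    clusters$p <- vapply(clusters$sum_t, function(s)
      sum(nullmax >= abs(s)) / n_perm, numeric(1))
    clusters$significant <- clusters$p < alpha
  } else {
    clusters$p <- numeric(0)
    clusters$significant <- logical(0)
  }
  if (!is.null(times) && nrow(clusters) > 0) {
    clusters$start_ms <- times[clusters$start]
    clusters$end_ms <- times[clusters$end]
  }
  structure(list(tseries = tseries, t_thresh = t_thresh, clusters = clusters,
                 n_perm = n_perm, threshold_p = threshold_p, seed = seed,
                 alpha = alpha, method = "montecarlo"),
            class = "cluster_test_result")
}

#' Exact (enumerated) cluster permutation test
#'
#' Ground-truth variant for small samples: enumerates all `2^n` sign
#' assignments of the per-subject difference series, so cluster p values
#' are exact permutation probabilities (multiples of `2^-n`). Used as the
#' oracle against which the Monte-Carlo implementation is checked.
#'
#' @param condA,condB subjects x samples matrices
#' @param threshold_p cluster-forming per-sample two-tailed p
#' @param alpha cluster significance level
#' @param times optional time axis in ms
#' @return a `cluster_test_result` with `method = "exact"` and
#'   `n_perm = 2^n`
#' @export
cluster_test_exact <- function(condA, condB, threshold_p = 0.05,
                               alpha = 0.05, times = NULL) {
  stopifnot(all(dim(condA) == dim(condB)))
  n <- nrow(condA)
  if (n < 2) stop("cluster_test_exact: need at least 2 subjects",
                  call. = FALSE)
  if (n > 14)
    stop("cluster_test_exact: enumeration limited to n <= 14 subjects (",
         2^n, " sign patterns)", call. = FALSE)
  D <- condA - condB
  t_thresh <- stats::qt(1 - threshold_p / 2, df = n - 1)
  tseries <- tseries_from_diffs(D)
  clusters <- find_clusters(tseries, t_thresh)

  n_all <- 2^n
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tmat <- perm_t_matrix(S, D)
  nullmax <- null_max_stats(tmat, t_thresh)
  if (nrow(clusters) > 0) {
    clusters$p <- vapply(clusters$sum_t, function(s)
      sum(nullmax >= abs(s)) / n_all, numeric(1))
    clusters$significant <- clusters$p < alpha
  } else {
    clusters$p <- numeric(0)
    clusters$significant <- logical(0)
  }
  if (!is.null(times) && nrow(clusters) > 0) {
    clusters$start_ms <- times[clusters$start]
    clusters$end_ms <- times[clusters$end]
  }
  structure(list(tseries = tseries, t_thresh = t_thresh, clusters = clusters,
                 n_perm = n_all, threshold_p = threshold_p, seed = NA,
                 alpha = alpha, method = "exact"),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("cluster_test_result (", x$method, ", ", x$n_perm, " permutations, ",
      "cluster-forming p = ", x$threshold_p, ")\n", sep = "")
  if (nrow(x$clusters) == 0) cat("  no supra-threshold clusters\n")
  else print(x$clusters)
  invisible(x)
}

#' Family-wise error-rate simulation for the cluster test
#'
#' Monte-Carlo calibration check: simulates null datasets (both conditions
#' drawn from the same noise process), runs the cluster permutation test on
#' each, and reports the fraction of datasets with at least one cluster
#' significant at `alpha` — the empirical family-wise false-positive rate —
#' with a binomial standard error.
#'
#' @param n_datasets number of null datasets
#' @param n_subjects subjects per dataset
#' @param n_samples samples per series
#' @param n_perm permutations per test
#' @param threshold_p cluster-forming per-sample p
#' @param alpha cluster significance level
#' @param seed master RNG seed
#' @param noise `"white"` (iid Gaussian) or `"pink"` (1/f-shaped Gaussian)
#' @return list with `fwer`, `se` (binomial), `n_false_positive`,
#'   `n_datasets` and the settings used
#' @export
fwer_simulation <- function(n_datasets = 500, n_subjects = 28,
                            n_samples = 462, n_perm = 1000,
                            threshold_p = 0.05, alpha = 0.05, seed = 1,
                            noise = c("white", "pink")) {
  noise <- match.arg(noise)
  set.seed(seed)
  hits <- logical(n_datasets)
  for (i in seq_len(n_datasets)) {
    gen <- function() {
      if (noise == "white")
        matrix(stats::rnorm(n_subjects * n_samples), n_subjects, n_samples)
      else
        pink_noise(n_subjects, n_samples, rms_uv = 1, exponent = 1)
    }
    res <- cluster_permutation_test(gen(), gen(), threshold_p = threshold_p,
                                    n_perm = n_perm,
                                    seed = sample.int(2^30, 1),
                                    alpha = alpha)
    hits[i] <- any(res$clusters$significant)
  }
  fwer <- mean(hits)
  list(fwer = fwer, se = sqrt(fwer * (1 - fwer) / n_datasets),
       n_false_positive = sum(hits), n_datasets = n_datasets,
       n_subjects = n_subjects, n_samples = n_samples, n_perm = n_perm,
       threshold_p = threshold_p, alpha = alpha, seed = seed, noise = noise)
}
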