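#' Experimental design specification
#'
#' Describes the probabilistic trial structure of the cross-modal cueing
#' session: one third of test trials carry no auditory cue; on cued trials
#' the cue predicts its associated visual category 75% of the time (valid)
#' and the other category 25% of the time (invalid). Target durations
#' (66/100/133 ms) are balanced within each block of nine trials. Timeline
#' constants: forward mask 1000 ms; the cue starts 500 ms after forward-mask
#' onset and plays for 250 ms; the target therefore follows cue onset by
#' 500 ms; the backward mask lasts `backward_mask_total_ms` minus the target
#' duration, so mask + target span a constant.
#'
#' @param p_nocue probability of a no-cue trial (default 1/3)
#' @param p_valid_given_cued probability that a cued trial is valid (0.75)
#' @param block_size test trials per block (default 9)
#' @param n_blocks number of test blocks (default 10)
#' @param durations_ms target durations in ms (default 66, 100, 133)
#' @param per_block_duration_balance if TRUE, each block holds
#'   `block_size / length(durations_ms)` trials of each duration
#' @param counterbalance_arm `"soundA_faces"` or `"soundA_flowers"`: which
#'   physical sound is associated with faces
#' @param familiarization_trials number of familiarization trials (default 10)
#' @param allocation `"exact"` (condition counts fixed per session, order
#'   shuffled) or `"iid"` (independent draws per trial)
#' @param forward_mask_ms,cue_onset_after_mask_onset_ms,cue_duration_ms,
#'   backward_mask_total_ms,interblock_interval_ms,feedback_duration_ms
#'   timeline constants in ms
#' @return a validated object of class `design_spec`
#' @export
design_spec <- function(p_nocue = 1 / 3,
                        p_valid_given_cued = 0.75,
                        block_size = 9L,
                        n_blocks = 10L,
                        durations_ms = c(66, 100, 133),
                        per_block_duration_balance = TRUE,
                        counterbalance_arm = c("soundA_faces", "soundA_flowers"),
                        familiarization_trials = 10L,
                        allocation = c("exact", "iid"),
                        forward_mask_ms = 1000,
                        cue_onset_after_mask_onset_ms = 500,
                        cue_duration_ms = 250,
                        backward_mask_total_ms = 1800,
                        interblock_interval_ms = 1500,
                        feedback_duration_ms = 3000) {
  counterbalance_arm <- match.arg(counterbalance_arm)
  allocation <- match.arg(allocation)
  spec <- list(
    p_nocue = p_nocue,
    p_valid_given_cued = p_valid_given_cued,
    block_size = as.integer(block_size),
    n_blocks = as.integer(n_blocks),
    durations_ms = durations_ms,
    per_block_duration_balance = isTRUE(per_block_duration_balance),
    counterbalance_arm = counterbalance_arm,
    familiarization_trials = as.integer(familiarization_trials),
    allocation = allocation,
    forward_mask_ms = forward_mask_ms,
    cue_onset_after_mask_onset_ms = cue_onset_after_mask_onset_ms,
    cue_duration_ms = cue_duration_ms,
    backward_mask_total_ms = backward_mask_total_ms,
    interblock_interval_ms = interblock_interval_ms,
    feedback_duration_ms = feedback_duration_ms
  )
  class(spec) <- "design_spec"
  validate_design_spec(spec)
  spec
}

validate_design_spec <- function(spec) {
  chk_prob <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      stop("design_spec: `", nm, "` must be a probability in [0, 1]",
           call. = FALSE)
  }
  chk_prob(spec$p_nocue, "p_nocue")
  chk_prob(spec$p_valid_given_cued, "p_valid_given_cued")
  if (spec$block_size < 1) stop("design_spec: `block_size` must be >= 1",
                                call. = FALSE)
  if (spec$n_blocks < 1) stop("design_spec: `n_blocks` must be >= 1",
                              call. = FALSE)
  if (any(spec$durations_ms <= 0))
    stop("design_spec: `durations_ms` must all be positive", call. = FALSE)
  if (spec$per_block_duration_balance &&
      spec$block_size %% length(spec$durations_ms) != 0)
    stop("design_spec: `block_size` must be divisible by the number of ",
         "durations when per-block balance is on", call. = FALSE)
  invisible(spec)
}

# sound associated with each visual category under the counterbalance arm
cue_sound_for <- function(category, arm) {
  if (arm == "soundA_faces") ifelse(category == "face", "A", "B")
  else ifelse(category == "face", "B", "A")
}

#' Generate one session's trial sequence
#'
#' Draws a full test-phase trial list honouring the design probabilities.
#' In `"exact"` allocation mode the per-condition counts are fixed to the
#' rounded expectations for the session and only the order is randomized
#' (stabilising small sessions); in `"iid"` mode each trial's cue condition
#' and category are drawn independently. Target durations are balanced
#' within each block when the balance flag is on. A familiarization phase of
#' alternating face/flower trials precedes the test blocks.
#'
#' @param spec a [design_spec()]
#' @param seed integer RNG seed; identical seeds give identical sessions
#' @param subject_id identifier stored with the design
#' @return object of class `session_design`: list with `subject_id`, `spec`,
#'   `seed`, `familiarization` (data.frame) and `trials` (data.frame with
#'   columns `block`, `trial`, `cue`, `category`, `duration_ms`, `cue_sound`,
#'   plus onset columns filled by [build_trial_timeline()])
#' @export
generate_session_design <- function(spec, seed, subject_id = "S01") {
  validate_design_spec(spec)
  n <- spec$block_size * spec$n_blocks
  set.seed(seed)

  if (spec$allocation == "exact") {
    n_nocue <- round(n * spec$p_nocue)
    n_cued <- n - n_nocue
    n_valid <- round(n_cued * spec$p_valid_given_cued)
    n_invalid <- n_cued - n_valid
    cue <- sample(rep(c("nocue", "valid", "invalid"),
                      c(n_nocue, n_valid, n_invalid)))
    # categories balanced within each cue condition (split as evenly as the
    # count allows, remainder assigned at random)
    category <- character(n)
    for (cc in c("nocue", "valid", "invalid")) {
      idx <- which(cue == cc)
      m <- length(idx)
      cats <- rep(c("face", "flower"), c(m %/% 2, m %/% 2))
      if (m %% 2) cats <- c(cats, sample(c("face", "flower"), 1))
      category[idx] <- sample(cats)
    }
  } else {
    cue <- ifelse(stats::runif(n) < spec$p_nocue, "nocue",
                  ifelse(stats::runif(n) < spec$p_valid_given_cued,
                         "valid", "invalid"))
    category <- sample(c("face", "flower"), n, replace = TRUE)
  }

  # per-block duration assignment
  durs <- numeric(n)
  for (b in seq_len(spec$n_blocks)) {
    idx <- (b - 1) * spec$block_size + seq_len(spec$block_size)
    if (spec$per_block_duration_balance) {
      reps <- spec$block_size / length(spec$durations_ms)
      durs[idx] <- sample(rep(spec$durations_ms, reps))
    } else {
      durs[idx] <- sample(spec$durations_ms, spec$block_size, replace = TRUE)
    }
  }

  trials <- data.frame(
    block = rep(seq_len(spec$n_blocks), each = spec$block_size),
    trial = seq_len(n),
    cue = cue,
    category = category,
    duration_ms = durs,
    stringsAsFactors = FALSE
  )
  # the physical sound on cued trials: the associated sound of the predicted
  # category (valid: target's own; invalid: the other category's sound)
  predicted <- ifelse(trials$cue == "valid", trials$category,
                      ifelse(trials$cue == "invalid",
                             ifelse(trials$category == "face", "flower", "face"),
                             NA_character_))
  trials$cue_sound <- ifelse(is.na(predicted), "none",
                             cue_sound_for(predicted, spec$counterbalance_arm))
  trials <- build_trial_timeline(trials, spec)

  fam <- data.frame(
    trial = seq_len(spec$familiarization_trials),
    category = rep(c("face", "flower"),
                   length.out = spec$familiarization_trials),
    stringsAsFactors = FALSE
  )
  fam$cue_sound <- cue_sound_for(fam$category, spec$counterbalance_arm)

  structure(list(subject_id = subject_id, spec = spec, seed = seed,
                 familiarization = fam, trials = trials),
            class = "session_design")
}

#' Fill within-trial event onsets
#'
#' Each test trial runs: forward mask (1000 ms) -> target (66/100/133 ms)
#' -> backward mask. On cued trials the 250 ms auditory cue starts 500 ms
#' after forward-mask onset, i.e. 500 ms before target onset. Onsets are in
#' ms from trial start; no-cue trials have `NA` cue onset.
#'
#' @param trials data.frame with `cue` and `duration_ms` columns
#' @param spec a [design_spec()]
#' @return `trials` with onset columns `onset_forward_mask`, `onset_cue`,
#'   `onset_target`, `onset_backward_mask` and `trial_span_ms`
#' @export
build_trial_timeline <- function(trials, spec) {
  trials$onset_forward_mask <- 0
  trials$onset_cue <- ifelse(trials$cue == "nocue", NA_real_,
                             spec$cue_onset_after_mask_onset_ms)
  trials$onset_target <- spec$forward_mask_ms
  trials$onset_backward_mask <- spec$forward_mask_ms + trials$duration_ms
  # backward mask lasts the configured mask+target span minus target duration
  trials$trial_span_ms <- spec$forward_mask_ms + spec$backward_mask_total_ms
  trials
}

#' @export
print.session_design <- function(x, ...) {
  cat("session_design:", x$subject_id, "\n")
  cat("  ", nrow(x$trials), "test trials in", x$spec$n_blocks, "blocks of",
      x$spec$block_size, "(allocation:", x$spec$allocation, ")\n")
  print(table(cue = x$trials$cue))
  invisible(x)
}

#' Condition label for a trial set
#'
#' Combines category and cue into the six analysis conditions
#' (e.g. `"face.valid"`).
#' @param labels data.frame with `category` and `cue` columns
#' @return character vector
#' @export
condition_label <- function(labels) {
  paste(labels$category, labels$cue, sep = ".")
}
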