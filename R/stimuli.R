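#' Grating stimulus sets for the triangle discrimination task
#'
#' A stimulus set holds the spatial frequency of the fixed standard grating
#' and two ordered pools of comparison gratings: four *more coarse* textures
#' (frequencies below the standard, i.e. wider gratings) and four *less
#' coarse* textures (frequencies above the standard). Frequencies are in
#' cycles per meter (m^-1).
#'
#' The constructor validates ordering and positivity. Sets whose standard
#' frequency is not the mean of the eight comparison frequencies, or whose
#' within-side spacing is uneven, are accepted (adaptive training sets are
#' such sets) but trigger a warning unless `check = FALSE`.
#'
#' @param standard spatial frequency of the standard grating (m^-1).
#' @param more_coarse increasing vector of comparison frequencies below the
#'   standard (m^-1).
#' @param less_coarse increasing vector of comparison frequencies above the
#'   standard (m^-1).
#' @param check warn when the set deviates from the balanced default
#'   structure (standard = mean of comparisons, constant spacing).
#' @return An object of class `stimulus_set`.
#' @seealso [default_stimulus_set()], [adapt_training_set()]
#' @export
stimulus_set <- function(standard, more_coarse, less_coarse, check = TRUE) {
  stop_if_not_positive(standard, "standard")
  stop_if_not_positive(more_coarse, "more_coarse")
  stop_if_not_positive(less_coarse, "less_coarse")
  if (any(diff(more_coarse) <= 0) || any(diff(less_coarse) <= 0))
    stop("comparison frequencies must be strictly increasing within each side")
  if (any(more_coarse >= standard) || any(less_coarse <= standard))
    stop("more_coarse must lie below and less_coarse above the standard frequency")
  if (isTRUE(check)) {
    comp <- c(more_coarse, less_coarse)
    if (abs(mean(comp) - standard) > 1e-9 * standard)
      warning("standard frequency is not the mean of the comparison frequencies")
    sp <- c(diff(more_coarse), diff(less_coarse))
    if (length(sp) > 1 && diff(range(sp)) > 1e-9 * standard)
      warning("comparison spacing is not constant within sides")
  }
  structure(
    list(standard = as.numeric(standard),
         more_coarse = as.numeric(more_coarse),
         less_coarse = as.numeric(less_coarse)),
    class = "stimulus_set")
}

#' Default experimental stimulus set
#'
#' Standard grating at 164 m^-1; more coarse comparisons
#' \{100, 116, 132, 148\} m^-1 and less coarse comparisons
#' \{180, 196, 212, 228\} m^-1, i.e. 16 m^-1 spacing on each side with the
#' standard equal to the mean of all eight comparisons.
#'
#' @return A `stimulus_set`.
#' @examples
#' s <- default_stimulus_set()
#' spatial_period(s$standard)
#' @export
default_stimulus_set <- function() {
  stimulus_set(164, c(100, 116, 132, 148), c(180, 196, 212, 228))
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Grating stimulus set (m^-1)\n")
  cat("  standard:   ", format(x$standard), "\n")
  cat("  more coarse:", paste(format(x$more_coarse), collapse = " "), "\n")
  cat("  less coarse:", paste(format(x$less_coarse), collapse = " "), "\n")
  invisible(x)
}

#' All comparison frequencies of a set
#'
#' @param set a `stimulus_set`.
#' @return Numeric vector of the eight (or fewer) comparison frequencies,
#'   more coarse first.
#' @export
comparison_frequencies <- function(set) {
  stopifnot(inherits(set, "stimulus_set"))
  c(set$more_coarse, set$less_coarse)
}

#' Difference ratio between a comparison and the standard grating
#'
#' The stimulus-intensity axis of the psychometric analysis:
#' `|f_co - f_st| / f_st` (dimensionless).
#'
#' @param f_co comparison spatial frequency (m^-1).
#' @param f_st standard spatial frequency (m^-1).
#' @return Non-negative difference ratio (vectorised).
#' @examples
#' difference_ratio(100, 164) # 0.390
#' difference_ratio(148, 164) # 0.098
#' @export
difference_ratio <- function(f_co, f_st) {
  stop_if_not_positive(f_co, "f_co")
  stop_if_not_positive(f_st, "f_st")
  abs(f_co - f_st) / f_st
}

#' Spatial period of a grating
#'
#' @param frequency spatial frequency (m^-1).
#' @return Period in meters, `1 / frequency` (vectorised).
#' @examples
#' spatial_period(100) # 0.010 m
#' @export
spatial_period <- function(frequency) {
  stop_if_not_positive(frequency, "frequency")
  1 / frequency
}

#' Range of difference ratios spanned by a stimulus set
#'
#' @param set a `stimulus_set`.
#' @return Length-2 vector `c(min, max)` of the set's difference ratios.
#' @export
ratio_range <- function(set) {
  r <- difference_ratio(comparison_frequencies(set), set$standard)
  c(min(r), max(r))
}

# The six triangle-test position patterns. Two entries equal, odd one out at
# the position where the pattern differs; "Co" odd in the St/St/Co family,
# "St" odd in the Co/Co/St family.
triangle_combinations <- function() {
  c("St/St/Co", "St/Co/St", "Co/St/St", "Co/Co/St", "Co/St/Co", "St/Co/Co")
}

combination_to_triplet <- function(combination, f_st, f_co) {
  roles <- strsplit(combination, "/", fixed = TRUE)[[1]]
  freq <- ifelse(roles == "St", f_st, f_co)
  n_co <- sum(roles == "Co")
  odd_role <- if (n_co == 1L) "Co" else "St"
  list(triplet = freq, odd_index = which(roles == odd_role), roles = roles)
}

#' Build one triangle-test trial
#'
#' Draws one of the six position patterns uniformly at random: two of the
#' three rendered textures share a frequency and the third (the odd one) is
#' either the comparison among two standards or the standard among two
#' comparisons.
#'
#' @param f_st,f_co standard and comparison spatial frequencies (m^-1); must
#'   differ, otherwise no odd texture exists.
#' @param seed optional integer seed (caller RNG state is preserved).
#' @return A list of class `trial_spec` with elements `triplet` (frequencies
#'   at positions 1:3), `odd_index` (1-based position of the odd texture),
#'   `combination`, `f_st`, `f_co`, `side` and `diff_ratio`.
#' @export
triangle_trial <- function(f_st, f_co, seed = NULL) {
  stop_if_not_positive(f_st, "f_st")
  stop_if_not_positive(f_co, "f_co")
  if (f_st == f_co)
    stop("standard and comparison frequencies are equal: no odd texture exists")
  combination <- with_seed(seed, sample(triangle_combinations(), 1L))
  tri <- combination_to_triplet(combination, f_st, f_co)
  structure(
    list(triplet = tri$triplet, odd_index = tri$odd_index,
         combination = combination, f_st = f_st, f_co = f_co,
         side = if (f_co < f_st) "more_coarse" else "less_coarse",
         diff_ratio = difference_ratio(f_co, f_st)),
    class = "trial_spec")
}

# Vectorised trial construction for a whole block: draws a position
# pattern per trial and expands triplet frequencies and odd positions by
# table lookup.
make_trials <- function(f_st, f_cos, phase) {
  labels <- triangle_combinations()
  roles <- do.call(rbind, strsplit(labels, "/", fixed = TRUE))
  odd_of <- apply(roles, 1, function(r)
    which(r == if (sum(r == "Co") == 1L) "Co" else "St"))
  ci <- sample.int(6L, length(f_cos), replace = TRUE)
  trip <- matrix(f_st, nrow = length(f_cos), ncol = 3)
  is_co <- roles[ci, , drop = FALSE] == "Co"
  for (j in 1:3) trip[is_co[, j], j] <- f_cos[is_co[, j]]
  out <- data.frame(trial_idx = seq_along(f_cos), phase = phase,
                    f_st = f_st, f_co = f_cos,
                    diff_ratio = difference_ratio(f_cos, f_st),
                    side = ifelse(f_cos < f_st, "more_coarse", "less_coarse"),
                    combination = labels[ci], odd_index = odd_of[ci],
                    f1 = trip[, 1], f2 = trip[, 2], f3 = trip[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_block", "data.frame")
  out
}

#' Build a constant-stimuli block of triangle trials
#'
#' Each comparison stimulus of the set is presented `repetitions` times
#' (40 trials for the default 8-comparison set with 5 repetitions) in a
#' seeded random order; the position pattern of every trial is drawn
#' independently.
#'
#' @param set a `stimulus_set`.
#' @param repetitions presentations per comparison stimulus (default 5).
#' @param phase phase label, one of `"iBL"`, `"BL"`, `"training"`, `"RT"`,
#'   `"familiarization"`.
#' @param seed optional integer seed.
#' @return A data.frame (class `trial_block`) with one row per trial:
#'   `trial_idx`, `phase`, `f_st`, `f_co`, `diff_ratio`, `side`,
#'   `combination`, `odd_index`, and the rendered triplet `f1:f3`.
#' @export
constant_stimuli_block <- function(set, repetitions = 5, phase = "BL",
                                   seed = NULL) {
  stopifnot(inherits(set, "stimulus_set"))
  phase <- match.arg(phase, c("iBL", "BL", "training", "RT", "familiarization"))
  if (repetitions < 1) stop("`repetitions` must be >= 1")
  comp <- comparison_frequencies(set)
  if (!length(comp)) stop("stimulus set has no comparison stimuli")
  with_seed(seed, {
    f_cos <- sample(rep(comp, each = repetitions))
    make_trials(set$standard, f_cos, phase)
  })
}

#' Build the three training blocks
#'
#' Three 40-trial constant-stimuli blocks. The comparison-stimulus
#' presentation order is randomised once, for the first block, and the same
#' order is reused in blocks two and three; the triangle position patterns
#' are re-drawn independently per trial so the odd position cannot be
#' memorised across blocks.
#'
#' @param training_set the (possibly PSE-adapted) `stimulus_set` for training.
#' @param repetitions presentations per comparison per block (default 5).
#' @param seed optional integer seed.
#' @return List of three `trial_block` data.frames, each with
#'   `phase == "training"` and a `block` column (1:3).
#' @export
training_blocks <- function(training_set, repetitions = 5, seed = NULL) {
  stopifnot(inherits(training_set, "stimulus_set"))
  with_seed(seed, {
    first <- constant_stimuli_block(training_set, repetitions, "training")
    first$block <- 1L
    blocks <- list(first)
    for (b in 2:3) {
      blk <- make_trials(first$f_st[1], first$f_co, "training")
      blk$block <- b
      blocks[[b]] <- blk
    }
    blocks
  })
}

#' Read or write a stimulus-set configuration file
#'
#' YAML with keys `standard_frequency`, `more_coarse`, `less_coarse`
#' (all m^-1).
#'
#' @param set a `stimulus_set`.
#' @param path file path.
#' @return `read_stimulus_set()` returns a `stimulus_set`;
#'   `write_stimulus_set()` returns `path` invisibly.
#' @export
write_stimulus_set <- function(set, path) {
  stopifnot(inherits(set, "stimulus_set"))
  yaml::write_yaml(list(standard_frequency = set$standard,
                        more_coarse = set$more_coarse,
                        less_coarse = set$less_coarse), path)
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("standard_frequency", "more_coarse", "less_coarse")
  if (!all(need %in% names(cfg)))
    stop("stimulus-set config must contain keys: ",
         paste(need, collapse = ", "))
  stimulus_set(cfg$standard_frequency, unlist(cfg$more_coarse),
               unlist(cfg$less_coarse), check = FALSE)
}
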