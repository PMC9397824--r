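# Exact bounds of the baseline difference-ratio range: 16/164 and 64/164,
# which print as 0.098 and 0.39.
baseline_ratio_bounds <- function() c(16 / 164, 64 / 164)

#' Probability of correct responses per comparison stimulus and phase score
#'
#' For each comparison stimulus the proportion of correct responses
#' `p_i = sum(Y_i) / n_i` is computed; the phase score is the unweighted
#' mean of the per-stimulus proportions.
#'
#' @param records data.frame of trial records with columns `f_co` and
#'   `correct` (0/1), typically one participant-phase slice of a session
#'   log.
#' @param set optional `stimulus_set`; when supplied, every comparison
#'   frequency of the set must be present in `records` (an error lists any
#'   absent ones).
#' @return List of class `phase_score` with `per_stimulus` (data.frame
#'   `f_co`, `n`, `p`) and `score` (mean of the per-stimulus proportions).
#' @export
phase_score <- function(records, set = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("f_co", "correct") %in% names(records)))
  if (!is.null(set)) {
    absent <- setdiff(comparison_frequencies(set), unique(records$f_co))
    if (length(absent))
      stop("no trials for comparison stimuli: ",
           paste(absent, collapse = ", "), " m^-1")
  }
  agg <- stats::aggregate(correct ~ f_co, data = records,
                          FUN = function(y) c(n = length(y), p = mean(y)))
  per <- data.frame(f_co = agg$f_co, n = agg$correct[, "n"],
                    p = agg$correct[, "p"])
  per <- per[order(per$f_co), , drop = FALSE]
  structure(list(per_stimulus = per, score = mean(per$p)),
            class = "phase_score")
}

#' @export
print.phase_score <- function(x, ...) {
  cat("Phase score (mean of per-stimulus proportions):",
      format(x$score, digits = 4), "\n")
  print(x$per_stimulus, row.names = FALSE)
  invisible(x)
}

#' Is a fitted PSE inside the baseline difference-ratio range?
#'
#' The fit of a psychometric side is treated as converged only when its
#' point of subjective equality falls (inclusively) inside the range of
#' difference ratios presented at baseline, 16/164 to 64/164 (printed
#' 0.098 and 0.39).
#'
#' @param pse point of subjective equality (difference ratio), may be `NA`.
#' @param bounds length-2 inclusive range; defaults to the baseline range.
#' @return Logical flag (FALSE for `NA`/non-finite input).
#' @export
check_convergence <- function(pse, bounds = baseline_ratio_bounds()) {
  !is.na(pse) & is.finite(pse) & pse >= bounds[1] & pse <= bounds[2]
}

#' Fit the logistic psychometric function for one coarseness side
#'
#' Maximum-likelihood logistic regression of response correctness on the
#' difference ratio, `P(correct | x) = 1 / (1 + exp(-(alpha + beta x)))`,
#' fitted separately for the more coarse and less coarse comparison sides.
#' The point of subjective equality is the ratio at which the fitted curve
#' crosses 0.5, `PSE = -alpha / beta`.
#'
#' Degenerate data states (perfect separation, all-equal responses,
#' non-positive slope, PSE outside the baseline ratio range) yield
#' `converged = FALSE` rather than an error.
#'
#' @param records trial records of one side: columns `diff_ratio` and
#'   `correct`.
#' @param side label stored in the result (`"more_coarse"`/`"less_coarse"`).
#' @return Object of class `psychometric_fit`: `side`, `alpha`, `beta`,
#'   `pse`, `converged`, `n_trials`.
#' @export
fit_psychometric <- function(records, side = "more_coarse") {
  stopifnot(is.data.frame(records),
            all(c("diff_ratio", "correct") %in% names(records)))
  out <- list(side = side, alpha = NA_real_, beta = NA_real_,
              pse = NA_real_, converged = FALSE, n_trials = nrow(records))
  distinct_x <- length(unique(records$diff_ratio))
  both_outcomes <- length(unique(records$correct)) == 2
  if (nrow(records) < 4 || distinct_x < 2 || !both_outcomes) {
    class(out) <- "psychometric_fit"
    return(out)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(correct ~ diff_ratio, family = stats::binomial(),
               data = records),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  out$alpha <- unname(cf[1])
  out$beta <- unname(cf[2])
  if (!separated && fit$converged && all(is.finite(cf)) && out$beta > 0) {
    out$pse <- -out$alpha / out$beta
    out$converged <- check_convergence(out$pse)
  }
  class(out) <- "psychometric_fit"
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Psychometric fit [%s]: alpha = %s, beta = %s, PSE = %s (%s, n = %d)\n",
              x$side, format(x$alpha, digits = 4), format(x$beta, digits = 4),
              format(x$pse, digits = 4),
              if (x$converged) "converged" else "not converged", x$n_trials))
  invisible(x)
}

#' PSE outcome of one participant-phase
#'
#' Fits the psychometric function per coarseness side and combines the two
#' PSEs into the phase-level score:
#' \itemize{
#'   \item if the participant answered every trial of the phase correctly,
#'     the phase PSE is set to the minimum presented difference ratio
#'     (16/164, printed 0.098) — the edge rule for a ceiling performer;
#'   \item otherwise the phase PSE is the mean of the two per-side fitted
#'     PSEs, and is missing (`NA`) unless both sides converged (so that
#'     downstream paired analyses can exclude the participant).
#' }
#'
#' @param records all trial records of one participant-phase: columns
#'   `diff_ratio`, `side`, `correct`.
#' @param all_correct_rule apply the ceiling edge rule per `"phase"` (all
#'   trials of the phase correct; default, matching the protocol
#'   description) or per `"side"`.
#' @param require_both_sides when `FALSE`, a phase with a single converged
#'   side uses that side's PSE instead of being missing.
#' @return List of class `pse_outcome`: `pse` (phase PSE or `NA`),
#'   `pse_more_coarse`, `pse_less_coarse`, `fits` (the two
#'   `psychometric_fit`s, `NULL` under the ceiling rule).
#' @export
pse_outcome <- function(records, all_correct_rule = c("phase", "side"),
                        require_both_sides = TRUE) {
  all_correct_rule <- match.arg(all_correct_rule)
  stopifnot(is.data.frame(records),
            all(c("diff_ratio", "side", "correct") %in% names(records)))
  floor_pse <- baseline_ratio_bounds()[1]
  if (all_correct_rule == "phase" && all(records$correct == 1)) {
    return(structure(list(pse = floor_pse, pse_more_coarse = floor_pse,
                          pse_less_coarse = floor_pse, fits = NULL),
                     class = "pse_outcome"))
  }
  side_pse <- function(side) {
    rec <- records[records$side == side, , drop = FALSE]
    if (!nrow(rec)) return(list(pse = NA_real_, fit = NULL))
    if (all_correct_rule == "side" && all(rec$correct == 1))
      return(list(pse = floor_pse, fit = NULL))
    fit <- fit_psychometric(rec, side)
    list(pse = if (fit$converged) fit$pse else NA_real_, fit = fit)
  }
  mc <- side_pse("more_coarse")
  lc <- side_pse("less_coarse")
  both <- c(mc$pse, lc$pse)
  pse <- if (all(!is.na(both))) mean(both)
  else if (!require_both_sides && any(!is.na(both))) mean(both, na.rm = TRUE)
  else NA_real_
  structure(list(pse = pse, pse_more_coarse = mc$pse,
                 pse_less_coarse = lc$pse,
                 fits = Filter(Negate(is.null), list(mc$fit, lc$fit))),
            class = "pse_outcome")
}

#' Build the PSE-adapted comparison set for training
#'
#' Centers each side's four training comparison stimuli on that side's
#' baseline PSE: difference ratios
#' `PSE + c(-1.5, -0.5, 0.5, 1.5) * delta` with the baseline spacing
#' `delta = 16/164` retained. Ratios are clipped below at the smallest
#' ratio the robot can render (one 0.02 mm change of the standard's spatial
#' period) and above at the maximum baseline ratio (64/164, printed 0.39).
#' Ratios map back to frequencies as `f_st * (1 - r)` on the more coarse
#' side and `f_st * (1 + r)` on the less coarse side. A side whose baseline
#' fit did not converge keeps its baseline comparison stimuli; when neither
#' side converged the training set is the baseline set.
#'
#' When the PSE equals a side's central baseline ratio the construction
#' reproduces that side's baseline stimuli (it is idempotent at its fixed
#' point).
#'
#' This construction is a reconstruction of the adaptive procedure from its
#' stated inputs (per-side PSEs, baseline spacing, admissible ratio range);
#' it is isolated here so an alternative rule can be swapped in.
#'
#' @param pse_mc,pse_lc per-side baseline PSEs (difference ratios); ignored
#'   for a side whose flag is `FALSE`.
#' @param baseline_set the baseline `stimulus_set`.
#' @param converged_mc,converged_lc per-side convergence flags.
#' @param resolution robot position resolution (m) defining the smallest
#'   renderable period change (default 2e-5, i.e. 0.02 mm).
#' @return A `stimulus_set` for training.
#' @export
adapt_training_set <- function(pse_mc, pse_lc, baseline_set,
                               converged_mc = check_convergence(pse_mc),
                               converged_lc = check_convergence(pse_lc),
                               resolution = 2e-5) {
  stopifnot(inherits(baseline_set, "stimulus_set"))
  f_st <- baseline_set$standard
  delta <- 16 / 164
  # smallest ratio whose frequency differs from the standard by at least
  # one resolution step of the spatial period
  r_min <- abs(1 / (spatial_period(f_st) - resolution) - f_st) / f_st
  r_max <- baseline_ratio_bounds()[2]
  side_ratios <- function(pse) {
    r <- pmin(pmax(pse + c(-1.5, -0.5, 0.5, 1.5) * delta, r_min), r_max)
    # clipping can collapse neighbours; keep them at least one resolution
    # step apart so the four stimuli stay distinct (range width >> 4 steps)
    for (i in 3:1) r[i] <- min(r[i], r[i + 1] - r_min)
    for (i in 2:4) r[i] <- max(r[i], r[i - 1] + r_min)
    r
  }
  mc <- if (isTRUE(converged_mc)) {
    r <- side_ratios(pse_mc)
    sort(f_st * (1 - r))
  } else baseline_set$more_coarse
  lc <- if (isTRUE(converged_lc)) {
    r <- side_ratios(pse_lc)
    sort(f_st * (1 + r))
  } else baseline_set$less_coarse
  suppressWarnings(stimulus_set(f_st, mc, lc))
}
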