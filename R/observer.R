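#' Simulated triangle-test observer
#'
#' A stateless generative model of a participant. The probability of a
#' correct odd-texture identification at difference ratio `x` follows a
#' logistic curve with known intercept `alpha` and slope `beta`, so the
#' analysis chain can be validated by parameter recovery.
#'
#' Two response-generation modes are provided:
#' \describe{
#'   \item{`plain_logistic`}{`p(x) = 1 / (1 + exp(-(alpha + beta * x)))`.
#'     With the default `alpha = -log(2)` the curve passes through the
#'     triangle-test chance level 1/3 at `x = 0`.}
#'   \item{`guess_floored`}{a guessing-rate-corrected curve anchored so
#'     that `p(0) = 1/3` exactly:
#'     `p(x) = 1/3 + (2/3) * (F(x) - F(0)) / (1 - F(0))` with
#'     `F(x) = 1 / (1 + exp(-(alpha + beta * x)))`. The anchoring keeps the
#'     floor exact for any finite `alpha` (an unanchored
#'     `1/3 + (2/3) F(x)` floors at 1/3 only in the limit
#'     `alpha -> -Inf`).}
#' }
#'
#' `alpha` and `beta` may be single numbers or named length-2 vectors
#' `c(more_coarse = , less_coarse = )` for side-specific sensitivity.
#'
#' @param alpha logistic intercept (default `-log(2)`).
#' @param beta logistic slope per unit difference ratio, `>= 0` (default 10).
#' @param floor_mode `"plain_logistic"` or `"guess_floored"`.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(alpha = -log(2), beta = 10,
                           floor_mode = c("plain_logistic", "guess_floored")) {
  floor_mode <- match.arg(floor_mode)
  expand_side <- function(v, name) {
    if (length(v) == 1L) v <- c(more_coarse = unname(v), less_coarse = unname(v))
    if (length(v) != 2L || !all(c("more_coarse", "less_coarse") %in% names(v)))
      stop("`", name, "` must be length 1 or named c(more_coarse=, less_coarse=)")
    v[c("more_coarse", "less_coarse")]
  }
  alpha <- expand_side(alpha, "alpha")
  beta <- expand_side(beta, "beta")
  if (any(beta < 0)) stop("`beta` must be >= 0")
  structure(list(alpha = alpha, beta = beta, floor_mode = floor_mode),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat("Simulated observer (", x$floor_mode, ")\n", sep = "")
  cat("  alpha:", format(x$alpha), "\n  beta: ", format(x$beta), "\n")
  invisible(x)
}

#' Probability of a correct response for an observer
#'
#' @param observer an `observer_model`.
#' @param x difference ratio(s), `>= 0`.
#' @param side `"more_coarse"` or `"less_coarse"`; recycles over `x`.
#' @return Probability of identifying the odd texture, in (0, 1),
#'   non-decreasing in `x`.
#' @export
p_correct <- function(observer, x, side = "more_coarse") {
  stopifnot(inherits(observer, "observer_model"), all(x >= 0))
  a <- observer$alpha[side]
  b <- observer$beta[side]
  base <- stats::plogis(unname(a) + unname(b) * x)
  if (observer$floor_mode == "guess_floored") {
    f0 <- stats::plogis(unname(a))
    1 / 3 + (2 / 3) * (base - f0) / (1 - f0)
  } else base
}

#' Simulate an observer's response to one triangle trial
#'
#' The response is correct with probability [p_correct()] at the trial's
#' difference ratio; an incorrect response is uniform over the two non-odd
#' positions.
#'
#' @param trial a `trial_spec` (see [triangle_trial()]) or a one-row subset
#'   of a `trial_block`.
#' @param observer an `observer_model`.
#' @param seed optional integer seed.
#' @return List with `response_index` (1:3) and `correct` (0/1).
#' @export
simulate_response <- function(trial, observer, seed = NULL) {
  if (is.data.frame(trial)) trial <- as.list(trial[1, ])
  with_seed(seed, {
    p <- p_correct(observer, trial$diff_ratio, trial$side)
    if (stats::runif(1) < p) {
      list(response_index = trial$odd_index, correct = 1L)
    } else {
      others <- setdiff(1:3, trial$odd_index)
      list(response_index = sample(others, 1L), correct = 0L)
    }
  })
}

#' Simulate an observer working through a block of trials
#'
#' @param block a `trial_block` data.frame.
#' @param observer an `observer_model`.
#' @param seed optional integer seed.
#' @return The block with `response_index` and `correct` columns appended
#'   (one record per trial, order preserved).
#' @export
simulate_block <- function(block, observer, seed = NULL) {
  stopifnot(is.data.frame(block), nrow(block) >= 1)
  with_seed(seed, {
    n <- nrow(block)
    p <- numeric(n)
    for (s in c("more_coarse", "less_coarse")) {
      sel <- block$side == s
      if (any(sel)) p[sel] <- p_correct(observer, block$diff_ratio[sel], s)
    }
    correct <- as.integer(stats::runif(n) < p)
    # wrong responses: uniform over the two non-odd positions
    shift <- 1L + stats::rbinom(n, 1L, 0.5)
    resp <- ifelse(correct == 1L, block$odd_index,
                   (block$odd_index - 1L + shift) %% 3L + 1L)
    out <- block
    out$response_index <- as.integer(resp)
    out$correct <- correct
    out
  })
}
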