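#' Exact binomial power of the triangle discrimination test
#'
#' One-sided exact test of the triangle-test guessing probability 1/3: the
#' critical count is the smallest `c` with `P(X >= c | n, 1/3) <= alpha`,
#' and the power is `P(X >= c | n, p_alt)` under the alternative proportion
#' correct `p_alt`.
#'
#' @param n_trials number of triangle trials.
#' @param p_alt true proportion correct under the alternative,
#'   in (1/3, 1].
#' @param alpha one-sided type-I error level.
#' @return Power in `[0, 1]`, with attribute `critical` (the critical
#'   count). When even `c = n` does not control the size, power 0 is
#'   returned with a warning.
#' @examples
#' triangle_power(40, 25 / 40)
#' @export
triangle_power <- function(n_trials, p_alt, alpha = 0.05) {
  stopifnot(n_trials >= 1, alpha > 0, alpha < 1)
  if (p_alt <= 1 / 3 || p_alt > 1)
    stop("`p_alt` must lie in (1/3, 1]")
  # P(X >= k | n, 1/3) for k = 0..n
  tail <- stats::pbinom(0:n_trials - 1, n_trials, 1 / 3, lower.tail = FALSE)
  ok <- which(tail <= alpha)
  if (!length(ok)) {
    warning("no critical region of level ", alpha, " exists at n = ",
            n_trials)
    return(structure(0, critical = NA_integer_))
  }
  crit <- min(ok) - 1L            # counts are 0-based
  pw <- stats::pbinom(crit - 1, n_trials, p_alt, lower.tail = FALSE)
  structure(pw, critical = crit)
}

#' Sample size for the triangle discrimination test
#'
#' Smallest number of trials whose exact binomial triangle test attains the
#' target power. Because exact-binomial power is a sawtooth in `n`, two
#' modes are offered: `"first"` (default) returns the first crossing;
#' `"stable"` additionally requires every larger `n` up to the search bound
#' to qualify.
#'
#' @param p_alt true proportion correct under the alternative, in (1/3, 1].
#' @param alpha one-sided type-I error level.
#' @param target_power required power.
#' @param mode `"first"` or `"stable"` crossing.
#' @param n_max search bound.
#' @return Smallest qualifying `n`, with attribute `power` (the attained
#'   power at that `n`).
#' @examples
#' triangle_sample_size(25 / 40)  # 34
#' @export
triangle_sample_size <- function(p_alt, alpha = 0.05, target_power = 0.95,
                                 mode = c("first", "stable"), n_max = 10000) {
  mode <- match.arg(mode)
  if (p_alt <= 1 / 3) stop("`p_alt` must exceed the guessing level 1/3")
  stopifnot(target_power > 0, target_power < 1)
  pw <- vapply(seq_len(n_max), function(n)
    as.numeric(suppressWarnings(triangle_power(n, p_alt, alpha))), numeric(1))
  qual <- pw >= target_power
  if (!any(qual))
    stop("no n <= ", n_max, " reaches power ", target_power)
  n <- if (mode == "first") which(qual)[1]
  else {
    stable <- rev(cumprod(rev(qual))) == 1
    which(stable)[1]
  }
  structure(as.integer(n), power = pw[n])
}
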