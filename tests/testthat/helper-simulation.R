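# Generate per-side psychometric records directly from an observer's
# response probabilities (the generative model of the analysis chain).
sim_side_records <- function(observer, ratios, reps, side = "more_coarse") {
  x <- rep(ratios, each = reps)
  data.frame(diff_ratio = x, side = side,
             correct = stats::rbinom(length(x), 1,
                                     p_correct(observer, x, side)))
}

# Analytic constant-speed sweep trace over one texture: the oracle for the
# kinematic outcomes (uniform motion along y at `speed`, in contact with
# texture `tex` the whole time).
uniform_sweep_trace <- function(speed = 0.2, length_m = 0.176, dt = 1e-3,
                                tex = 2L, t0 = 0) {
  n <- as.integer(round(length_m / (speed * dt))) + 1L
  tt <- (seq_len(n) - 1) * dt
  df <- data.frame(time_s = t0 + tt, x = 0, y = -length_m / 2 + speed * tt,
                   z = 0, vx = 0, vy = speed, vz = 0, Fg = 0, Fz = 0,
                   Fhg = 0, Fx = 0, Fy = 0, Fz_total = 0, y_ref = NA_real_,
                   contact = TRUE, texture_id = tex)
  attr(df, "dt") <- dt
  class(df) <- c("kinematic_trace", "data.frame")
  df
}

# From-scratch two-way ANOVA mean squares via stats::aov (independent route
# used as the ICC oracle).
aov_icc_2k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (MSC - MSE) / n)
}
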