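#' Simulate the exploration of one triangle trial
#'
#' Stands in for the participant-plus-robot loop: a point-mass hand /
#' end-effector model `m_h * acc = F_robot + F_hand - b_h * vel` is
#' integrated with semi-implicit Euler at a fixed haptic rate. The simulated
#' hand visits the three textures in order; on each texture it presses down
#' into contact and performs back-and-forth cycloidal sweeps along the
#' scanning axis.
#'
#' In `"passive"` mode the sweeps are driven by the robot's cycloidal
#' guidance controller while the hand stays compliant (it only presses down
#' and holds the lateral position); in `"active"` mode guidance is off and
#' the hand's own scripted policy tracks the same cycloidal schedule. Sweep
#' duration is chosen so the cycloid's peak speed equals `target_speed`.
#'
#' @param trial a `trial_spec` (see [triangle_trial()]) or one-row
#'   `trial_block` subset; its triplet gives the grating frequency on each
#'   texture.
#' @param mode `"active"` or `"passive"`.
#' @param params a `haptic_params`.
#' @param dt integration timestep (s), default 0.001 (1 kHz haptic rate).
#' @param sweeps back-and-forth cycloidal segments per texture (default 2).
#' @param target_speed peak sweep speed (m/s), default 0.17.
#' @param press_force downward hand force while exploring (N).
#' @param m_h,b_h hand/end-effector mass (kg) and viscous impedance (N.s/m).
#' @param edge_margin sweep turn-around margin inside the texture edge (m).
#' @return A `kinematic_trace` data.frame sampled at `dt`: time_s, position,
#'   velocity, force components (`Fg` contact-gated grating force, `Fz`
#'   wall, `Fhg` guidance, `Fx`/`Fy`/`Fz_total` total force), `y_ref`
#'   (NA outside sweeps), `contact`, `texture_id`. Attributes: `dt`, `mode`,
#'   `last_texture` (for response attribution).
#' @export
simulate_exploration <- function(trial, mode = c("active", "passive"),
                                 params = haptic_params(), dt = 1e-3,
                                 sweeps = 2, target_speed = 0.17,
                                 press_force = 5, m_h = 1, b_h = 5,
                                 edge_margin = 0.004) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("`dt` must be > 0")
  if (is.data.frame(trial))
    freqs <- c(trial$f1[1], trial$f2[1], trial$f3[1])
  else freqs <- trial$triplet
  layout <- texture_layout(params)

  l <- params$texture_length
  y0 <- -l / 2 + edge_margin
  y1 <- l / 2 - edge_margin
  T_sweep <- 2 * (y1 - y0) / target_speed   # cycloid peak speed = 2 D / T
  z_hover <- params$z_tbl + 0.004
  x_centers <- (layout$xmin + layout$xmax) / 2

  # Per-texture visit schedule: transit above the texture, press into
  # contact, alternate cycloidal sweeps, lift off.
  segs <- list()
  for (k in 1:3) {
    segs <- c(segs, list(list(type = "transit", T = 0.7, tex = k,
                              x = x_centers[k], y = y0, z = z_hover)))
    segs <- c(segs, list(list(type = "press", T = 0.35, tex = k,
                              x = x_centers[k], y = y0)))
    ya <- y0
    for (s in seq_len(sweeps)) {
      yb <- if (s %% 2 == 1) y1 else y0
      segs <- c(segs, list(list(type = "sweep", T = T_sweep, tex = k,
                                x = x_centers[k], y0 = ya, y1 = yb)))
      ya <- yb
    }
    segs <- c(segs, list(list(type = "lift", T = 0.2, tex = k,
                              x = x_centers[k], y = ya, z = z_hover)))
  }

  n_steps <- sum(vapply(segs, function(s) ceiling(s$T / dt), numeric(1)))
  alloc <- function() numeric(n_steps)
  tr <- list(time_s = alloc(), x = alloc(), y = alloc(), z = alloc(),
             vx = alloc(), vy = alloc(), vz = alloc(),
             Fg = alloc(), Fz = alloc(), Fhg = alloc(),
             Fx = alloc(), Fy = alloc(), Fz_total = alloc(),
             y_ref = rep(NA_real_, n_steps),
             contact = logical(n_steps), texture_id = rep(NA_integer_, n_steps))

  # transit PD gains of the scripted hand
  Kp <- 200; Kd <- 30
  pos <- c(x_centers[1], y0, z_hover)
  vel <- c(0, 0, 0)
  t_now <- 0
  i <- 0L
  last_tex <- NA_integer_

  for (seg in segs) {
    n_seg <- ceiling(seg$T / dt)
    for (j in seq_len(n_seg)) {
      t_seg <- (j - 1) * dt
      # --- contact ---
      in_x <- pos[1] >= layout$xmin & pos[1] <= layout$xmax
      in_y <- pos[2] >= layout$ymin & pos[2] <= layout$ymax
      tex <- which(in_x & in_y)[1]
      contact <- !is.na(tex) && pos[3] < params$z_tbl
      if (contact) last_tex <- tex

      # --- robot forces ---
      F_rd <- if (contact) grating_force(pos[2], freqs[tex], params$C) else 0
      F_z <- if (pos[3] < params$z_tbl)
        params$K_z * (params$z_tbl - pos[3]) + params$B_z * (-vel[3]) else 0

      ref <- NULL
      if (seg$type == "sweep") {
        ref <- cycloidal_reference(min(t_seg, seg$T), seg$y0, seg$y1, seg$T)
        tr$y_ref[i + 1L] <- ref$y
      }
      F_hg <- if (mode == "passive" && !is.null(ref) && contact)
        params$m_v * ref$a + params$K_hg * (ref$y - pos[2]) +
          params$B_hg * (ref$v - vel[2]) else 0

      # --- scripted hand policy ---
      Fh_x <- Kp * (seg$x - pos[1]) - Kd * vel[1]
      Fh_y <- 0
      Fh_z <- 0
      if (seg$type %in% c("transit", "lift")) {
        Fh_y <- Kp * (seg$y - pos[2]) - Kd * vel[2]
        Fh_z <- Kp * (seg$z - pos[3]) - Kd * vel[3]
      } else {
        Fh_z <- -press_force
        if (seg$type == "press") {
          Fh_y <- Kp * (seg$y - pos[2]) - Kd * vel[2]
        } else if (mode == "active") {
          # active exploration: hand tracks the cycloidal schedule itself
          Fh_y <- m_h * ref$a + Kp * (ref$y - pos[2]) + Kd * (ref$v - vel[2])
        }
      }

      F_tot <- c(Fh_x, F_rd + F_hg + Fh_y, F_z + Fh_z)

      # --- record, then integrate (semi-implicit Euler) ---
      i <- i + 1L
      tr$time_s[i] <- t_now; tr$x[i] <- pos[1]; tr$y[i] <- pos[2]
      tr$z[i] <- pos[3]; tr$vx[i] <- vel[1]; tr$vy[i] <- vel[2]
      tr$vz[i] <- vel[3]
      tr$Fg[i] <- F_rd; tr$Fz[i] <- F_z; tr$Fhg[i] <- F_hg
      tr$Fx[i] <- 0; tr$Fy[i] <- F_rd + F_hg; tr$Fz_total[i] <- F_z
      tr$contact[i] <- contact
      tr$texture_id[i] <- if (contact) tex else NA_integer_

      acc <- (F_tot - b_h * vel) / m_h
      vel <- vel + dt * acc
      pos <- pos + dt * vel
      t_now <- t_now + dt
      if (any(!is.finite(pos)) || any(!is.finite(vel)))
        stop(sprintf(paste0("exploration integration diverged at t = %.3f s ",
                            "(dt = %g, K_z = %g, B_z = %g, K_hg = %g, ",
                            "B_hg = %g, m_h = %g, b_h = %g)"),
                     t_now, dt, params$K_z, params$B_z, params$K_hg,
                     params$B_hg, m_h, b_h))
    }
  }

  out <- as.data.frame(tr)[seq_len(i), , drop = FALSE]
  attr(out, "dt") <- dt
  attr(out, "mode") <- mode
  attr(out, "last_texture") <- last_tex
  class(out) <- c("kinematic_trace", "data.frame")
  out
}

#' Drop test against the virtual table wall
#'
#' One-axis diagnostic of the wall renderer: a free point mass is dropped
#' onto the virtual table under gravity with no hand force and integrated
#' with the same semi-implicit Euler scheme as [simulate_exploration()].
#' Useful for verifying that the PD wall plus damping behaves passively
#' (total mechanical energy non-increasing).
#'
#' @param z0,v0 initial height (m) and vertical velocity (m/s).
#' @param params a `haptic_params`.
#' @param dt timestep (s).
#' @param duration simulated time (s).
#' @param m_h mass (kg).
#' @param g gravitational acceleration (m/s^2).
#' @return data.frame with `time_s`, `z`, `vz`, `Fz` and `energy` (kinetic
#'   + wall elastic + gravitational potential, J).
#' @export
simulate_wall_drop <- function(z0 = 0.004, v0 = 0, params = haptic_params(),
                               dt = 1e-3, duration = 2, m_h = 1, g = 9.81) {
  n <- ceiling(duration / dt)
  z <- numeric(n); v <- numeric(n)
  z[1] <- z0; v[1] <- v0
  for (i in 2:n) {
    F <- if (z[i - 1] < params$z_tbl)
      params$K_z * (params$z_tbl - z[i - 1]) + params$B_z * (-v[i - 1]) else 0
    a <- (F - m_h * g) / m_h
    v[i] <- v[i - 1] + dt * a
    z[i] <- z[i - 1] + dt * v[i]
  }
  pen <- pmax(0, params$z_tbl - z)
  Fz <- ifelse(z < params$z_tbl, params$K_z * (params$z_tbl - z) - params$B_z * v, 0)
  data.frame(time_s = (seq_len(n) - 1) * dt, z = z, vz = v, Fz = Fz,
             energy = 0.5 * m_h * v^2 + 0.5 * params$K_z * pen^2 +
               m_h * g * z)
}

trace_columns <- c("time_s", "x", "y", "z", "vx", "vy", "vz", "Fg", "Fz",
                   "Fhg", "Fx", "Fy", "Fz_total", "y_ref", "contact",
                   "texture_id")

#' Read or write a kinematic trace CSV
#'
#' Plain CSV with one row per haptic sample and the columns produced by
#' [simulate_exploration()].
#'
#' @param trace a `kinematic_trace`.
#' @param path file path.
#' @return `read_trace()` returns a `kinematic_trace`; `write_trace()`
#'   returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, trace_columns], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(trace_columns, names(df))
  if (length(missing))
    stop("trace file lacks columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), trace_columns)
  if (length(extra)) {
    warning("ignoring unknown trace columns: ", paste(extra, collapse = ", "))
    df <- df[, trace_columns]
  }
  df$contact <- as.logical(df$contact)
  if (nrow(df) >= 2) attr(df, "dt") <- df$time_s[2] - df$time_s[1]
  class(df) <- c("kinematic_trace", "data.frame")
  df
}

#' Force profile of a grating frequency sweep
#'
#' Tabulates the rendered grating force along the scanning axis for one or
#' more spatial frequencies (the computation behind the `render-forces`
#' command-line subcommand).
#'
#' @param frequencies grating spatial frequencies (m^-1).
#' @param params a `haptic_params`.
#' @param n samples along the texture length.
#' @return data.frame with `frequency`, `y`, `force`.
#' @export
render_force_profile <- function(frequencies, params = haptic_params(),
                                 n = 200) {
  y <- seq(-params$texture_length / 2, params$texture_length / 2,
           length.out = n)
  do.call(rbind, lapply(frequencies, function(f)
    data.frame(frequency = f, y = y, force = grating_force(y, f, params$C))))
}
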