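#' Haptic rendering parameters
#'
#' Bundles the constants of the rendered environment: the sinusoidal grating
#' amplitude, the virtual-table PD wall, the guidance PD controller, and the
#' texture geometry. Defaults are the values used on the desktop delta robot
#' the task was designed around.
#'
#' @param C grating force amplitude (N).
#' @param K_z,B_z virtual-table wall stiffness (N/m) and damping (N.s/m).
#' @param K_hg,B_hg guidance stiffness (N/m) and damping (N.s/m).
#' @param m_v virtual feedforward mass multiplying the reference
#'   acceleration in the guidance law (kg). With `m_v = 1` the guidance
#'   force is numerically the sum of reference acceleration and PD terms.
#' @param z_tbl virtual table height (m).
#' @param texture_length texture extent along the scanning axis y (m).
#' @param texture_width texture extent along x (m).
#' @param texture_gap gap between adjacent textures along x (m).
#' @return A list of class `haptic_params`.
#' @export
haptic_params <- function(C = 3, K_z = 1960, B_z = 28, K_hg = 300, B_hg = 60,
                          m_v = 1, z_tbl = 0.001, texture_length = 0.176,
                          texture_width = 0.02, texture_gap = 0.01) {
  vals <- list(C = C, K_z = K_z, B_z = B_z, K_hg = K_hg, B_hg = B_hg,
               m_v = m_v, z_tbl = z_tbl, texture_length = texture_length,
               texture_width = texture_width, texture_gap = texture_gap)
  for (nm in c("C", "K_z", "B_z", "K_hg", "B_hg", "m_v"))
    if (vals[[nm]] < 0) stop("`", nm, "` must be >= 0")
  for (nm in c("texture_length", "texture_width", "texture_gap"))
    stop_if_not_positive(vals[[nm]], nm)
  structure(vals, class = "haptic_params")
}

#' Texture layout in the workspace
#'
#' Three parallel rectangular textures, long axis along y, laid out along x
#' with a fixed gap. The workspace origin is the center of the middle
#' (second) texture.
#'
#' @param params a `haptic_params`.
#' @return data.frame with one row per texture: `texture_id`, `xmin`,
#'   `xmax`, `ymin`, `ymax` (m).
#' @export
texture_layout <- function(params = haptic_params()) {
  w <- params$texture_width
  g <- params$texture_gap
  l <- params$texture_length
  centers <- c(-(w + g), 0, w + g)
  data.frame(texture_id = 1:3,
             xmin = centers - w / 2, xmax = centers + w / 2,
             ymin = -l / 2, ymax = l / 2)
}

#' Sinusoidal grating force
#'
#' Tangential rendering force of a grating of spatial frequency `f` at end
#' effector position `y_ee` along the scanning axis:
#' `F_g = C * sin(2 * pi * f * y_ee)`. Bounded by `|C|`, periodic with the
#' spatial period `1/f`, and independent of the normal force pressed into
#' the texture.
#'
#' @param y_ee end effector y position (m), vectorised.
#' @param frequency grating spatial frequency (m^-1).
#' @param C force amplitude (N).
#' @return Grating force (N).
#' @export
grating_force <- function(y_ee, frequency, C = 3) {
  stop_if_not_positive(frequency, "frequency")
  C * sin(2 * pi * frequency * y_ee)
}

#' Contact test against the texture layout
#'
#' The end effector is in contact with a texture when it is below the
#' virtual table height and inside that texture's rectangle in the xy-plane.
#'
#' @param x,y,z end effector position (m), vectorised.
#' @param layout a [texture_layout()] data.frame.
#' @param z_tbl virtual table height (m).
#' @return List with logical `contact` and integer `texture_id` (NA when
#'   not in contact).
#' @export
contact_test <- function(x, y, z, layout = texture_layout(), z_tbl = 0.001) {
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  tex <- rep(NA_integer_, n)
  for (k in seq_len(nrow(layout))) {
    inside <- x >= layout$xmin[k] & x <= layout$xmax[k] &
      y >= layout$ymin[k] & y <= layout$ymax[k]
    tex[inside & is.na(tex)] <- layout$texture_id[k]
  }
  contact <- z < z_tbl & !is.na(tex)
  tex[!contact] <- NA_integer_
  list(contact = contact, texture_id = tex)
}

#' Virtual-table wall force
#'
#' PD penalty wall along z: `F_z = K_z * (z_tbl - z) + B_z * (-vz)` when the
#' end effector is below the table height, zero otherwise.
#'
#' @param z,vz end effector vertical position (m) and velocity (m/s),
#'   vectorised.
#' @param params a `haptic_params`.
#' @return Vertical wall force (N).
#' @export
table_force <- function(z, vz, params = haptic_params()) {
  ifelse(z < params$z_tbl,
         params$K_z * (params$z_tbl - z) + params$B_z * (-vz),
         0)
}

#' Cycloidal reference trajectory
#'
#' Point-to-point motion law with zero velocity and acceleration at both
#' segment endpoints:
#' `y(t) = y_start + D * (t/T - sin(2*pi*t/T) / (2*pi))` with
#' `D = y_end - y_start`, plus its analytic first and second derivatives.
#' Peak speed `2 D / T` occurs at mid-segment.
#'
#' @param t time within the segment (s), vectorised; must lie in `[0, T]`.
#' @param y_start,y_end segment endpoints (m).
#' @param T segment duration (s), `> 0`.
#' @return List with `y`, `v`, `a` (position m, velocity m/s,
#'   acceleration m/s^2) and `t`.
#' @export
cycloidal_reference <- function(t, y_start, y_end, T) {
  stop_if_not_positive(T, "T")
  if (any(t < -1e-12 | t > T + 1e-12))
    stop("`t` outside the segment [0, T]")
  t <- pmin(pmax(t, 0), T)
  D <- y_end - y_start
  w <- 2 * pi / T
  list(t = t,
       y = y_start + D * (t / T - sin(w * t) / (2 * pi)),
       v = (D / T) * (1 - cos(w * t)),
       a = (D * w / T) * sin(w * t))
}

#' Haptic guidance force
#'
#' PD tracking of the cycloidal reference along y, with a feedforward
#' reference-acceleration term, active only while the end effector is in
#' contact with a texture:
#' `F_hg = m_v * a_R + K_hg * (y_R - y_ee) + B_hg * (v_R - vy_ee)`.
#'
#' @param y_ee,vy_ee end effector y position (m) and velocity (m/s).
#' @param ref a reference point as returned by [cycloidal_reference()]
#'   (elements `y`, `v`, `a`).
#' @param in_contact logical contact gate.
#' @param params a `haptic_params`.
#' @return Guidance force along y (N); 0 when not in contact.
#' @export
guidance_force <- function(y_ee, vy_ee, ref, in_contact, params = haptic_params()) {
  f <- params$m_v * ref$a + params$K_hg * (ref$y - y_ee) +
    params$B_hg * (ref$v - vy_ee)
  ifelse(in_contact, f, 0)
}

#' Total rendered force at the end effector
#'
#' Composes the contact-gated grating force, the virtual-table wall force
#' and (passive mode only) the guidance force. The robot is transparent in
#' x, so the x component is always zero.
#'
#' @param state list with `x`, `y`, `z`, `vx`, `vy`, `vz` (m, m/s).
#' @param ref reference point (as from [cycloidal_reference()]); ignored in
#'   active mode.
#' @param frequency_by_texture length-3 vector: grating frequency rendered
#'   on each texture (m^-1).
#' @param params a `haptic_params`.
#' @param mode `"active"` (no guidance) or `"passive"` (robot-guided).
#' @param layout a [texture_layout()]; defaults to the layout of `params`.
#' @return List of class `force_breakdown`: `F_g` (ungated grating force),
#'   `F_rd` (contact-gated grating force), `F_z`, `F_hg`, `F_total`
#'   (3-vector, N), plus `contact` and `texture_id`.
#' @export
total_force <- function(state, ref = NULL, frequency_by_texture,
                        params = haptic_params(),
                        mode = c("active", "passive"),
                        layout = texture_layout(params)) {
  mode <- match.arg(mode)
  ct <- contact_test(state$x, state$y, state$z, layout, params$z_tbl)
  f_tex <- if (ct$contact) frequency_by_texture[ct$texture_id] else NA_real_
  F_g <- if (ct$contact) grating_force(state$y, f_tex, params$C) else 0
  F_rd <- if (ct$contact) F_g else 0
  F_z <- table_force(state$z, state$vz, params)
  F_hg <- if (mode == "passive" && !is.null(ref))
    guidance_force(state$y, state$vy, ref, ct$contact, params) else 0
  structure(list(F_g = F_g, F_rd = F_rd, F_z = F_z, F_hg = F_hg,
                 F_total = c(0, F_rd + F_hg, F_z),
                 contact = ct$contact, texture_id = ct$texture_id),
            class = "force_breakdown")
}
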