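#' Kinematic outcomes of one explored trial
#'
#' From a kinematic trace, computes the three exploration measures:
#' \describe{
#'   \item{scanning_duration}{time in contact with a texture while moving
#'     faster than `speed_threshold`, averaged over the three textures (s);}
#'   \item{path_length}{path covered over a texture (sum of |dy| across
#'     contact samples), averaged over the three textures (m);}
#'   \item{mean_scanning_speed}{mean end-effector speed along the scanning
#'     axis over contact samples above the threshold (m/s).}
#' }
#' Textures never visited contribute zero to the per-texture averages.
#'
#' @param trace a `kinematic_trace` (constant timestep).
#' @param speed_threshold minimum speed counted as scanning (m/s),
#'   default 0.01.
#' @param speed_axis `"y"` (scanning-axis speed, default) or `"3d"` (full
#'   speed magnitude) for the thresholding and speed outcome.
#' @return List of class `trial_kinematics` with `scanning_duration`,
#'   `path_length`, `mean_scanning_speed` and the per-texture breakdown
#'   `per_texture`.
#' @export
trial_kinematics <- function(trace, speed_threshold = 0.01,
                             speed_axis = c("y", "3d")) {
  speed_axis <- match.arg(speed_axis)
  stopifnot(is.data.frame(trace), nrow(trace) >= 2)
  dt <- attr(trace, "dt")
  if (is.null(dt)) dt <- trace$time_s[2] - trace$time_s[1]
  steps <- diff(trace$time_s)
  if (max(abs(steps - dt)) > 1e-9)
    stop("trace timestep is not constant")

  speed <- if (speed_axis == "y") abs(trace$vy)
  else sqrt(trace$vx^2 + trace$vy^2 + trace$vz^2)

  if (!any(trace$contact)) {
    warning("trace has no contact samples; all outcomes are zero")
    out <- list(scanning_duration = 0, path_length = 0,
                mean_scanning_speed = 0,
                per_texture = data.frame(texture_id = 1:3, duration = 0,
                                         path = 0))
    class(out) <- "trial_kinematics"
    return(out)
  }

  per <- data.frame(texture_id = 1:3, duration = 0, path = 0)
  dy <- c(0, abs(diff(trace$y)))
  for (k in 1:3) {
    on_k <- trace$contact & !is.na(trace$texture_id) & trace$texture_id == k
    per$duration[k] <- sum(on_k & speed > speed_threshold) * dt
    per$path[k] <- sum(dy[on_k])
  }
  moving <- trace$contact & speed > speed_threshold
  out <- list(scanning_duration = mean(per$duration),
              path_length = mean(per$path),
              mean_scanning_speed = if (any(moving)) mean(speed[moving]) else 0,
              per_texture = per)
  class(out) <- "trial_kinematics"
  out
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat(sprintf(paste0("Trial kinematics: duration %.3f s, path %.3f m, ",
                     "speed %.3f m/s\n"),
              x$scanning_duration, x$path_length, x$mean_scanning_speed))
  invisible(x)
}
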