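#' Calibrate the pixel-to-metre scale from a reference object
#'
#' High-speed video is calibrated against an object of known size in frame
#' (the petri-dish diameter in the assay geometry).
#'
#' @param reference_px apparent size of the reference in pixels, > 0.
#' @param reference_mm true size of the reference in millimetres, > 0.
#' @return scale in metres per pixel.
#' @examples
#' calibrate_scale(450, 90)  # 90 mm dish spanning 450 px -> 2e-4 m/px
#' @export
calibrate_scale <- function(reference_px, reference_mm) {
  stopifnot(is.numeric(reference_px), is.numeric(reference_mm))
  if (any(reference_px <= 0) || any(reference_mm <= 0)) {
    stop("scale reference must be positive", call. = FALSE)
  }
  mm_to_m(reference_mm) / reference_px
}

#' A digitized track of one subject
#'
#' Ordered pixel coordinates of one tracked body (ball or termite) with the
#' acquisition metadata needed to calibrate them. Image coordinates follow
#' the video convention (y grows downward); [direction_angle()] accounts for
#' this when computing signed angles.
#'
#' @param frame integer frame indices, strictly increasing, 0-based with
#'   index 0 = first post-impact frame.
#' @param x_px,y_px pixel coordinates, same length as `frame`.
#' @param frame_rate frames per second, > 0.
#' @param scale metres per pixel, > 0; see [calibrate_scale()].
#' @param body_axis length-2 numeric, body-axis direction at impact in image
#'   coordinates (need not be unit length); optional.
#' @return object of class `track`.
#' @export
track <- function(frame, x_px, y_px, frame_rate, scale, body_axis = NULL) {
  stopifnot(length(frame) == length(x_px), length(x_px) == length(y_px))
  if (length(frame) < 2) stop("a track needs >= 2 points", call. = FALSE)
  if (any(diff(frame) <= 0)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (frame_rate <= 0 || scale <= 0) {
    stop("frame_rate and scale must be > 0", call. = FALSE)
  }
  structure(list(frame = frame, x_px = x_px, y_px = y_px,
                 frame_rate = frame_rate, scale = scale,
                 body_axis = body_axis),
            class = "track")
}

#' Post-impact speed from the first inter-frame interval
#'
#' Forward difference over the first two samples of the post-impact track:
#' Euclidean pixel displacement, converted by the scale, divided by the
#' elapsed time implied by the frame-index gap and frame rate. No smoothing
#' is applied before differencing.
#'
#' @param tr a [track()].
#' @return speed (m/s).
#' @export
first_interval_speed <- function(tr) {
  stopifnot(inherits(tr, "track"))
  gap <- tr$frame[2] - tr$frame[1]
  if (gap <= 0) stop("coincident frame indices", call. = FALSE)
  disp_px <- sqrt((tr$x_px[2] - tr$x_px[1])^2 + (tr$y_px[2] - tr$y_px[1])^2)
  disp_px * tr$scale * tr$frame_rate / gap
}

#' Rotation rate from counted rotations
#'
#' Post-impact termite spin is too fast for frame-by-frame angle tracking at
#' 1,000 fps, so it is measured as full rotations counted over a time window.
#'
#' @param rotations number of full rotations (may be fractional), >= 0.
#' @param duration_s observation window (s), > 0.
#' @return angular speed (rad/s).
#' @export
rotation_rate <- function(rotations, duration_s) {
  stopifnot(is.numeric(rotations), is.numeric(duration_s))
  if (any(duration_s <= 0)) stop("duration must be > 0", call. = FALSE)
  2 * pi * rotations / duration_s
}

#' Direction angle of a displacement relative to the body axis
#'
#' Angle of deviation of a movement direction (e.g. the struck ball's) from
#' the termite's body axis: the unsigned angle in \[0, 180\] degrees via the
#' normalized dot product, plus the side via the 2D cross product with left
#' positive. Inputs are image coordinates (y-down); the cross product is
#' evaluated after flipping to the mathematical y-up convention so that
#' "left of the body axis" matches the anatomical meaning.
#'
#' @param displacement length-2 numeric, displacement vector.
#' @param body_axis length-2 numeric, body-axis direction.
#' @param y_down TRUE (default) when vectors are in image coordinates
#'   (y grows downward, the digitized-video input boundary); FALSE for
#'   mathematical y-up vectors. Only the side label depends on this.
#' @return list with `angle_deg` in \[0, 180\], `side` ("left", "right" or
#'   "on-axis"), and `signed_deg` (positive left).
#' @export
direction_angle <- function(displacement, body_axis, y_down = TRUE) {
  stopifnot(length(displacement) == 2, length(body_axis) == 2)
  nd <- sqrt(sum(displacement^2))
  na_ <- sqrt(sum(body_axis^2))
  if (nd == 0 || na_ == 0) {
    stop("zero-length vector has no direction", call. = FALSE)
  }
  cosang <- sum(displacement * body_axis) / (nd * na_)
  angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  # z of the 2D cross product in y-up convention; flip y first if image coords
  flip <- if (y_down) -1 else 1
  cross <- body_axis[1] * (flip * displacement[2]) -
    (flip * body_axis[2]) * displacement[1]
  side <- if (abs(cross) < 1e-12 * nd * na_) "on-axis"
          else if (cross > 0) "left" else "right"
  list(angle_deg = angle, side = side,
       signed_deg = if (side == "right") -angle else angle)
}

#' Convert a pair of digitized tracks into a ball-strike observation
#'
#' Measurement layer feeding the energy inversion: ball and termite speeds
#' from the first post-impact interval, termite rotation rate from counted
#' rotations, and the ball's deflection angle from the body axis.
#'
#' @param ball_track,termite_track [track()] objects.
#' @param rotations full termite rotations counted over `rotation_window_s`.
#' @param rotation_window_s duration of the rotation count window (s).
#' @return list with `v_b`, `v_t` (m/s), `omega_t` (rad/s), and `angle_deg`
#'   (unsigned, degrees; NA if the ball track has no body axis).
#' @export
measure_ball_strike <- function(ball_track, termite_track,
                                rotations = 0, rotation_window_s = 0.05) {
  v_b <- first_interval_speed(ball_track)
  v_t <- first_interval_speed(termite_track)
  omega_t <- rotation_rate(rotations, rotation_window_s)
  angle <- NA_real_
  if (!is.null(ball_track$body_axis)) {
    disp <- c(ball_track$x_px[2] - ball_track$x_px[1],
              ball_track$y_px[2] - ball_track$y_px[1])
    angle <- direction_angle(disp, ball_track$body_axis)$angle_deg
  }
  list(v_b = v_b, v_t = v_t, omega_t = omega_t, angle_deg = angle)
}
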