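#' One ball-strike event
#'
#' In a ball-strike experiment a small metal ball (2.25 mg, similar to the
#' termite's own mass) is placed in front of a soldier; the mandible snap
#' sends ball and termite moving apart. The post-impact linear speeds of both
#' bodies and the termite's rotation rate, together with the termite's
#' cylinder moment of inertia, are the observables from which the snap energy
#' is reconstructed by energy conservation.
#'
#' @param v_b ball post-impact linear speed (m/s), >= 0.
#' @param v_t termite post-impact linear speed (m/s), >= 0.
#' @param omega_t termite post-impact angular speed (rad/s), >= 0.
#' @param m_t termite body mass (kg), > 0.
#' @param i_t termite moment of inertia (kg m^2), >= 0; see [compute_it()].
#' @param m_b ball mass (kg), default [default_ball_mass()].
#' @param angle_deg ball movement direction relative to the body axis
#'   (degrees, in \[-180, 180\]), optional.
#' @return object of class `ball_strike_event`.
#' @export
ball_strike_event <- function(v_b, v_t, omega_t, m_t, i_t,
                              m_b = default_ball_mass(), angle_deg = NA) {
  stopifnot(is.numeric(v_b), is.numeric(v_t), is.numeric(omega_t))
  if (m_b <= 0 || m_t <= 0) stop("masses must be > 0", call. = FALSE)
  if (v_b < 0 || v_t < 0 || omega_t < 0 || i_t < 0) {
    stop("speeds, omega_t and i_t must be >= 0", call. = FALSE)
  }
  if (!is.na(angle_deg) && (angle_deg < -180 || angle_deg > 180)) {
    stop("angle_deg must lie in [-180, 180]", call. = FALSE)
  }
  structure(list(m_b = m_b, v_b = v_b, m_t = m_t, v_t = v_t,
                 i_t = i_t, omega_t = omega_t, angle_deg = angle_deg),
            class = "ball_strike_event")
}

#' Total post-impact kinetic energy of a ball-strike event
#'
#' Energy-conservation bookkeeping: the snap energy released by the mandible
#' equals the sum of the linear kinetic energies of ball and termite and the
#' termite's rotational kinetic energy,
#' \deqn{E_A = \tfrac12 M_B V_B^2 + \tfrac12 M_T V_T^2 +
#'             \tfrac12 I_T \omega_T^2.}
#' Air resistance, friction, and ball rotation are assumed lossless/absent by
#' default, making the estimate conservative. For sensitivity analysis a ball
#' rotation term (solid sphere, \eqn{I_B = \tfrac25 M_B r_B^2}) can be added.
#'
#' @param e a [ball_strike_event()].
#' @param include_ball_rotation add a ball spin term (default FALSE, the
#'   published assumption).
#' @param omega_b ball spin rate (rad/s), used only when
#'   `include_ball_rotation` is TRUE.
#' @param r_b ball radius (m), default 0.35 mm (0.7 mm diameter pen ball).
#' @return kinetic energy (J).
#' @export
event_kinetic_energy <- function(e, include_ball_rotation = FALSE,
                                 omega_b = 0, r_b = mm_to_m(0.35)) {
  stopifnot(inherits(e, "ball_strike_event"))
  ke <- 0.5 * e$m_b * e$v_b^2 + 0.5 * e$m_t * e$v_t^2 +
    0.5 * e$i_t * e$omega_t^2
  if (include_ball_rotation) {
    ke <- ke + 0.5 * (0.4 * e$m_b * r_b^2) * omega_b^2
  }
  ke
}

#' Tip velocity from snap energy (energy-conservation inversion)
#'
#' Inverts the rotational energy relation using the inertia model
#' \eqn{I_A = K M_A L_A^2}:
#' \deqn{V_{MT} = L_A \omega_A = \sqrt{2 E_A / (M_A K)}}
#'
#' @param e_a snap energy (J), >= 0.
#' @param m_a anterior mandible mass (kg), > 0.
#' @param k dimensionless inertia constant, > 0; see [compute_k()].
#' @return tip speed (m/s).
#' @export
invert_tip_velocity <- function(e_a, m_a, k) {
  stopifnot(is.numeric(e_a), is.numeric(m_a), is.numeric(k))
  if (any(e_a < 0)) stop("snap energy must be >= 0", call. = FALSE)
  if (any(m_a <= 0) || any(k <= 0)) stop("m_a and k must be > 0", call. = FALSE)
  sqrt(2 * e_a / (m_a * k))
}

#' Snap force implied by a reconstructed tip velocity
#'
#' Assumes the mandible struck at its peak velocity, reached `t_a` seconds
#' after snap initiation, and chains the kinematic relations
#' (\eqn{\omega_A = V_{MT}/L_A}, \eqn{\alpha_A = \omega_A/t_A},
#' \eqn{F_A = \tfrac13 M_A L_A \alpha_A}); the length cancels:
#' \deqn{F_A = M_A V_{MT} / (3 t_A)}
#'
#' @param v_mt tip speed (m/s).
#' @param m_a anterior mandible mass (kg).
#' @param t_a time to peak velocity (s), default [default_t_a()].
#' @return force (N).
#' @export
strike_force_from_event <- function(v_mt, m_a, t_a = default_t_a()) {
  stopifnot(is.numeric(v_mt), is.numeric(m_a), is.numeric(t_a))
  if (any(t_a <= 0)) stop("t_a must be > 0", call. = FALSE)
  m_a * v_mt / (3 * t_a)
}

#' Strike-angle precision summary
#'
#' Summarises ball deflection angles (absolute deviation from the body axis,
#' degrees) and tests their normality with a Shapiro-Wilk test (Royston's
#' algorithm via [stats::shapiro.test()]). A non-rejected normality test with
#' a well-defined mean indicates a particular hitting zone, i.e. a precise
#' strike; raw (non-circular) statistics are used since angles concentrate
#' far from the 0/360 wrap.
#'
#' @param angles_deg numeric vector of angles in degrees, length >= 3.
#' @return object of class `strike_angle_summary`: `n`, `mean_deg`, `sd_deg`,
#'   `min_deg`, `max_deg`, `w` (Shapiro-Wilk statistic), `p`.
#' @export
strike_angle_summary <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (length(angles_deg) < 3) {
    stop("insufficient data: need >= 3 angles for a normality test",
         call. = FALSE)
  }
  if (any(!is.finite(angles_deg))) {
    stop("angles must be finite", call. = FALSE)
  }
  sw <- stats::shapiro.test(angles_deg)
  structure(
    list(n = length(angles_deg), mean_deg = mean(angles_deg),
         sd_deg = stats::sd(angles_deg), min_deg = min(angles_deg),
         max_deg = max(angles_deg), w = unname(sw$statistic),
         p = sw$p.value),
    class = "strike_angle_summary"
  )
}

#' @export
print.strike_angle_summary <- function(x, ...) {
  cat(sprintf(
    "Strike angles: n = %d, %.1f +- %.1f deg (range %.1f-%.1f)\n",
    x$n, round_half_up(x$mean_deg), round_half_up(x$sd_deg),
    round_half_up(x$min_deg), round_half_up(x$max_deg)))
  cat(sprintf("Shapiro-Wilk: W = %.2f, p = %.2f\n", x$w, x$p))
  invisible(x)
}

#' Reconstruct snap performance for a table of ball-strike events
#'
#' Applies [event_kinetic_energy()], [invert_tip_velocity()] and
#' [strike_force_from_event()] row-wise to a calibrated event table.
#'
#' @param events data.frame with SI columns `v_b`, `v_t`, `omega_t`, `m_t`,
#'   `i_t` and optionally `m_b` (default ball mass used when absent) and
#'   `angle_deg`.
#' @param morph a [mandible_morphometry()] object supplying `m_a` and K.
#' @param t_a assumed time to peak velocity (s), default [default_t_a()].
#' @return the events data.frame with added SI columns `e_a`, `v_mt`, `f_a`.
#' @export
ball_strike_performance <- function(events, morph, t_a = default_t_a()) {
  stopifnot(is.data.frame(events), inherits(morph, "mandible_morphometry"))
  need <- c("v_b", "v_t", "omega_t", "m_t", "i_t")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols)) {
    stop("ball-strike table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m_b <- if ("m_b" %in% names(events)) events$m_b else default_ball_mass()
  k <- compute_k(morph)
  events$e_a <- 0.5 * m_b * events$v_b^2 + 0.5 * events$m_t * events$v_t^2 +
    0.5 * events$i_t * events$omega_t^2
  events$v_mt <- invert_tip_velocity(events$e_a, morph$m_a, k)
  events$f_a <- strike_force_from_event(events$v_mt, morph$m_a, t_a)
  events
}
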