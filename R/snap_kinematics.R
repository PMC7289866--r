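#' Mandible tip linear velocity
#'
#' \deqn{V_{MT} = L_A \omega_A}
#'
#' @param l_a length of the rotating anterior part (m), > 0.
#' @param omega_a angular velocity (rad/s), >= 0. Vectorised.
#' @return tip speed (m/s).
#' @export
tip_velocity <- function(l_a, omega_a) {
  stopifnot(is.numeric(l_a), is.numeric(omega_a))
  if (any(l_a <= 0)) stop("l_a must be > 0", call. = FALSE)
  l_a * omega_a
}

#' Mean angular acceleration of the snap
#'
#' \deqn{\alpha_A = \omega_A / t_A}
#' where `t_a` is the time from snap initiation to peak angular velocity.
#'
#' @param omega_a peak angular velocity (rad/s).
#' @param t_a time to peak (s), > 0; defaults to [default_t_a()].
#' @return mean angular acceleration (rad/s^2).
#' @export
angular_acceleration <- function(omega_a, t_a = default_t_a()) {
  stopifnot(is.numeric(omega_a), is.numeric(t_a))
  if (any(t_a <= 0)) stop("invalid duration: t_a must be > 0", call. = FALSE)
  omega_a / t_a
}

#' Snap force of the accelerating mandible
#'
#' Force exerted by a uniform rod of mass `m_a` and length `l_a` under mean
#' angular acceleration `alpha_a`:
#' \deqn{F_A = \tfrac13 M_A L_A \alpha_A}
#'
#' @param m_a total mass of the anterior part (kg).
#' @param l_a length of the anterior part (m).
#' @param alpha_a mean angular acceleration (rad/s^2).
#' @return force (N).
#' @export
snap_force <- function(m_a, l_a, alpha_a) {
  stopifnot(is.numeric(m_a), is.numeric(l_a), is.numeric(alpha_a))
  m_a * l_a * alpha_a / 3
}

#' Rotational kinetic energy of the snap
#'
#' \deqn{E_A = \tfrac12 I_A \omega_A^2}
#'
#' @param i_a moment of inertia of the anterior part about the pivot (kg m^2).
#' @param omega_a angular velocity (rad/s).
#' @return energy (J).
#' @export
snap_energy <- function(i_a, omega_a) {
  stopifnot(is.numeric(i_a), is.numeric(omega_a))
  if (any(i_a < 0)) stop("i_a must be >= 0", call. = FALSE)
  0.5 * i_a * omega_a^2
}

#' Force-to-body-weight ratio
#'
#' Impact force divided by body weight (mass times standard gravity), the
#' dimensionless metric used for cross-species comparison of power-amplified
#' strikes (typically quoted in thousands of BW).
#'
#' @param f_a force (N).
#' @param m_t body mass (kg), > 0.
#' @param g gravitational acceleration (m/s^2), default [standard_gravity()].
#' @return dimensionless ratio.
#' @export
force_to_bodyweight <- function(f_a, m_t, g = standard_gravity()) {
  stopifnot(is.numeric(f_a), is.numeric(m_t))
  if (any(m_t <= 0)) stop("m_t must be > 0", call. = FALSE)
  f_a / (m_t * g)
}

#' Peak angular velocity and its time from a sampled series
#'
#' Extracts the peak of an angular-velocity time series digitized from
#' ultrahigh-speed footage. Ties are broken by the earliest time.
#'
#' @param time_s sample times (s), strictly increasing, starting at snap
#'   initiation (time 0 allowed).
#' @param omega angular velocity samples (rad/s), same length.
#' @return list with `omega_a` (peak, rad/s) and `t_a` (its time, s).
#' @export
peak_from_series <- function(time_s, omega) {
  if (length(time_s) == 0 || length(omega) == 0) {
    stop("empty angular-velocity series", call. = FALSE)
  }
  stopifnot(length(time_s) == length(omega))
  if (any(diff(time_s) <= 0)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  i <- which.max(omega)  # which.max returns the first maximum: earliest tie
  list(omega_a = omega[i], t_a = time_s[i])
}

#' Per-event snap performance from angular measurements
#'
#' Chains the kinematic relations for a set of snap events measured with an
#' ultrahigh-speed camera: tip velocity, mean angular acceleration, force,
#' energy, and body-weight ratio.
#'
#' @param omega_a peak angular velocities (rad/s), one per event.
#' @param t_a times to peak (s); recycled; default [default_t_a()].
#' @param morph a [mandible_morphometry()] object (cohort-mean or individual).
#' @param m_t body mass (kg) for the body-weight ratio; `NA` to skip.
#' @return data.frame with columns `omega_a`, `t_a`, `v_mt`, `alpha_a`,
#'   `f_a`, `e_a`, and `f_bw` (NA when `m_t` is NA), all in SI units.
#' @export
snap_performance <- function(omega_a, t_a = default_t_a(), morph, m_t = NA) {
  stopifnot(inherits(morph, "mandible_morphometry"))
  inertia <- mandible_inertia(morph)
  alpha <- angular_acceleration(omega_a, t_a)
  f <- snap_force(morph$m_a, morph$l_a, alpha)
  data.frame(
    omega_a = omega_a,
    t_a = rep_len(t_a, length(omega_a)),
    v_mt = tip_velocity(morph$l_a, omega_a),
    alpha_a = alpha,
    f_a = f,
    e_a = snap_energy(inertia$i_a, omega_a),
    f_bw = if (all(is.na(m_t))) NA_real_ else force_to_bodyweight(f, m_t)
  )
}

#' Cohort summary in mean +- sd (range) style
#'
#' Sample statistics of a per-individual or per-event metric: mean, sample
#' standard deviation (n - 1 denominator), minimum and maximum. This is the
#' single path through which all cohort tables are produced, so that the
#' caveat "mean of per-event values differs from the value at mean inputs" is
#' handled in one place.
#'
#' @param x numeric vector, NAs dropped.
#' @return list with `n`, `mean`, `sd` (NA when n < 2), `min`, `max`.
#' @export
cohort_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no non-missing values to summarise", call. = FALSE)
  list(n = length(x), mean = mean(x),
       sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       min = min(x), max = max(x))
}

#' Summarise behavioural phase durations
#'
#' Mean and sample standard deviation of phase durations (e.g. the elastic
#' loading phase during which the right mandible presses on the left),
#' reported in milliseconds.
#'
#' @param durations_ms numeric vector of durations (ms), length >= 2.
#' @return list with `n`, `mean_ms`, `sd_ms`.
#' @export
summarize_durations <- function(durations_ms) {
  durations_ms <- durations_ms[!is.na(durations_ms)]
  if (length(durations_ms) < 2) {
    stop("need at least 2 durations for mean +- sd", call. = FALSE)
  }
  list(n = length(durations_ms), mean_ms = mean(durations_ms),
       sd_ms = stats::sd(durations_ms))
}
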