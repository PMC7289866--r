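#' Simulation configuration for the synthetic-data generator
#'
#' The generator forward-simulates every input table the pipeline consumes —
#' morphometry, ultrahigh-speed snap events, ball-strike events (with
#' digitized tracks), and defence trials — with known ground truth, so each
#' stage can be tested without the original recordings. Defaults describe a
#' realistic soldier cohort: body mass 3.22 +- 0.12 mg, body length
#' 6.06 +- 0.075 mm, anterior mandible 28 ug split 8.5/19.5 ug between the
#' distal and proximal subsections, anterior length 1.06 +- 0.0375 mm,
#' ultrahigh-speed peak angular velocity centred on 12.8e4 rad/s, ball-strike
#' tip velocity lognormal with mean 60.4 and sd 12.0 m/s, and per-species
#' defence rates at the published pooled proportions.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical tables.
#' @param n_individuals morphometry cohort size (default 17).
#' @param n_events number of ball-strike events (default 92).
#' @param n_ultra number of ultrahigh-speed snap events (default 2).
#' @param morph list of truncated-normal means/sds (reporting units):
#'   `m_t_mg`, `sd_m_t_mg`, `l_t_mm`, `sd_l_t_mm`, `m_a1_ug`, `sd_m_a1_ug`,
#'   `m_a2_ug`, `sd_m_a2_ug`, `l_a_mm`, `sd_l_a_mm`.
#' @param omega_mean,omega_sd mean and sd (rad/s) of the lognormal
#'   ultrahigh-speed peak angular velocity.
#' @param v_mt_mean,v_mt_sd mean and sd (m/s) of the lognormal true
#'   ball-strike tip velocity.
#' @param partition_weights length-3 non-negative weights summing to 1:
#'   expected energy shares of (ball translation, termite translation,
#'   termite rotation).
#' @param partition_concentration Dirichlet concentration (weights are
#'   multiplied by this to give the Dirichlet alpha).
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   measurement noise on tracked velocities (masses are weighed and get no
#'   noise).
#' @param angle_mean,angle_sd strike-angle truncated normal (degrees,
#'   truncated to \[0, 180\]).
#' @param defence data.frame of per-species true rates with columns
#'   `species`, `encounters_per_trial` (Poisson mean), `attack_rate`,
#'   `snaps_per_trial` (Poisson mean), `hit_prob`, `kill_prob`,
#'   `immob_prob`; plus `n_trials` trials per species.
#' @param n_trials fight trials per species (default 6).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_individuals = 17L,
    n_events = 92L,
    n_ultra = 2L,
    morph = list(m_t_mg = 3.22, sd_m_t_mg = 0.12,
                 l_t_mm = 6.06, sd_l_t_mm = 0.075,
                 m_a1_ug = 8.5, sd_m_a1_ug = 0.85,
                 m_a2_ug = 19.5, sd_m_a2_ug = 1.95,
                 l_a_mm = 1.06, sd_l_a_mm = 0.0375),
    omega_mean = 12.8e4, omega_sd = 1.3e4,
    v_mt_mean = 60.4, v_mt_sd = 12.0,
    partition_weights = c(ball = 0.65, termite_translation = 0.30,
                          termite_rotation = 0.05),
    partition_concentration = 40,
    noise_cv = 0.05,
    angle_mean = 52.9, angle_sd = 22.7,
    defence = default_defence_rates(),
    n_trials = 6L) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  sds <- unlist(morph[grepl("^sd_", names(morph))])
  if (any(sds < 0) || omega_sd < 0 || v_mt_sd < 0 || noise_cv < 0 ||
      angle_sd < 0) {
    stop("standard deviations and noise_cv must be >= 0", call. = FALSE)
  }
  means <- unlist(morph[!grepl("^sd_", names(morph))])
  if (any(means <= 0)) {
    stop("config error: infeasible truncation, morphometry means must be > 0",
         call. = FALSE)
  }
  if (any(partition_weights < 0) ||
      abs(sum(partition_weights) - 1) > 1e-9) {
    stop("partition weights must be non-negative and sum to 1", call. = FALSE)
  }
  rates <- unlist(defence[c("attack_rate", "hit_prob", "kill_prob",
                            "immob_prob")])
  if (any(rates < 0 | rates > 1)) {
    stop("defence rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(seed = seed, n_individuals = as.integer(n_individuals),
                 n_events = as.integer(n_events),
                 n_ultra = as.integer(n_ultra), morph = morph,
                 omega_mean = omega_mean, omega_sd = omega_sd,
                 v_mt_mean = v_mt_mean, v_mt_sd = v_mt_sd,
                 partition_weights = partition_weights,
                 partition_concentration = partition_concentration,
                 noise_cv = noise_cv, angle_mean = angle_mean,
                 angle_sd = angle_sd, defence = defence,
                 n_trials = as.integer(n_trials)),
            class = "simulation_config")
}

#' Default per-species defence rates
#'
#' True rates of the four assayed ant species (two generalists, two ponerine
#' specialists) at the published pooled proportions; snaps per trial have no
#' published total and default to a Poisson mean of 5.
#'
#' @return data.frame of per-species rate parameters.
#' @export
default_defence_rates <- function() {
  data.frame(
    species = c("Ph_megacephala", "Anop_gracilipes", "Anoc_taiwaniensis",
                "Pa_javanus"),
    encounters_per_trial = c(93, 107, 300, 143) / 6,
    attack_rate = c(8 / 93, 18 / 107, 102 / 300, 33 / 143),
    snaps_per_trial = 5,
    hit_prob = c(0.83, 0.13, 0.30, 0.41),
    kill_prob = c(1.0, 0.9, 0.0, 0.0),
    immob_prob = c(0, 0, 2 / 24, 0),
    stringsAsFactors = FALSE
  )
}

# Truncated-normal draw by CDF inversion (deterministic given the RNG state).
rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm((lower - mean) / sd)
  hi <- stats::pnorm((upper - mean) / sd)
  stats::qnorm(stats::runif(n, lo, hi)) * sd + mean
}

# Lognormal draw parameterised by arithmetic mean and sd.
rlnorm_meansd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Dirichlet draw via normalised gammas; zero weights give exact zeros.
rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) if (a == 0) 0 else stats::rgamma(1, a),
              numeric(1))
  if (sum(g) == 0) stop("degenerate Dirichlet draw", call. = FALSE)
  g / sum(g)
}

#' Generate a synthetic morphometry table
#'
#' Truncated-normal (lower bound 0) draws of per-individual body mass, body
#' length, mandible subsection masses and anterior length, in the CSV
#' dialect's reporting units.
#'
#' @param cfg a [simulation_config()].
#' @return data.frame with columns `individual_id`, `m_t_mg`, `l_t_mm`,
#'   `m_a1_ug`, `m_a2_ug`, `l_a_mm`.
#' @export
gen_morphometry <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- cfg$n_individuals
  p <- cfg$morph
  data.frame(
    individual_id = sprintf("T%02d", seq_len(n)),
    m_t_mg = rtruncnorm(n, p$m_t_mg, p$sd_m_t_mg),
    l_t_mm = rtruncnorm(n, p$l_t_mm, p$sd_l_t_mm),
    m_a1_ug = rtruncnorm(n, p$m_a1_ug, p$sd_m_a1_ug),
    m_a2_ug = rtruncnorm(n, p$m_a2_ug, p$sd_m_a2_ug),
    l_a_mm = rtruncnorm(n, p$l_a_mm, p$sd_l_a_mm),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic ultrahigh-speed snap events
#'
#' Lognormal peak angular velocities with the default time-to-peak, in the
#' snap-event CSV dialect.
#'
#' @param cfg a [simulation_config()].
#' @param morphometry a morphometry table from [gen_morphometry()].
#' @return data.frame with columns `individual_id`, `omega_a_rad_s`,
#'   `t_a_us`.
#' @export
gen_snap_events <- function(cfg, morphometry = gen_morphometry(cfg)) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- cfg$n_ultra
  ids <- rep_len(morphometry$individual_id, n)
  data.frame(
    individual_id = ids,
    omega_a_rad_s = rlnorm_meansd(n, cfg$omega_mean, cfg$omega_sd),
    t_a_us = s_to_us(default_t_a()),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic ball-strike events with hidden truth
#'
#' For each event a true tip velocity is drawn, converted to a true snap
#' energy through the cohort inertia model, partitioned into ball
#' translation, termite translation and termite rotation by a Dirichlet
#' draw, and expressed as the post-impact observables. Multiplicative
#' Gaussian noise (`noise_cv`) is applied to the three tracked velocities;
#' with `noise_cv = 0` the events invert exactly to the hidden truth.
#'
#' @param cfg a [simulation_config()].
#' @param morphometry a morphometry table from [gen_morphometry()].
#' @param tracks also emit digitized two-frame pixel tracks per event that
#'   regenerate the stated velocities through the track-processing layer.
#' @return list with `events` (CSV dialect: `individual_id`, `event_id`,
#'   `v_b_m_s`, `v_t_m_s`, `omega_t_rad_s`, `angle_deg`, `m_b_mg`,
#'   `m_t_mg`, `l_t_mm`), `truth` (per-event `v_mt_true_m_s`,
#'   `e_a_true_uj`, energy shares), `morph` (the cohort-mean
#'   [mandible_morphometry()] used), and optionally `tracks` (long
#'   data.frame: `event_id`, `subject`, `frame`, `x_px`, `y_px`) with
#'   `track_meta` (frame_rate, scale).
#' @export
gen_ball_strike_events <- function(cfg, morphometry = gen_morphometry(cfg),
                                   tracks = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2L, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- cfg$n_events
  morph <- cohort_mandible(morphometry)
  k <- compute_k(morph)
  row <- rep_len(seq_len(nrow(morphometry)), n)
  m_t <- mg_to_kg(morphometry$m_t_mg[row])
  l_t <- mm_to_m(morphometry$l_t_mm[row])
  i_t <- compute_it(m_t, l_t)
  m_b <- default_ball_mass()

  v_true <- rlnorm_meansd(n, cfg$v_mt_mean, cfg$v_mt_sd)
  e_true <- 0.5 * morph$m_a * k * v_true^2
  alpha <- cfg$partition_weights * cfg$partition_concentration
  shares <- t(vapply(seq_len(n), function(i) rdirichlet1(alpha), numeric(3)))
  v_b <- sqrt(2 * e_true * shares[, 1] / m_b)
  v_t <- sqrt(2 * e_true * shares[, 2] / m_t)
  omega_t <- sqrt(2 * e_true * shares[, 3] / i_t)
  if (cfg$noise_cv > 0) {
    v_b <- v_b * (1 + cfg$noise_cv * stats::rnorm(n))
    v_t <- v_t * (1 + cfg$noise_cv * stats::rnorm(n))
    omega_t <- omega_t * (1 + cfg$noise_cv * stats::rnorm(n))
    v_b <- pmax(v_b, 0); v_t <- pmax(v_t, 0); omega_t <- pmax(omega_t, 0)
  }
  angle <- rtruncnorm(n, cfg$angle_mean, cfg$angle_sd, 0, 180)

  events <- data.frame(
    individual_id = morphometry$individual_id[row],
    event_id = sprintf("E%03d", seq_len(n)),
    v_b_m_s = v_b, v_t_m_s = v_t, omega_t_rad_s = omega_t,
    angle_deg = angle, m_b_mg = kg_to_mg(m_b),
    m_t_mg = morphometry$m_t_mg[row], l_t_mm = morphometry$l_t_mm[row],
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    event_id = events$event_id,
    v_mt_true_m_s = v_true, e_a_true_uj = uj_from_j(e_true),
    share_ball = shares[, 1], share_translation = shares[, 2],
    share_rotation = shares[, 3],
    stringsAsFactors = FALSE
  )
  out <- list(events = events, truth = truth, morph = morph)
  if (tracks) {
    frame_rate <- 1000
    scale <- calibrate_scale(450, 90)  # 90 mm dish spanning 450 px
    mk <- function(event_id, subject, v, ang_deg) {
      # y-down image coords; body axis along +x
      theta <- ang_deg * pi / 180
      d_px <- v / (scale * frame_rate)
      data.frame(event_id = event_id, subject = subject, frame = 0:1,
                 x_px = c(0, d_px * cos(theta)),
                 y_px = c(0, -d_px * sin(theta)),  # left of axis in y-down
                 stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, lapply(seq_len(n), function(i) rbind(
      mk(events$event_id[i], "ball", v_b[i], angle[i]),
      mk(events$event_id[i], "termite", v_t[i], 180 + angle[i])
    )))
    out$tracks <- tr
    out$track_meta <- list(frame_rate = frame_rate, scale = scale,
                           body_axis = c(1, 0))
  }
  out
}

#' Cohort-mean mandible morphometry from a table
#'
#' Pools subsection masses and the anterior length across the cohort, the
#' standard guard against weighing error on sub-microgram cut parts.
#'
#' @param morphometry data.frame with columns `m_a1_ug`, `m_a2_ug`, `l_a_mm`.
#' @return a [mandible_morphometry()] with provenance `"cohort-mean"`.
#' @export
cohort_mandible <- function(morphometry) {
  mandible_morphometry(
    m_a1 = ug_to_kg(mean(morphometry$m_a1_ug)),
    m_a2 = ug_to_kg(mean(morphometry$m_a2_ug)),
    l_a = mm_to_m(mean(morphometry$l_a_mm)),
    provenance = "cohort-mean"
  )
}

#' Generate synthetic defence trials
#'
#' Per species and trial: encounters and snaps are Poisson counts; attacks,
#' hits, kills and immobilisations are binomial thinnings at the configured
#' true rates (attacks of encounters, hits of snaps, kills of hits,
#' immobilisations of non-lethal hits), so every count invariant of the
#' defence table holds by construction.
#'
#' @param cfg a [simulation_config()].
#' @return data.frame with columns `species`, `trial_id`, `encounters`,
#'   `attacks`, `snaps`, `hits`, `kills`, `immobilised`.
#' @export
gen_defence_trials <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 3L, kind = "Mersenne-Twister", normal.kind = "Inversion")
  d <- cfg$defence
  rows <- lapply(seq_len(nrow(d)), function(i) {
    enc <- stats::rpois(cfg$n_trials, d$encounters_per_trial[i])
    snp <- stats::rpois(cfg$n_trials, d$snaps_per_trial[i])
    att <- stats::rbinom(cfg$n_trials, enc, d$attack_rate[i])
    hit <- stats::rbinom(cfg$n_trials, snp, d$hit_prob[i])
    kil <- stats::rbinom(cfg$n_trials, hit, d$kill_prob[i])
    imm <- stats::rbinom(cfg$n_trials, hit - kil, d$immob_prob[i])
    data.frame(species = d$species[i], trial_id = seq_len(cfg$n_trials),
               encounters = enc, attacks = att, snaps = snp, hits = hit,
               kills = kil, immobilised = imm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
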