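test_that("gen_morphometry is deterministic and respects its config", {
  cfg <- simulation_config(seed = 1)
  a <- gen_morphometry(cfg)
  b <- gen_morphometry(simulation_config(seed = 1))
  expect_identical(a, b)
  expect_false(identical(a, gen_morphometry(simulation_config(seed = 2))))
  expect_equal(nrow(a), 17)
  # all sds zero -> every row equals the configured means
  flat <- simulation_config(seed = 3, morph = list(
    m_t_mg = 3.22, sd_m_t_mg = 0, l_t_mm = 6.06, sd_l_t_mm = 0,
    m_a1_ug = 8.5, sd_m_a1_ug = 0, m_a2_ug = 19.5, sd_m_a2_ug = 0,
    l_a_mm = 1.06, sd_l_a_mm = 0))
  f <- gen_morphometry(flat)
  expect_true(all(f$m_t_mg == 3.22) && all(f$l_a_mm == 1.06))
  # column means within 3 sd/sqrt(n) brackets of the configured means
  big <- gen_morphometry(simulation_config(seed = 4, n_individuals = 500))
  expect_lt(abs(mean(big$m_t_mg) - 3.22), 3 * 0.12 / sqrt(500))
  expect_lt(abs(mean(big$l_a_mm) - 1.06), 3 * 0.0375 / sqrt(500))
  expect_error(simulation_config(morph = list(
    m_t_mg = -1, sd_m_t_mg = 0, l_t_mm = 1, sd_l_t_mm = 0,
    m_a1_ug = 1, sd_m_a1_ug = 0, m_a2_ug = 1, sd_m_a2_ug = 0,
    l_a_mm = 1, sd_l_a_mm = 0)), "infeasible truncation")
})

test_that("generated tables pass every consuming module's validation", {
  cfg <- simulation_config(seed = 9, n_individuals = 8, n_events = 30)
  morph <- gen_morphometry(cfg)
  expect_silent(cohort_mandible(morph))
  for (r in seq_len(nrow(morph))) {
    expect_silent(mandible_morphometry(ug_to_kg(morph$m_a1_ug[r]),
                                       ug_to_kg(morph$m_a2_ug[r]),
                                       mm_to_m(morph$l_a_mm[r])))
  }
  bs <- gen_ball_strike_events(cfg, morph)
  prepared <- prepare_ball_strike(bs$events, morph)
  expect_silent(ball_strike_performance(prepared, bs$morph))
  def <- gen_defence_trials(cfg)
  expect_silent(pool_defence_trials(def))
})

test_that("noiseless events invert exactly to the hidden truth", {
  cfg <- simulation_config(seed = 5, n_events = 40, noise_cv = 0)
  morph <- gen_morphometry(cfg)
  bs <- gen_ball_strike_events(cfg, morph)
  out <- ball_strike_performance(prepare_ball_strike(bs$events, morph),
                                 bs$morph)
  expect_equal(out$v_mt, bs$truth$v_mt_true_m_s, tolerance = 1e-9)
  expect_equal(uj_from_j(out$e_a), bs$truth$e_a_true_uj, tolerance = 1e-9)
})

test_that("degenerate all-to-ball partition zeroes the termite motion", {
  cfg <- simulation_config(seed = 6, n_events = 10, noise_cv = 0,
                           partition_weights = c(1, 0, 0))
  bs <- gen_ball_strike_events(cfg)
  expect_true(all(bs$events$v_t_m_s == 0))
  expect_true(all(bs$events$omega_t_rad_s == 0))
  expect_true(all(bs$truth$share_ball == 1))
})

test_that("emitted tracks regenerate the stated velocities", {
  cfg <- simulation_config(seed = 8, n_events = 12)
  bs <- gen_ball_strike_events(cfg, tracks = TRUE)
  meta <- bs$track_meta
  for (ev in bs$events$event_id[1:5]) {
    tr <- bs$tracks[bs$tracks$event_id == ev &
                      bs$tracks$subject == "ball", ]
    btr <- track(tr$frame, tr$x_px, tr$y_px, meta$frame_rate, meta$scale,
                 body_axis = meta$body_axis)
    expect_equal(first_interval_speed(btr),
                 bs$events$v_b_m_s[bs$events$event_id == ev],
                 tolerance = 1e-9)
    disp <- c(diff(tr$x_px), diff(tr$y_px))
    expect_equal(direction_angle(disp, meta$body_axis)$angle_deg,
                 bs$events$angle_deg[bs$events$event_id == ev],
                 tolerance = 1e-6)
  }
})

test_that("defence trials recover the configured rates", {
  cfg <- simulation_config(seed = 3)
  trials <- gen_defence_trials(cfg)
  expect_identical(trials, gen_defence_trials(simulation_config(seed = 3)))
  pooled <- pool_defence_trials(trials)
  # ~300 encounters at true rate 0.34: inside a generous binomial interval
  anoc <- pooled$Anoc_taiwaniensis
  expect_gt(attack_rate(anoc), 0.28)
  expect_lt(attack_rate(anoc), 0.40)
  # zero true rates stay zero
  zero <- simulation_config(seed = 3, defence = data.frame(
    species = "none", encounters_per_trial = 20, attack_rate = 0,
    snaps_per_trial = 5, hit_prob = 0.5, kill_prob = 0, immob_prob = 0))
  expect_true(all(gen_defence_trials(zero)$attacks == 0))
})
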