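test_that("kinematic relations match hand arithmetic", {
  # tip velocity at the cohort means
  expect_equal(tip_velocity(mm_to_m(1.06), 12.8e4), 135.68)
  expect_equal(tip_velocity(1, 1), 1)
  expect_equal(tip_velocity(mm_to_m(1.06), 0), 0)
  # angular acceleration, Table-1 mean and max rows
  expect_equal(angular_acceleration(12.8e4, us_to_s(8.68)), 14.7e9,
               tolerance = 5e-3)
  expect_equal(angular_acceleration(15.3e4, us_to_s(8.68)), 17.6e9,
               tolerance = 5e-3)
  expect_equal(angular_acceleration(0), 0)
  expect_error(angular_acceleration(1e4, 0), "invalid duration")
  # force and energy
  expect_equal(snap_force(ug_to_kg(28), mm_to_m(1.06), 14.7e9), 0.14543,
               tolerance = 1e-4)
  expect_equal(snap_force(3, 1, 1), 1)
  expect_equal(snap_energy(0.56e-14, 12.8e4), 45.9e-6, tolerance = 1e-3)
  expect_equal(snap_energy(2, 1), 1)
  expect_equal(snap_energy(1, 0), 0)
  # body-weight ratio at g = 9.81
  expect_equal(force_to_bodyweight(0.1562, mg_to_kg(3.39)), 4.70e3,
               tolerance = 1e-3)
  expect_equal(force_to_bodyweight(9.81e-3, 1e-3), 1)
  expect_equal(force_to_bodyweight(0, 1e-3), 0)
})

test_that("peak_from_series finds the earliest maximum", {
  t_us <- us_to_s(c(0, 4.34, 8.68, 13.0))
  p <- peak_from_series(t_us, c(0, 6e4, 1.2e5, 9e4))
  expect_equal(p$omega_a, 1.2e5)
  expect_equal(p$t_a, us_to_s(8.68))
  single <- peak_from_series(us_to_s(2.17), 5e4)
  expect_equal(single, list(omega_a = 5e4, t_a = us_to_s(2.17)))
  # tie broken by earliest time
  tie <- peak_from_series(us_to_s(c(0, 8.68, 10.85)), c(0, 1e5, 1e5))
  expect_equal(tie$t_a, us_to_s(8.68))
  expect_error(peak_from_series(numeric(), numeric()), "empty")
  expect_error(peak_from_series(c(0, 0), c(1, 2)), "strictly increasing")
})

test_that("energy via inertia model equals energy via tip velocity", {
  # 1/2 (k m l^2) w^2 == 1/2 k m (l w)^2 for arbitrary inputs
  set.seed(7)
  for (i in 1:25) {
    m <- mandible_morphometry(runif(1, 1e-9, 2e-8), runif(1, 1e-9, 3e-8),
                              runif(1, 5e-4, 2e-3))
    w <- runif(1, 1e3, 2e5)
    k <- compute_k(m)
    expect_equal(snap_energy(compute_ia(m, k), w),
                 0.5 * k * m$m_a * tip_velocity(m$l_a, w)^2,
                 tolerance = 1e-12)
  }
})

test_that("performance metrics are strictly increasing in omega", {
  m <- fixture_mandible()
  omega <- seq(1e4, 2e5, length.out = 40)
  perf <- snap_performance(omega, morph = m, m_t = mg_to_kg(3.22))
  for (col in c("v_mt", "alpha_a", "f_a", "e_a", "f_bw")) {
    expect_true(all(diff(perf[[col]]) > 0), info = col)
  }
})

test_that("mean of per-event outputs differs from output at mean inputs", {
  # the cohort-table reconciliation caveat: nonlinear chains do not commute
  # with averaging when inputs vary
  m <- fixture_mandible()
  omega <- c(10.2e4, 15.3e4)
  perf <- snap_performance(omega, morph = m)
  e_of_mean <- snap_energy(mandible_inertia(m)$i_a, mean(omega))
  expect_false(isTRUE(all.equal(mean(perf$e_a), e_of_mean)))
  expect_gt(mean(perf$e_a), e_of_mean)  # Jensen: energy is convex in omega
})

test_that("cohort_summary and summarize_durations use sample statistics", {
  s <- cohort_summary(c(200, 300))
  expect_equal(s$mean, 250)
  expect_equal(s$sd, sqrt(5000))  # n - 1 denominator: 70.71
  expect_equal(c(s$min, s$max), c(200, 300))
  d <- summarize_durations(rep(261.3, 10))
  expect_equal(d$sd_ms, 0)
  expect_equal(d$mean_ms, 261.3)
  expect_error(summarize_durations(250), "at least 2")
  set.seed(5)
  sim <- summarize_durations(rnorm(10, 261.3, 43.1))
  expect_gt(sim$mean_ms, 220)  # 3-sigma window for n = 10
  expect_lt(sim$mean_ms, 300)
})
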