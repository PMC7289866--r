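test_that("the simulated pipeline is deterministic end to end", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- list(seed = 7, simulate = list(n_individuals = 6, n_events = 20))
  run_pipeline(cfg, out_dir = d1)
  run_pipeline(cfg, out_dir = d2)
  for (f in c("report.json", "report.txt", "events.csv", "defence.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the report
  run_pipeline(list(seed = 8, simulate = cfg$simulate), out_dir = d2)
  expect_false(identical(readLines(file.path(d1, "report.json")),
                         readLines(file.path(d2, "report.json"))))
})

test_that("the file-input route reproduces the simulated route", {
  d <- withr::local_tempdir()
  sim <- simulation_config(seed = 12, n_individuals = 5, n_events = 15)
  morph <- gen_morphometry(sim)
  paths <- list(
    morphometry = file.path(d, "morph.csv"),
    snap_events = file.path(d, "snap.csv"),
    ball_strike = file.path(d, "ball.csv"),
    defence = file.path(d, "defence.csv"))
  write.csv(morph, paths$morphometry, row.names = FALSE)
  write.csv(gen_snap_events(sim, morph), paths$snap_events, row.names = FALSE)
  write.csv(gen_ball_strike_events(sim, morph)$events, paths$ball_strike,
            row.names = FALSE)
  write.csv(gen_defence_trials(sim), paths$defence, row.names = FALSE)

  from_files <- run_pipeline(list(seed = 12, inputs = paths))
  simulated <- run_pipeline(list(seed = 12,
                                 simulate = list(n_individuals = 5,
                                                 n_events = 15)))
  expect_equal(from_files$strike$v_mt$mean, simulated$strike$v_mt$mean,
               tolerance = 1e-9)
  expect_equal(from_files$defence$table, simulated$defence$table)
})

test_that("schema violations fail with the offending column named", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "morph.csv")
  write.csv(data.frame(individual_id = "T1", m_t_mg = 3.2), bad,
            row.names = FALSE)
  expect_error(read_morphometry(bad), "missing column.*l_t_mm")
  neg <- file.path(d, "neg.csv")
  write.csv(data.frame(individual_id = "T1", m_t_mg = -3.2, l_t_mm = 6,
                       m_a1_ug = 8, m_a2_ug = 19, l_a_mm = 1), neg,
            row.names = FALSE)
  expect_error(read_morphometry(neg), "line 2.*m_t_mg")
  expect_error(run_pipeline(list(seed = 1)), "config error")
})

test_that("snap-event reader honours series files and defaults", {
  d <- withr::local_tempdir()
  write.csv(data.frame(time_s = c(0, 4.34e-6, 8.68e-6, 1.3e-5),
                       omega = c(0, 6e4, 1.2e5, 9e4)),
            file.path(d, "series1.csv"), row.names = FALSE)
  write.csv(data.frame(individual_id = c("T1", "T2"),
                       omega_a_rad_s = c(1e4, 1e4),
                       t_a_us = c(NA, 5),
                       series_file = c("series1.csv", "")),
            file.path(d, "snap.csv"), row.names = FALSE)
  df <- read_snap_events(file.path(d, "snap.csv"))
  expect_equal(df$omega_a_rad_s[1], 1.2e5)  # peak overrides the column
  expect_equal(df$t_a_us[1], 8.68)
  expect_equal(df$t_a_us[2], 5)             # explicit value kept
})

test_that("tracks round-trip through the side-car config", {
  d <- withr::local_tempdir()
  write.csv(data.frame(event_id = "E1", subject = "ball", frame = 0:1,
                       x_px = c(0, 10), y_px = c(0, 0)),
            file.path(d, "tracks.csv"), row.names = FALSE)
  writeLines(c("frame_rate: 1000", "reference_px: 450", "reference_mm: 90",
               "body_axis: [1, 0]"), file.path(d, "tracks.yaml"))
  tl <- read_tracks(file.path(d, "tracks.csv"))
  expect_equal(tl$scale, 2e-4)
  tr <- track(tl$tracks$frame, tl$tracks$x_px, tl$tracks$y_px,
              tl$frame_rate, tl$scale)
  expect_equal(first_interval_speed(tr), 2)
})

test_that("every reported unit string matches the converter applied", {
  report <- run_pipeline(list(seed = 4,
                              simulate = list(n_individuals = 5,
                                              n_events = 12)))
  registry <- snapmech:::report_unit_registry()
  expect_equal(report$body$m_t$unit, registry$m_t$unit)
  expect_equal(report$ultra$alpha_a$unit, registry$alpha_a$unit)
  expect_equal(report$strike$e_a$unit, registry$e_a$unit)
  # value audit: the reported mean is the registry conversion of the SI mean
  morph <- gen_morphometry(simulation_config(seed = 4, n_individuals = 5,
                                             n_events = 12))
  expect_equal(report$body$m_t$mean,
               registry$m_t$from_si(mean(mg_to_kg(morph$m_t_mg))))
  expect_equal(report$strike$e_a$mean,
               registry$e_a$from_si(mean(report$events$e_a)))
})

test_that("the CLI runs, writes outputs, and fails loudly on bad input", {
  cli <- system.file("cli", "snapmech.R", package = "snapmech")
  d <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  # the child must see the same library tree this session loaded snapmech from
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2(rscript,
                    c(cli, "simulate", "--seed", "3", "--out-dir",
                      shQuote(d), "--log-level", "quiet"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  expect_true(all(file.exists(file.path(
    d, c("morphometry.csv", "ball_strike.csv", "ball_strike_truth.csv",
         "defence.csv", "tracks.csv")))))
  status_bad <- system2(rscript, c(cli, "report", "--config",
                                   shQuote(file.path(d, "missing.yaml"))),
                        stdout = FALSE, stderr = FALSE)
  expect_gt(status_bad, 0L)
})
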