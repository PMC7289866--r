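#' Run the full snap-biomechanics pipeline
#'
#' Executes morphometry -> inertia model -> ultrahigh-speed kinematics ->
#' ball-strike energy inversion -> strike-angle summary -> defence
#' statistics, from either a seeded simulation or CSV inputs, and returns a
#' cohort report. The report deliberately carries two versions of the force
#' and energy summaries: the mean of per-event values and the value computed
#' at mean inputs — the two differ whenever inputs covary, and conflating
#' them is a classic reconciliation trap in cohort tables.
#'
#' @param config a configuration list, or a path to a YAML or JSON file
#'   holding one. Recognised fields: `seed` (integer); either `simulate`
#'   (a list of [simulation_config()] overrides, may be empty) or `inputs`
#'   (list of paths: `morphometry`, `snap_events`, `ball_strike`,
#'   `defence`); optional `out_dir` to write `report.json`, `report.txt`,
#'   `events.csv`, `defence.csv`.
#' @param out_dir output directory, overrides the config field; `NULL`
#'   writes nothing.
#' @return (invisibly) an object of class `cohort_report`.
#' @export
run_pipeline <- function(config = list(simulate = list()), out_dir = NULL) {
  cfg <- load_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  provenance <- list(seed = seed, package = "snapmech",
                     version = as.character(utils::packageVersion("snapmech")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."))
  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(simulation_config, c(list(seed = seed), cfg$simulate))
    morph_tab <- gen_morphometry(sim_cfg)
    snap_tab <- gen_snap_events(sim_cfg, morph_tab)
    bs <- gen_ball_strike_events(sim_cfg, morph_tab)
    ball_tab <- bs$events
    defence_tab <- gen_defence_trials(sim_cfg)
    provenance$source <- "simulation"
    provenance$simulate <- cfg$simulate
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    for (f in c("morphometry", "snap_events", "ball_strike", "defence")) {
      if (is.null(inp[[f]])) {
        stop("config error: inputs$", f, " is required", call. = FALSE)
      }
    }
    morph_tab <- read_morphometry(inp$morphometry)
    snap_tab <- read_snap_events(inp$snap_events)
    ball_tab <- read_ball_strike(inp$ball_strike)
    defence_tab <- read_defence(inp$defence)
    provenance$source <- "files"
    provenance$inputs <- inp
    provenance$md5 <- as.list(tools::md5sum(unlist(inp)))
  } else {
    stop("config error: need either a 'simulate' or an 'inputs' block",
         call. = FALSE)
  }

  report <- build_cohort_report(morph_tab, snap_tab, ball_tab, defence_tab,
                                provenance)
  if (!is.null(out_dir)) write_cohort_report(report, out_dir)
  invisible(report)
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config: ", config, call. = FALSE)
    if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a list or a file path", call. = FALSE)
  }
}

#' Assemble a cohort report from the four validated tables
#'
#' @param morph_tab,snap_tab,ball_tab,defence_tab validated tables in the
#'   CSV dialects (see the `read_*` readers or the generators).
#' @param provenance list recorded verbatim in the report.
#' @return object of class `cohort_report`.
#' @export
build_cohort_report <- function(morph_tab, snap_tab, ball_tab, defence_tab,
                                provenance = list()) {
  morph <- cohort_mandible(morph_tab)
  inertia <- mandible_inertia(morph)
  units <- report_unit_registry()
  su <- function(metric, x_si) {  # cohort summary in the registry's unit
    s <- cohort_summary(units[[metric]]$from_si(x_si))
    c(s, unit = units[[metric]]$unit)
  }

  body <- list(
    m_t = su("m_t", mg_to_kg(morph_tab$m_t_mg)),
    l_t = su("l_t", mm_to_m(morph_tab$l_t_mm)),
    m_a = su("m_a", ug_to_kg(morph_tab$m_a1_ug + morph_tab$m_a2_ug)),
    l_a = su("l_a", mm_to_m(morph_tab$l_a_mm)),
    i_a_cohort = list(value = units$i_a$from_si(inertia$i_a),
                      unit = units$i_a$unit),
    k_cohort = inertia$k,
    l_com_mm = m_to_mm(inertia$l_com)
  )

  # ultrahigh-speed events: per-event chain through the cohort mandible
  i <- match(snap_tab$individual_id, morph_tab$individual_id)
  m_t_event <- mg_to_kg(morph_tab$m_t_mg[i])
  if (anyNA(m_t_event)) m_t_event <- NA  # unmatched ids: skip BW ratios
  perf <- snap_performance(snap_tab$omega_a_rad_s,
                           us_to_s(snap_tab$t_a_us), morph, m_t_event)
  ultra <- list(
    n = nrow(perf),
    omega_a = su("omega_a", perf$omega_a),
    alpha_a = su("alpha_a", perf$alpha_a),
    v_mt = su("v_mt", perf$v_mt),
    e_a = su("e_a", perf$e_a),
    f_a = su("f_a", perf$f_a),
    f_bw = if (!all(is.na(perf$f_bw))) su("f_bw", perf$f_bw),
    at_mean_inputs = list(
      note = paste("f_a/e_a evaluated at mean omega differ from the mean of",
                   "per-event values whenever inputs covary"),
      f_a = units$f_a$from_si(snap_force(
        morph$m_a, morph$l_a,
        angular_acceleration(mean(perf$omega_a), mean(perf$t_a)))),
      e_a = units$e_a$from_si(snap_energy(inertia$i_a, mean(perf$omega_a)))
    )
  )

  # ball-strike inversion
  prepared <- prepare_ball_strike(ball_tab, morph_tab)
  inverted <- ball_strike_performance(prepared, morph)
  angles <- inverted$angle_deg[!is.na(inverted$angle_deg)]
  strike <- list(
    n = nrow(inverted),
    e_a = su("e_a", inverted$e_a),
    v_mt = su("v_mt", inverted$v_mt),
    f_a = su("f_a", inverted$f_a),
    angle = if (length(angles) >= 3) {
      unclass(strike_angle_summary(angles))
    }
  )

  # defence statistics
  pooled <- pool_defence_trials(defence_tab)
  def_rows <- lapply(pooled, function(c) {
    pr <- hit_kill_probabilities(c)
    data.frame(species = c$species, encounters = c$encounters,
               attacks = c$attacks, snaps = c$snaps, hits = c$hits,
               kills = c$kills,
               attack_rate_pct = round_half_up(100 * attack_rate(c)),
               hit_prob_pct = round_half_up(100 * pr$hit_prob),
               kill_prob_pct = if (pr$kill_defined)
                 round_half_up(100 * pr$kill_prob) else NA_real_,
               stringsAsFactors = FALSE)
  })
  defence <- list(
    table = do.call(rbind, c(def_rows, make.row.names = FALSE)),
    fisher_hit = unclass_fisher(pairwise_fisher(pooled, "hit")),
    fisher_kill = unclass_fisher(pairwise_fisher(pooled, "kill"))
  )

  structure(list(body = body, ultra = ultra, strike = strike,
                 defence = defence, events = inverted,
                 provenance = provenance),
            class = "cohort_report")
}

unclass_fisher <- function(x) {
  list(outcome = x$outcome, m = x$m, pairs = x$pairs,
       letters = as.list(x$letters))
}

#' Write a cohort report to disk
#'
#' Emits `report.json` (machine-readable, full precision), `report.txt`
#' (human-readable, reporting units at one decimal), `events.csv` (per-event
#' ball-strike results) and `defence.csv` (pooled per-species counts and
#' rates). Output is deterministic: identical report objects give
#' byte-identical files.
#'
#' @param report a `cohort_report`.
#' @param out_dir directory, created if needed.
#' @return (invisibly) the paths written.
#' @export
write_cohort_report <- function(report, out_dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("report.json", "report.txt", "events.csv",
                                "defence.csv"))
  jsonlite::write_json(unclass(report[c("body", "ultra", "strike", "defence",
                                        "provenance")]),
                       paths[1], auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  writeLines(format_cohort_report(report), paths[2])
  utils::write.csv(report$events, paths[3], row.names = FALSE)
  utils::write.csv(report$defence$table, paths[4], row.names = FALSE)
  invisible(paths)
}

fmt_summary <- function(label, s) {
  sprintf("  %-10s %s +- %s (%s-%s) %s", label,
          format(round_half_up(s$mean), nsmall = 1),
          if (is.na(s$sd)) "NA" else format(round_half_up(s$sd), nsmall = 1),
          format(round_half_up(s$min), nsmall = 1),
          format(round_half_up(s$max), nsmall = 1), s$unit)
}

format_cohort_report <- function(report) {
  b <- report$body; u <- report$ultra; s <- report$strike
  lines <- c(
    "Snap-performance cohort report",
    "",
    "Body measurements (mean +- sd (range)):",
    fmt_summary("M_T", b$m_t), fmt_summary("L_T", b$l_t),
    fmt_summary("M_A", b$m_a), fmt_summary("L_A", b$l_a),
    sprintf("  cohort K = %.4f, L_COM = %.4f mm, I_A = %.2f %s",
            b$k_cohort, b$l_com_mm, round_half_up(b$i_a_cohort$value, 2),
            b$i_a_cohort$unit),
    "",
    sprintf("Ultrahigh-speed snap events (n = %d):", u$n),
    fmt_summary("omega_A", u$omega_a), fmt_summary("alpha_A", u$alpha_a),
    fmt_summary("V_MT", u$v_mt), fmt_summary("E_A", u$e_a),
    fmt_summary("F_A", u$f_a),
    if (!is.null(u$f_bw)) fmt_summary("F_A/BW", u$f_bw),
    sprintf("  at mean inputs: F_A = %.1f mN, E_A = %.1f uJ (caveat: %s)",
            round_half_up(u$at_mean_inputs$f_a),
            round_half_up(u$at_mean_inputs$e_a), u$at_mean_inputs$note),
    "",
    sprintf("Ball-strike events (n = %d, energy-conservation inversion):",
            s$n),
    fmt_summary("E_A", s$e_a), fmt_summary("V_MT", s$v_mt),
    fmt_summary("F_A", s$f_a))
  if (!is.null(s$angle)) {
    lines <- c(lines, sprintf(
      "  angles: %.1f +- %.1f deg (%.1f-%.1f), Shapiro-Wilk W = %.2f, p = %.2f",
      round_half_up(s$angle$mean_deg), round_half_up(s$angle$sd_deg),
      round_half_up(s$angle$min_deg), round_half_up(s$angle$max_deg),
      s$angle$w, s$angle$p))
  }
  d <- report$defence
  lines <- c(lines, "", "Defence assay (pooled across trials):")
  tab <- d$table
  for (r in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf(
      "  %-18s attack %s%% (%d/%d), hit %s%% (%d/%d), kill %s%% (%d/%d) [%s|%s]",
      tab$species[r], format(tab$attack_rate_pct[r], nsmall = 1),
      tab$attacks[r], tab$encounters[r],
      format(tab$hit_prob_pct[r], nsmall = 1), tab$hits[r], tab$snaps[r],
      ifelse(is.na(tab$kill_prob_pct[r]), "NA",
             format(tab$kill_prob_pct[r], nsmall = 1)),
      tab$kills[r], tab$hits[r],
      d$fisher_hit$letters[[tab$species[r]]],
      if (is.null(d$fisher_kill$letters[[tab$species[r]]])) "-"
      else d$fisher_kill$letters[[tab$species[r]]]))
  }
  lines <- c(lines, "",
             sprintf("Provenance: seed %s, %s v%s, source: %s",
                     report$provenance$seed, report$provenance$package,
                     report$provenance$version, report$provenance$source))
  lines
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(format_cohort_report(x), sep = "\n")
  invisible(x)
}
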