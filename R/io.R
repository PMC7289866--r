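# CSV dialects: headers required, UTF-8, decimal point. Units are encoded in
# the column names (reporting units); conversion to SI happens in the
# prepare_* helpers, never in the readers.

require_columns <- function(df, cols, file) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("validation error in %s: missing column(s) %s",
                 file, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

check_positive <- function(df, cols, file) {
  for (col in cols) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("validation error in %s, line %d: column %s must be > 0",
                   file, bad[1] + 1L, col), call. = FALSE)
    }
  }
  invisible(df)
}

read_table_checked <- function(file, cols, positive = character()) {
  if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  require_columns(df, cols, file)
  check_positive(df, positive, file)
  df
}

#' Read a morphometry CSV
#'
#' Columns: `individual_id`, `m_t_mg`, `l_t_mm`, `m_a1_ug`, `m_a2_ug`,
#' `l_a_mm`.
#'
#' @param file path to a CSV file.
#' @return validated data.frame in reporting units.
#' @export
read_morphometry <- function(file) {
  read_table_checked(
    file,
    c("individual_id", "m_t_mg", "l_t_mm", "m_a1_ug", "m_a2_ug", "l_a_mm"),
    positive = c("m_t_mg", "l_t_mm", "l_a_mm"))
}

#' Read an ultrahigh-speed snap-event CSV
#'
#' Columns: `individual_id`, `omega_a_rad_s`; optional `t_a_us` (defaults to
#' the standard 8.68 us when absent or NA) and `series_file` (path to a
#' two-column time/omega CSV, relative to the event file's directory).
#'
#' @param file path to a CSV file.
#' @return validated data.frame with a filled `t_a_us` column.
#' @export
read_snap_events <- function(file) {
  df <- read_table_checked(file, c("individual_id", "omega_a_rad_s"),
                           positive = "omega_a_rad_s")
  if (!"t_a_us" %in% names(df)) df$t_a_us <- NA_real_
  df$t_a_us[is.na(df$t_a_us)] <- s_to_us(default_t_a())
  if ("series_file" %in% names(df)) {
    base <- dirname(file)
    for (i in which(!is.na(df$series_file) & nzchar(df$series_file))) {
      series <- utils::read.csv(file.path(base, df$series_file[i]))
      peak <- peak_from_series(series[[1]], series[[2]])
      df$omega_a_rad_s[i] <- peak$omega_a
      df$t_a_us[i] <- s_to_us(peak$t_a)
    }
  }
  df
}

#' Read a ball-strike event CSV
#'
#' Columns: `individual_id`, `event_id`, `v_b_m_s`, `v_t_m_s`,
#' `omega_t_rad_s`; optional `angle_deg` and `m_b_mg` (ball mass, default
#' 2.25 mg when absent).
#'
#' @param file path to a CSV file.
#' @return validated data.frame in reporting units.
#' @export
read_ball_strike <- function(file) {
  df <- read_table_checked(
    file, c("individual_id", "event_id", "v_b_m_s", "v_t_m_s",
            "omega_t_rad_s"))
  if (!"m_b_mg" %in% names(df)) df$m_b_mg <- kg_to_mg(default_ball_mass())
  if (!"angle_deg" %in% names(df)) df$angle_deg <- NA_real_
  df
}

#' Read a defence-assay CSV
#'
#' Columns: `species`, `trial_id`, `encounters`, `attacks`, `snaps`, `hits`,
#' `kills`; optional `immobilised`.
#'
#' @param file path to a CSV file.
#' @return validated data.frame of per-trial counts.
#' @export
read_defence <- function(file) {
  df <- read_table_checked(
    file, c("species", "trial_id", "encounters", "attacks", "snaps", "hits",
            "kills"))
  if (!"immobilised" %in% names(df)) df$immobilised <- NA_integer_
  counts <- c("encounters", "attacks", "snaps", "hits", "kills")
  for (col in counts) {
    bad <- which(df[[col]] < 0 | df[[col]] != floor(df[[col]]))
    if (length(bad)) {
      stop(sprintf(
        "validation error in %s, line %d: column %s must be a count",
        file, bad[1] + 1L, col), call. = FALSE)
    }
  }
  df
}

#' Read digitized tracks and their side-car configuration
#'
#' Track CSV columns: `event_id`, `subject` (`ball` or `termite`), `frame`,
#' `x_px`, `y_px`. The side-car YAML carries `frame_rate`, a scale reference
#' (`reference_px`, `reference_mm`) and `body_axis` (length-2).
#'
#' @param file path to the track CSV.
#' @param config path to the side-car YAML; defaults to `file` with the
#'   extension replaced by `.yaml`.
#' @return list with the track data.frame (`tracks`) and calibration
#'   metadata (`frame_rate`, `scale`, `body_axis`).
#' @export
read_tracks <- function(file, config = sub("\\.csv$", ".yaml", file)) {
  df <- read_table_checked(file, c("event_id", "subject", "frame", "x_px",
                                   "y_px"))
  if (!file.exists(config)) stop("no such config: ", config, call. = FALSE)
  meta <- yaml::read_yaml(config)
  for (field in c("frame_rate", "reference_px", "reference_mm")) {
    if (is.null(meta[[field]])) {
      stop("validation error in ", config, ": missing field ", field,
           call. = FALSE)
    }
  }
  list(tracks = df, frame_rate = meta$frame_rate,
       scale = calibrate_scale(meta$reference_px, meta$reference_mm),
       body_axis = if (is.null(meta$body_axis)) c(1, 0)
                   else as.numeric(meta$body_axis))
}

#' Join ball-strike events to morphometry and convert to SI
#'
#' Adds per-individual body mass and cylinder moment of inertia to each
#' event and converts all observables to SI, producing the input expected by
#' [ball_strike_performance()].
#'
#' @param events ball-strike table in reporting units (see [read_ball_strike()]).
#' @param morphometry morphometry table (see [read_morphometry()]).
#' @return data.frame with SI columns `v_b`, `v_t`, `omega_t`, `m_t`, `i_t`,
#'   `m_b` plus identifiers and `angle_deg`.
#' @export
prepare_ball_strike <- function(events, morphometry) {
  i <- match(events$individual_id, morphometry$individual_id)
  if (anyNA(i)) {
    stop("validation error: event individual_id not in morphometry table: ",
         paste(unique(events$individual_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  m_t <- mg_to_kg(morphometry$m_t_mg[i])
  l_t <- mm_to_m(morphometry$l_t_mm[i])
  data.frame(
    individual_id = events$individual_id, event_id = events$event_id,
    v_b = events$v_b_m_s, v_t = events$v_t_m_s,
    omega_t = events$omega_t_rad_s,
    m_t = m_t, i_t = compute_it(m_t, l_t), m_b = mg_to_kg(events$m_b_mg),
    angle_deg = events$angle_deg, stringsAsFactors = FALSE
  )
}
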