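#' Unit converters between reporting units and strict SI
#'
#' All internal computation in snapmech is done in strict SI (kg, m, s, J, N,
#' rad/s). Input tables and reports use the mixed units conventional in insect
#' biomechanics (micrograms, milligrams, millimetres, microseconds,
#' microjoules, millinewtons). These converters are the only place where unit
#' scaling happens; every reader and report formatter goes through them.
#'
#' @param x numeric vector in the source unit.
#' @return numeric vector in the target unit.
#' @examples
#' ug_to_kg(28)        # 2.8e-08 kg
#' mn_from_n(0.1312)   # 131.2 mN
#' @name units
NULL

#' @rdname units
#' @export
ug_to_kg <- function(x) x * 1e-9

#' @rdname units
#' @export
mg_to_kg <- function(x) x * 1e-6

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
us_to_s <- function(x) x * 1e-6

#' @rdname units
#' @export
ms_to_s <- function(x) x * 1e-3

#' @rdname units
#' @export
kg_to_ug <- function(x) x * 1e9

#' @rdname units
#' @export
kg_to_mg <- function(x) x * 1e6

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

#' @rdname units
#' @export
s_to_us <- function(x) x * 1e6

#' @rdname units
#' @export
uj_from_j <- function(x) x * 1e6

#' @rdname units
#' @export
mn_from_n <- function(x) x * 1e3

#' Round half away from zero at a fixed number of decimals
#'
#' Reporting convention: reported values are printed to one decimal with
#' ties rounded up (half-up), unlike [base::round()]'s round-half-even. A tiny
#' epsilon (1e-9 relative to the shifted value) guards against binary
#' representation of exact halves such as 111.05. Internal values are never
#' rounded; this is a formatting-layer function only.
#'
#' @param x numeric vector.
#' @param digits integer, decimals to keep (default 1).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(111.05)   # 111.1 (round() would give 111)
#' round_half_up(16.8224)  # 16.8
#' @export
round_half_up <- function(x, digits = 1) {
  shifted <- abs(x) * 10^digits
  sign(x) * floor(shifted + 0.5 + 1e-9 * pmax(1, shifted)) / 10^digits
}

#' Standard gravity used for body-weight ratios
#'
#' @return standard gravitational acceleration, 9.81 m/s^2.
#' @export
standard_gravity <- function() 9.81

#' Default time to peak angular velocity
#'
#' Four inter-frame intervals of ultrahigh-speed footage at 460,830 fps,
#' i.e. 8.68 microseconds. Used as the per-event default for force
#' reconstruction when no angular-velocity series is available.
#'
#' @return default t_A in seconds (8.68e-6).
#' @export
default_t_a <- function() 8.68e-6

#' Default metal ball mass in ball-strike experiments
#'
#' @return ball mass in kg (2.25 mg ballpoint-pen ball).
#' @export
default_ball_mass <- function() mg_to_kg(2.25)

# Unit registry for report fields: maps a reported metric to the unit string
# and the converter applied from SI. Tested by the unit-audit test.
report_unit_registry <- function() {
  list(
    m_t    = list(unit = "mg",            from_si = kg_to_mg),
    l_t    = list(unit = "mm",            from_si = m_to_mm),
    m_a    = list(unit = "ug",            from_si = kg_to_ug),
    l_a    = list(unit = "mm",            from_si = m_to_mm),
    i_a    = list(unit = "1e-14 kg m^2",  from_si = function(x) x * 1e14),
    t_a    = list(unit = "us",            from_si = s_to_us),
    v_mt   = list(unit = "m/s",           from_si = identity),
    omega_a = list(unit = "1e4 rad/s",    from_si = function(x) x * 1e-4),
    alpha_a = list(unit = "1e9 rad/s^2",  from_si = function(x) x * 1e-9),
    e_a    = list(unit = "uJ",            from_si = uj_from_j),
    f_a    = list(unit = "mN",            from_si = mn_from_n),
    f_bw   = list(unit = "1e3 BW",        from_si = function(x) x * 1e-3)
  )
}
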