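#' Mandible morphometry of the rotating anterior left mandible
#'
#' The soldier's twisted left mandible stores the elastic energy and does the
#' striking; only its anterior part (length `l_a`) rotates about the pivot.
#' Because the mandible is too irregular for a standard geometric inertia
#' formula, the anterior part is cut into a distal subsection A1 and a
#' proximal subsection A2 whose masses enter a two-point-mass model of the
#' moment of inertia.
#'
#' @param m_a1 mass of the distal subsection A1 (kg), >= 0.
#' @param m_a2 mass of the proximal subsection A2 (kg), >= 0.
#' @param l_a length of the rotating anterior part (m), > 0.
#' @param provenance `"individual"` if subsection masses come from this
#'   individual, `"cohort-mean"` if they are pooled cohort means (subsection
#'   masses are routinely pooled across cut mandibles to limit weighing
#'   error at the sub-microgram scale).
#' @return an object of class `mandible_morphometry` with fields `m_a1`,
#'   `m_a2`, `m_a` (= m_a1 + m_a2), `l_a`, `provenance`.
#' @examples
#' m <- mandible_morphometry(m_a1 = ug_to_kg(8.5), m_a2 = ug_to_kg(19.5),
#'                           l_a = mm_to_m(1.06), provenance = "cohort-mean")
#' compute_k(m)
#' @export
mandible_morphometry <- function(m_a1, m_a2, l_a,
                                 provenance = c("individual", "cohort-mean")) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(m_a1), is.numeric(m_a2), is.numeric(l_a))
  if (!is.finite(m_a1) || !is.finite(m_a2) || !is.finite(l_a)) {
    stop("invalid morphometry: non-finite input", call. = FALSE)
  }
  if (m_a1 < 0 || m_a2 < 0) {
    stop("invalid morphometry: subsection masses must be non-negative",
         call. = FALSE)
  }
  if (m_a1 + m_a2 <= 0) {
    stop("invalid morphometry: total anterior mass m_a1 + m_a2 must be > 0",
         call. = FALSE)
  }
  if (l_a <= 0) {
    stop("invalid morphometry: anterior length l_a must be > 0", call. = FALSE)
  }
  structure(
    list(m_a1 = m_a1, m_a2 = m_a2, m_a = m_a1 + m_a2, l_a = l_a,
         provenance = provenance),
    class = "mandible_morphometry"
  )
}

#' @export
print.mandible_morphometry <- function(x, ...) {
  cat("Mandible morphometry (", x$provenance, ")\n", sep = "")
  cat(sprintf("  m_a1 = %.3f ug, m_a2 = %.3f ug, m_a = %.3f ug, l_a = %.3f mm\n",
              kg_to_ug(x$m_a1), kg_to_ug(x$m_a2), kg_to_ug(x$m_a),
              m_to_mm(x$l_a)))
  invisible(x)
}

#' Centre of mass of the anterior mandible part
#'
#' Places each subsection's mass at the midpoint of its half of the anterior
#' part (A2 spans the proximal half, centroid at l_a/4; A1 the distal half,
#' centroid at 3 l_a/4):
#' \deqn{L_{COM} = (\tfrac14 L_A M_{A2} + \tfrac34 L_A M_{A1}) / M_A}
#'
#' @param m a [mandible_morphometry()] object.
#' @return centre-of-mass distance from the pivot (m), strictly between
#'   `l_a/4` and `3*l_a/4`.
#' @export
compute_lcom <- function(m) {
  stopifnot(inherits(m, "mandible_morphometry"))
  (0.25 * m$l_a * m$m_a2 + 0.75 * m$l_a * m$m_a1) / m$m_a
}

#' Dimensionless inertia constant K of the anterior mandible part
#'
#' Adjusts the point-mass inertia formula for the mandible's inhomogeneous
#' mass distribution:
#' \deqn{K = \frac{M_{A2}}{M_A}\left(\frac{L_{COM}}{2L_A}\right)^2 +
#'           \frac{M_{A1}}{M_A}\left(\frac{L_{COM}+L_A}{2L_A}\right)^2}
#' With `l_com` from [compute_lcom()], K lies in \[1/64, 49/64\], the limits
#' attained when all mass is proximal (m_a1 = 0) or distal (m_a2 = 0). Note
#' the lever arms are `l_com/2` and `(l_com + l_a)/2`, not the subsection
#' centroids; this model is kept exactly as published (see the methods
#' vignette for discussion).
#'
#' @inheritParams compute_lcom
#' @param l_com centre-of-mass location (m); defaults to [compute_lcom()].
#' @return dimensionless K.
#' @export
compute_k <- function(m, l_com = compute_lcom(m)) {
  stopifnot(inherits(m, "mandible_morphometry"))
  if (!is.finite(l_com) || l_com <= 0 || l_com >= m$l_a) {
    stop("invalid geometry: l_com must lie strictly inside (0, l_a)",
         call. = FALSE)
  }
  (m$m_a2 / m$m_a) * (l_com / (2 * m$l_a))^2 +
    (m$m_a1 / m$m_a) * ((l_com + m$l_a) / (2 * m$l_a))^2
}

#' Moment of inertia of the anterior mandible part about the pivot
#'
#' \deqn{I_A = K M_A L_A^2}
#'
#' @inheritParams compute_lcom
#' @param k dimensionless inertia constant; defaults to [compute_k()].
#' @return moment of inertia (kg m^2).
#' @export
compute_ia <- function(m, k = compute_k(m)) {
  stopifnot(inherits(m, "mandible_morphometry"), is.numeric(k), k >= 0)
  k * m$m_a * m$l_a^2
}

#' Full inertia model for a mandible
#'
#' Convenience wrapper chaining [compute_lcom()], [compute_k()] and
#' [compute_ia()].
#'
#' @inheritParams compute_lcom
#' @return an object of class `inertia_model` with fields `l_com`, `k`, `i_a`.
#' @export
mandible_inertia <- function(m) {
  l_com <- compute_lcom(m)
  k <- compute_k(m, l_com)
  structure(list(l_com = l_com, k = k, i_a = compute_ia(m, k)),
            class = "inertia_model")
}

#' @export
print.inertia_model <- function(x, ...) {
  cat(sprintf("Inertia model: l_com = %.4f mm, K = %.4f, I_A = %.3g kg m^2\n",
              m_to_mm(x$l_com), x$k, x$i_a))
  invisible(x)
}

#' Whole-body moment of inertia of a termite
#'
#' The termite body is modelled as a uniform cylinder rotating about its
#' centre of mass:
#' \deqn{I_T = \tfrac{1}{12} M_T L_T^2}
#'
#' @param m_t body mass (kg), > 0.
#' @param l_t body length (m), > 0.
#' @return moment of inertia (kg m^2).
#' @export
compute_it <- function(m_t, l_t) {
  stopifnot(is.numeric(m_t), is.numeric(l_t))
  if (any(m_t <= 0) || any(l_t <= 0)) {
    stop("invalid body: m_t and l_t must be > 0", call. = FALSE)
  }
  m_t * l_t^2 / 12
}

#' Termite body description
#'
#' @inheritParams compute_it
#' @return object of class `termite_body` with fields `m_t`, `l_t`, `i_t`.
#' @export
termite_body <- function(m_t, l_t) {
  structure(list(m_t = m_t, l_t = l_t, i_t = compute_it(m_t, l_t)),
            class = "termite_body")
}
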