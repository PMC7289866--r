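# Shared fixtures and independent oracles, built in code at test time.

# the 10/18 ug, 1.06 mm worked mandible used across modules
fixture_mandible <- function() {
  mandible_morphometry(m_a1 = ug_to_kg(10), m_a2 = ug_to_kg(18),
                       l_a = mm_to_m(1.06))
}

# cohort-mean mandible matching the published cohort inertia (K ~ 0.177)
cohort_fixture_mandible <- function() {
  mandible_morphometry(m_a1 = ug_to_kg(8.5), m_a2 = ug_to_kg(19.5),
                       l_a = mm_to_m(1.06), provenance = "cohort-mean")
}

# independent two-point-mass oracle for I_A: explicit sum of m r^2 at the
# lever arms l_com/2 and (l_com + l_a)/2
ia_two_point_oracle <- function(m) {
  l_com <- compute_lcom(m)
  m$m_a2 * (l_com / 2)^2 + m$m_a1 * ((l_com + m$l_a) / 2)^2
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher p,
# written with raw lchoose() arithmetic (independent of dhyper)
fisher_oracle <- function(s1, f1, s2, f2) {
  n1 <- s1 + f1; n2 <- s2 + f2; k <- s1 + s2
  supp <- max(0, k - n2):min(k, n1)
  p <- exp(lchoose(n1, supp) + lchoose(n2, k - supp) - lchoose(n1 + n2, k))
  sum(p[p <= p[supp == s1] * (1 + 1e-7)])
}

# truncated-normal sampler mirroring the generator's inversion scheme
sample_truncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  lo <- pnorm((lower - mean) / sd)
  hi <- pnorm((upper - mean) / sd)
  qnorm(runif(n, lo, hi)) * sd + mean
}

# tiny valid defence table (two species, two trials each)
fixture_defence_trials <- function() {
  data.frame(
    species = rep(c("gen", "pon"), each = 2),
    trial_id = rep(1:2, 2),
    encounters = c(10, 12, 20, 25),
    attacks = c(1, 2, 8, 9),
    snaps = c(5, 6, 4, 5),
    hits = c(4, 5, 1, 2),
    kills = c(4, 4, 0, 0),
    immobilised = c(0, 0, 1, 0)
  )
}
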