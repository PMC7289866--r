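#' Per-species defence counts
#'
#' Pooled tallies from staged fight trials between termite soldiers and one
#' ant species: encounters between an ant and a termite, attacks launched by
#' the ant, mandible snaps by the termite, hits landed, ants killed, and
#' (optionally) ants immobilised.
#'
#' @param species ant species label.
#' @param encounters,attacks,snaps,hits,kills non-negative integer counts
#'   with `attacks <= encounters`, `hits <= snaps`, `kills <= hits`.
#' @param immobilised optional count of ants left immobilised.
#' @return object of class `defence_counts`.
#' @export
defence_counts <- function(species, encounters, attacks, snaps, hits, kills,
                           immobilised = NA_integer_) {
  counts <- c(encounters = encounters, attacks = attacks, snaps = snaps,
              hits = hits, kills = kills)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (attacks > encounters) stop("attacks exceed encounters", call. = FALSE)
  if (hits > snaps) stop("hits exceed snaps", call. = FALSE)
  if (kills > hits) stop("kills exceed hits", call. = FALSE)
  structure(list(species = species, encounters = encounters,
                 attacks = attacks, snaps = snaps, hits = hits,
                 kills = kills, immobilised = immobilised),
            class = "defence_counts")
}

#' Ant attack rate
#'
#' Attacks per encounter, the measure used to confirm predator status.
#'
#' @param c a [defence_counts()] object.
#' @return proportion in \[0, 1\].
#' @export
attack_rate <- function(c) {
  stopifnot(inherits(c, "defence_counts"))
  if (c$encounters == 0) {
    stop("undefined rate: zero encounters", call. = FALSE)
  }
  c$attacks / c$encounters
}

#' Hitting and killing probabilities
#'
#' Hitting probability = hits per snap; killing probability = kills per hit.
#' The killing probability is undefined (NA with a flag) when no hits were
#' recorded.
#'
#' @param c a [defence_counts()] object.
#' @return list with `hit_prob`, `kill_prob` (NA when undefined) and
#'   `kill_defined` flag.
#' @export
hit_kill_probabilities <- function(c) {
  stopifnot(inherits(c, "defence_counts"))
  if (c$snaps == 0) {
    return(list(hit_prob = NA_real_, hit_defined = FALSE,
                kill_prob = NA_real_, kill_defined = FALSE))
  }
  hit <- c$hits / c$snaps
  if (c$hits == 0) {
    return(list(hit_prob = hit, hit_defined = TRUE,
                kill_prob = NA_real_, kill_defined = FALSE))
  }
  list(hit_prob = hit, hit_defined = TRUE,
       kill_prob = c$kills / c$hits, kill_defined = TRUE)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Point-probability definition: with margins fixed, the p-value is the sum
#' of hypergeometric probabilities of all tables no more probable than the
#' observed one (a relative tolerance of 1e-7 guards floating-point ties, as
#' in standard implementations). The table is
#' \preformatted{ successes_1  failures_1
#'  successes_2  failures_2 }
#'
#' @param s1,f1 successes and failures in group 1.
#' @param s2,f2 successes and failures in group 2.
#' @return two-sided p-value in \[0, 1\].
#' @export
fisher_exact_p <- function(s1, f1, s2, f2) {
  counts <- c(s1, f1, s2, f2)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  n1 <- s1 + f1
  n2 <- s2 + f2
  k <- s1 + s2
  if (n1 == 0 || n2 == 0 || k + f1 + f2 == 0) {
    stop("empty table margin", call. = FALSE)
  }
  support <- max(0, k - n2):min(k, n1)
  probs <- stats::dhyper(support, n1, n2, k)
  p_obs <- probs[match(s1, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pairwise Fisher exact tests with Bonferroni correction
#'
#' For one outcome (attack per encounter, hit per snap, or kill per hit),
#' builds the 2x2 success/failure table for every pair of species, computes
#' the two-sided Fisher exact p, and Bonferroni-adjusts within the outcome
#' family (adjusted p = min(1, m p) with m = number of pairs). A compact
#' letter display at alpha = 0.05 groups species that are not significantly
#' different.
#'
#' Pairs in which either species has a zero denominator are skipped with a
#' warning (NA p-values); such species receive their own letter group.
#'
#' @param counts list of [defence_counts()] objects, length >= 2.
#' @param outcome one of `"attack"`, `"hit"`, `"kill"`.
#' @param alpha significance level for the letter display (default 0.05).
#' @return object of class `pairwise_fisher`: data.frame `pairs` with
#'   columns `species_1`, `species_2`, `p_raw`, `p_adj`; named character
#'   vector `letters`; the `outcome`; `m` (family size).
#' @export
pairwise_fisher <- function(counts, outcome = c("attack", "hit", "kill"),
                            alpha = 0.05) {
  outcome <- match.arg(outcome)
  stopifnot(length(counts) >= 2,
            all(vapply(counts, inherits, logical(1), "defence_counts")))
  sf <- lapply(counts, function(c) {
    switch(outcome,
           attack = c(s = c$attacks, n = c$encounters),
           hit    = c(s = c$hits,   n = c$snaps),
           kill   = c(s = c$kills,  n = c$hits))
  })
  species <- vapply(counts, `[[`, character(1), "species")
  idx <- utils::combn(length(counts), 2)
  m <- ncol(idx)
  p_raw <- apply(idx, 2, function(ij) {
    a <- sf[[ij[1]]]; b <- sf[[ij[2]]]
    if (a["n"] == 0 || b["n"] == 0) {
      warning("pair ", species[ij[1]], " vs ", species[ij[2]],
              " skipped: empty margin", call. = FALSE)
      return(NA_real_)
    }
    fisher_exact_p(a["s"], a["n"] - a["s"], b["s"], b["n"] - b["s"])
  })
  pairs <- data.frame(species_1 = species[idx[1, ]],
                      species_2 = species[idx[2, ]],
                      p_raw = p_raw,
                      p_adj = pmin(1, m * p_raw))
  structure(list(outcome = outcome, m = m, pairs = pairs,
                 letters = compact_letters(species, pairs, alpha)),
            class = "pairwise_fisher")
}

# Compact letter display: species that are NOT significantly different
# (adjusted p >= alpha) must share a letter; significantly different pairs
# must not. Letters are the maximal cliques of the "not different" graph,
# enumerated by decreasing subset size (group counts are tiny, <= ~6).
compact_letters <- function(species, pairs, alpha) {
  ns <- length(species)
  adj <- matrix(TRUE, ns, ns, dimnames = list(species, species))
  for (r in seq_len(nrow(pairs))) {
    p <- pairs$p_adj[r]
    if (!is.na(p) && p < alpha) {
      i <- pairs$species_1[r]; j <- pairs$species_2[r]
      adj[i, j] <- adj[j, i] <- FALSE
    }
  }
  cliques <- list()
  covered <- matrix(FALSE, ns, ns)
  for (size in ns:1) {
    for (set in utils::combn(ns, size, simplify = FALSE)) {
      if (all(adj[set, set])) {
        sub <- covered[set, set, drop = FALSE]
        new_edge <- size == 1 || any(!sub[upper.tri(sub, diag = TRUE)])
        contained <- any(vapply(cliques, function(cl) all(set %in% cl),
                                logical(1)))
        if (new_edge && !contained) {
          cliques <- c(cliques, list(set))
          covered[set, set] <- TRUE
        }
      }
    }
  }
  lab <- stats::setNames(rep("", ns), species)
  for (i in seq_along(cliques)) {
    lab[cliques[[i]]] <- paste0(lab[cliques[[i]]], letters[i])
  }
  lab
}

#' @export
print.pairwise_fisher <- function(x, ...) {
  cat("Pairwise Fisher exact tests (", x$outcome,
      "), Bonferroni m = ", x$m, "\n", sep = "")
  print(x$pairs, row.names = FALSE)
  cat("Letters (alpha = 0.05): ",
      paste(names(x$letters), x$letters, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Pool defence trials per species
#'
#' Sums the per-trial counts of a tidy defence table (one row per trial) to
#' one [defence_counts()] per species, mirroring the pooling of repeated
#' fight trials before rate estimation.
#'
#' @param trials data.frame with columns `species`, `encounters`, `attacks`,
#'   `snaps`, `hits`, `kills`, optional `immobilised`.
#' @return named list of [defence_counts()], in order of first appearance.
#' @export
pool_defence_trials <- function(trials) {
  need <- c("species", "encounters", "attacks", "snaps", "hits", "kills")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("defence table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(unique(trials$species), function(sp) {
    d <- trials[trials$species == sp, , drop = FALSE]
    defence_counts(
      species = sp,
      encounters = sum(d$encounters), attacks = sum(d$attacks),
      snaps = sum(d$snaps), hits = sum(d$hits), kills = sum(d$kills),
      immobilised = if ("immobilised" %in% names(d)) sum(d$immobilised)
                    else NA_integer_)
  })
  stats::setNames(out, unique(trials$species))
}
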