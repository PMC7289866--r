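test_that("defence_counts enforces count invariants", {
  expect_error(defence_counts("x", 10, 11, 5, 4, 1), "attacks exceed")
  expect_error(defence_counts("x", 10, 5, 5, 6, 1), "hits exceed")
  expect_error(defence_counts("x", 10, 5, 5, 4, 5), "kills exceed")
  expect_error(defence_counts("x", -1, 0, 0, 0, 0), "non-negative")
})

test_that("rates match the published pooled proportions", {
  gen1 <- defence_counts("Ph_megacephala", 93, 8, 12, 10, 10)
  expect_equal(attack_rate(gen1), 8 / 93)
  expect_equal(round_half_up(100 * attack_rate(gen1)), 8.6)
  spec1 <- defence_counts("Anoc_taiwaniensis", 300, 102, 30, 9, 0)
  expect_equal(round_half_up(100 * attack_rate(spec1)), 34.0)
  spec2 <- defence_counts("Pa_javanus", 143, 33, 30, 12, 0)
  expect_equal(round_half_up(100 * attack_rate(spec2)), 23.1)
  expect_equal(attack_rate(defence_counts("z", 10, 0, 0, 0, 0)), 0)
  expect_error(attack_rate(defence_counts("z", 0, 0, 0, 0, 0)),
               "undefined rate")
})

test_that("hit and kill probabilities guard their denominators", {
  pr <- hit_kill_probabilities(defence_counts("x", 50, 10, 12, 10, 3))
  expect_equal(pr$hit_prob, 10 / 12)
  expect_equal(round_half_up(100 * pr$hit_prob), 83.3)
  expect_equal(pr$kill_prob, 0.3)
  zero_kill <- hit_kill_probabilities(defence_counts("x", 50, 10, 12, 7, 0))
  expect_equal(zero_kill$kill_prob, 0)
  no_snap <- hit_kill_probabilities(defence_counts("x", 50, 10, 0, 0, 0))
  expect_false(no_snap$hit_defined)
  no_hit <- hit_kill_probabilities(defence_counts("x", 50, 10, 5, 0, 0))
  expect_true(no_hit$hit_defined)
  expect_false(no_hit$kill_defined)
})

test_that("fisher_exact_p matches the enumeration oracle on known tables", {
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_p(10, 0, 0, 10), 2 / 184756)
  set.seed(31)
  for (i in 1:200) {
    t <- rmultinom(1, rpois(1, 25) + 2, runif(4, 0.05, 1))
    if (t[1] + t[2] == 0 || t[3] + t[4] == 0 || t[1] + t[3] == 0) next
    expect_equal(fisher_exact_p(t[1], t[2], t[3], t[4]),
                 fisher_oracle(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
  }
})

test_that("pairwise_fisher adjusts within the outcome family", {
  trials <- fixture_defence_trials()
  pooled <- pool_defence_trials(trials)
  expect_equal(pooled$gen$encounters, 22)   # trials are summed per species
  expect_equal(pooled$pon$hits, 3)
  pf <- pairwise_fisher(pooled, "hit")
  expect_equal(pf$m, 1)
  expect_equal(pf$pairs$p_adj, pmin(1, pf$m * pf$pairs$p_raw))
  expect_true(all(pf$pairs$p_adj >= pf$pairs$p_raw))
  expect_true(all(pf$pairs$p_raw >= 0 & pf$pairs$p_adj <= 1))
  # four species -> m = 6, and the letter display separates the extremes
  four <- list(
    defence_counts("a", 50, 5, 30, 25, 25),
    defence_counts("b", 50, 5, 30, 24, 20),
    defence_counts("c", 50, 5, 30, 4, 0),
    defence_counts("d", 50, 5, 30, 5, 0))
  pf4 <- pairwise_fisher(four, "hit")
  expect_equal(pf4$m, 6)
  ab <- pf4$pairs[pf4$pairs$species_1 == "a" & pf4$pairs$species_2 == "b", ]
  expect_equal(ab$p_adj, min(1, 6 * ab$p_raw))
  letters4 <- pf4$letters
  expect_equal(letters4[["a"]], letters4[["b"]])
  expect_false(grepl(letters4[["a"]], letters4[["c"]], fixed = TRUE))
})

test_that("zero-margin pairs are skipped with a warning", {
  counts <- list(defence_counts("a", 10, 5, 0, 0, 0),
                 defence_counts("b", 10, 5, 10, 5, 2))
  expect_warning(pf <- pairwise_fisher(counts, "hit"), "empty margin")
  expect_true(is.na(pf$pairs$p_raw))
})

test_that("rates are equivariant under pooling of trials", {
  trials <- fixture_defence_trials()
  pooled <- pool_defence_trials(trials)
  g <- trials[trials$species == "gen", ]
  expect_equal(attack_rate(pooled$gen), sum(g$attacks) / sum(g$encounters))
  expect_equal(hit_kill_probabilities(pooled$gen)$hit_prob,
               sum(g$hits) / sum(g$snaps))
})
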