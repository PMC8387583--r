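# Diagnostics: frequency-effect curves, U-shape detection, variance
# explained, distribution tables, radicalization traces, outcome tests.

test_that("frequency-effect curves bin by rank and summarize p_hat", {
  st <- make_state(freq = c(1, 2, 4, 8), n_red = c(0, 1, 2, 8))
  cv <- frequency_effect_curve(st, n_bins = 2)
  expect_equal(nrow(cv), 2)
  expect_equal(cv$n_types, c(2, 2))
  expect_equal(cv$median, c(median(c(0, 0.5)), median(c(0.5, 1))))
  expect_equal(cv$freq_max, c(2, 8))

  flat <- make_state(freq = rep(10, 12), n_red = rep(5, 12))
  cvf <- frequency_effect_curve(flat, n_bins = 3)
  expect_true(all(cvf$median == 0.5))
})

test_that("seeded generations show a monotone frequency effect", {
  # wide frequency range, no word noise, large counts: medians must rise
  lex <- lexicon(sprintf("w%02d", 1:30), round(exp(seq(log(50), log(5000),
                                                       length.out = 30))))
  st <- seed_generation(lex, seed_params(-2, 0.003, 0), seed = 4)
  cv <- frequency_effect_curve(st, n_bins = 5)
  expect_true(all(diff(cv$median) >= 0))
})

test_that("the U-shape index flags valleys and only valleys", {
  u <- make_state(freq = c(1, 2, 4, 8, 16, 32), n_red = c(1, 2, 0, 0, 16, 32))
  expect_true(ushape_index(u)$is_u)
  mono <- make_state(freq = c(1, 2, 4, 8, 16, 32), n_red = c(0, 0, 2, 4, 16, 32))
  expect_false(ushape_index(mono)$is_u)
  # seeded monotone construction never registers a U
  lex <- zipf_lexicon(90, 25, 900, seed = 2)
  for (i in 1:20) {
    st <- seed_generation(lex, seed_params(-1, 0.02, 0), seed = 300 + i)
    expect_false(ushape_index(st)$is_u)
  }
})

test_that("variance explained behaves like a squared correlation", {
  # exactly linear response
  st <- make_state(freq = c(10, 20, 30, 40), n_red = c(1, 2, 3, 4))
  st$p_hat <- st$freq / 50
  expect_equal(variance_explained(st, "raw"), 1)
  # constant response: defined as zero
  cst <- make_state(freq = c(10, 20, 30), n_red = c(5, 10, 15))
  expect_equal(variance_explained(cst, "raw"), 0)
  # invariant under affine rescaling of the predictor
  a <- make_state(freq = c(3, 7, 21, 60), n_red = c(0, 3, 15, 50))
  b <- a
  b$freq <- a$freq * 10L
  expect_equal(variance_explained(a, "raw"), variance_explained(b, "raw"))
  expect_equal(variance_explained(a, "log"), variance_explained(b, "log"))
  expect_error(variance_explained(make_state(freq = c(5, 5, 5),
                                             n_red = c(1, 2, 3)), "raw"),
               "constant")
})

test_that("log frequency outfits raw frequency on raw-driven seeds", {
  lex <- zipf_lexicon(762, 236, 2793, seed = 8)
  sp <- seed_params(-1, 0.02, 0.4)
  wins <- vapply(1:50, function(i) {
    st <- seed_generation(lex, sp, seed = 500 + i)
    variance_explained(st, "log") > variance_explained(st, "raw")
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("probability distributions bin types exactly", {
  st <- make_state(freq = rep(10, 3), n_red = c(0, 5, 10))
  d <- probability_distribution(st)
  expect_equal(sum(d$mean_count), 3)
  expect_equal(d$mean_count[d$bin == "0"], 1)
  expect_equal(d$mean_count[d$bin == "(0.45,0.55]"], 1)
  expect_equal(d$mean_count[d$bin == "1"], 1)

  # boundary values: closed on the upper edge, singletons exact
  st2 <- make_state(freq = rep(100, 4), n_red = c(5, 15, 95, 99))
  d2 <- probability_distribution(st2)
  expect_equal(d2$mean_count[d2$bin == "(0,0.05]"], 1)
  expect_equal(d2$mean_count[d2$bin == "(0.05,0.15]"], 1)
  expect_equal(d2$mean_count[d2$bin == "(0.85,0.95]"], 1)
  expect_equal(d2$mean_count[d2$bin == "(0.95,1)"], 1)

  # averaging across chains
  all1 <- make_state(freq = rep(4, 6), n_red = rep(4, 6))
  d3 <- probability_distribution(list(all1, st))
  expect_equal(sum(d3$mean_count), (6 + 3) / 2)
  expect_equal(d3$mean_count[d3$bin == "1"], (6 + 1) / 2)
})

test_that("random-effect traces recover stored modes and flag radicals", {
  lex <- headless_eth_lexicon()
  cfg <- chain_config(seed_params(-3, 0.02, 0.4), max_generations = 6,
                      master_seed = 13, keep_states = "all",
                      keep_fits = TRUE)
  ch <- run_chain(lex, cfg)
  tr <- random_effect_trace(ch, k = 2)
  gens <- as.integer(names(ch$fits))
  expect_equal(sort(unique(tr$u_paths$generation)), sort(gens))
  for (g in gens) {
    got <- tr$u_paths[tr$u_paths$generation == g, ]
    expect_equal(setNames(got$u_hat, got$word), ch$fits[[as.character(g)]]$u_hat)
  }
  expect_equal(nrow(tr$summary), length(gens))
  # radicalized words, when flagged, really sat below -2 sigma for k runs
  for (w in tr$radicalized) {
    below <- vapply(ch$fits, function(f) {
      f$sigma_hat > 0 && f$u_hat[[w]] < -2 * f$sigma_hat
    }, logical(1))
    r <- rle(below)
    expect_gte(max(r$lengths[r$values]), 2)
  }
  cfg0 <- chain_config(seed_params(-3, 0.02, 0.4), max_generations = 3,
                       master_seed = 13, keep_fits = FALSE)
  expect_error(random_effect_trace(run_chain(lex, cfg0)), "keep_fits")
})

test_that("outcome comparisons use the exact test", {
  expect_equal(outcome_comparison(c(10, 5, 85), c(10, 5, 85)), 1)
  expect_lt(outcome_comparison(c(65, 33, 2), c(0, 2, 98)), 1e-4)
  # two chains total: enumeration gives p = 1
  expect_equal(outcome_comparison(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_error(outcome_comparison(c(0, 0, 0), c(1, 1, 1)), "zero")
  expect_error(outcome_comparison(c(1, 2), c(3, 4)), "3 categories")
})
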