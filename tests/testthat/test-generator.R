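trained_hierarchy <- function(seed = 1, fac = 1, trials = 3,
                              scheme = "pitch_duration", c_thr = 5) {
  ts <- default_fixture_tokens(seed, scheme)
  m <- dm_model(alphabet_size(ts), sensitivity_factor = fac)
  for (tr in seq_len(trials)) m <- learn_sequence(m, ts$tokens, tr)$model
  ch <- extract_chunks(m, ts$tokens, c = c_thr)
  list(ts = ts, h = build_hierarchy(ts$tokens, ch, m, n_passes = trials)$hmodel)
}

test_that("generation is deterministic in the seed and honors length", {
  th <- trained_hierarchy()
  a <- generate_sequence(th$h, 40, seed = 9)
  b <- generate_sequence(th$h, 40, seed = 9)
  expect_identical(a, b)
  expect_length(a, 40)
  expect_false(identical(a, generate_sequence(th$h, 40, seed = 10)))
  expect_true(all(a >= 1 & a <= alphabet_size(th$ts)))
  expect_equal(a[1], th$ts$tokens[1])   # starts at the training start token
  expect_error(generate_sequence(th$h, 1), "length")
})

test_that("a deterministically learned cycle is reproduced verbatim", {
  cyc <- rep(1:3, 12)
  m <- dm_model(3, sensitivity_factor = 4)
  for (tr in 1:10) m <- learn_sequence(m, cyc, tr)$model
  h <- build_hierarchy(cyc, list(), m)$hmodel
  piece <- generate_sequence(h, length(cyc), seed = 3,
                             estimator = "count_ratio")
  expect_equal(piece, cyc)
})

test_that("sampling frequencies calibrate to the transition probabilities", {
  # two-symbol chain with p(2|1) = p(2|2) = 0.75 exactly (count ratios)
  m <- dm_model(2)
  m$rows <- list("1" = c(25, 75), "2" = c(25, 75))
  attr(m, "training_tokens") <- 1L
  n <- 10000
  piece <- generate_sequence(m, n + 1, seed = 77, estimator = "count_ratio")
  p_hat <- mean(piece[-1] == 2)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("bigram distributions are proper and average correctly", {
  ts <- default_fixture_tokens()
  d <- bigram_distribution(ts$tokens)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_true(all(d >= 0))
  # frequencies recomputed independently
  counts <- oracle_counts(ts$tokens, alphabet_size(ts))
  expect_equal(unname(d[paste(ts$tokens[1], ts$tokens[2])]),
               counts[ts$tokens[1], ts$tokens[2]] / (length(ts$tokens) - 1))
  # a corpus of identical pieces averages to any one piece
  avg <- average_bigram_distribution(list(ts$tokens, ts$tokens, ts$tokens))
  expect_equal(sort(names(avg)), sort(names(d)))
  expect_equal(avg[sort(names(avg))], d[sort(names(d))], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(bigram_distribution(1L), "two tokens")
})

test_that("Jensen-Shannon divergence is symmetric, bounded and smooth", {
  p <- c("1 1" = 0.6, "1 2" = 0.4)
  q <- c("1 1" = 0.1, "2 1" = 0.9)
  expect_equal(js_divergence(p, p), 0, tolerance = 1e-6)
  expect_equal(js_divergence(p, q), js_divergence(q, p))
  expect_lte(js_divergence(p, q), log(2))
  disjoint <- js_divergence(c("1 1" = 1), c("2 2" = 1))
  expect_equal(disjoint, log(2), tolerance = 1e-6)
  expect_equal(distance_to_reference(p, q), js_divergence(p, q))
})

test_that("corpus generation is reproducible piece by piece", {
  th <- trained_hierarchy()
  c1 <- generate_corpus(th$h, 5, 30, seed = 100)
  c2 <- generate_corpus(th$h, 5, 30, seed = 100)
  expect_identical(c1$pieces, c2$pieces)
  expect_length(c1$pieces, 5)
  expect_identical(c1$pieces[[2]], generate_sequence(th$h, 30, seed = 102))
})

test_that("the 2-D embedding is seeded and shaped correctly", {
  set.seed(31)
  dists <- lapply(1:6, function(i) {
    v <- prop.table(runif(9) + 0.1)
    names(v) <- paste(rep(1:3, each = 3), rep(1:3, 3))
    v
  })
  y1 <- embed_distributions(dists, seed = 4)
  y2 <- embed_distributions(dists, seed = 4)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(6, 2))
  expect_true(all(is.finite(y1)))
})
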