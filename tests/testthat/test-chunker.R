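test_that("transition scores are z-normalized over observed pairs", {
  ts <- default_fixture_tokens()
  m <- learn_sequence(dm_model(alphabet_size(ts)), ts$tokens)$model
  sc <- score_transitions(m)
  expect_gt(nrow(sc), 2)
  expect_equal(mean(sc$z_prob), 0, tolerance = 1e-9)
  expect_equal(sd(sc$z_prob), 1, tolerance = 1e-9)
  expect_equal(mean(sc$z_rel), 0, tolerance = 1e-9)
  expect_equal(sd(sc$z_rel), 1, tolerance = 1e-9)
  expect_equal(sc$product, sc$z_prob * sc$z_rel)
  # a pair maximal in both dimensions is maximal in product
  i_p <- which.max(sc$z_prob)
  if (which.max(sc$z_rel) == i_p)
    expect_equal(which.max(sc$product), i_p)
})

test_that("degenerate zero-variance score dimensions give zero z-scores", {
  # perfectly cyclic stream: every observed pair has identical stats
  m <- dm_model(3)
  m <- learn_sequence(m, c(rep(1:3, 20), 1))$model
  sc <- score_transitions(m)
  expect_true(all(abs(sc$z_prob) < 1e-12))
  expect_true(all(sc$product == 0))
})

test_that("chunk extraction is empty for untrained models and infinite c", {
  ts <- default_fixture_tokens()
  m <- dm_model(alphabet_size(ts))
  expect_equal(extract_chunks(m, ts$tokens), list())
  m <- learn_sequence(m, ts$tokens)$model
  expect_equal(extract_chunks(m, ts$tokens, c = Inf), list())
})

test_that("raising the threshold never increases the number of chunks", {
  ts <- default_fixture_tokens()
  m <- dm_model(alphabet_size(ts), sensitivity_factor = 0.25)
  for (tr in 1:5) m <- learn_sequence(m, ts$tokens, tr)$model
  counts <- vapply(c(0, 0.25, 0.5, 1, 2, 5, 10),
                   function(cc) length(extract_chunks(m, ts$tokens, c = cc)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("chunk sets match the independent brute-force oracle", {
  for (seed in 1:3) {
    mel <- make_fixture_melody(60, 8, 4, 8, seed = seed)
    for (scheme in c("pitch", "pitch_duration")) {
      ts <- tokenize(mel, scheme)
      K <- alphabet_size(ts)
      for (fac in c(0.25, 1, 4)) {
        m <- dm_model(K, sensitivity_factor = fac)
        for (tr in 1:3) m <- learn_sequence(m, ts$tokens, tr)$model
        for (cc in c(0.5, 1, 5)) {
          got <- sort(vapply(extract_chunks(m, ts$tokens, c = cc),
                             function(ch) paste(ch$tokens, collapse = " "), ""))
          want <- oracle_chunks(ts$tokens, K, prior = fac, n_passes = 3,
                                c_thr = cc)
          expect_equal(got, want,
                       info = sprintf("seed %d %s fac %g c %g",
                                      seed, scheme, fac, cc))
        }
      }
    }
  }
})

test_that("planted motif transitions dominate the chunk scores", {
  # with a rhythm-bearing alphabet the motif's internal transitions carry
  # the top reliability-x-probability products, and every chunk extracted
  # at a threshold matched to this sample length is a motif sub-phrase
  hits <- 0
  for (seed in 1:10) {
    mel <- make_fixture_melody(40, 8, 4, 5, seed = seed)
    ts <- tokenize(mel, "pitch_duration")
    motif <- ts$tokens[1:4]
    m <- dm_model(alphabet_size(ts), sensitivity_factor = 0.25)
    for (tr in 1:5) m <- learn_sequence(m, ts$tokens, tr)$model
    sc <- score_transitions(m)
    top <- sc[which.max(sc$product), ]
    expect_true(is_contiguous_sub(c(as.integer(top$context), top$symbol),
                                  motif))
    chunks <- extract_chunks(m, ts$tokens, c = 1)
    if (length(chunks)) {
      hits <- hits + 1
      for (ch in chunks)
        expect_true(is_contiguous_sub(ch$tokens, motif))
    }
  }
  expect_gte(hits, 7)
})

test_that("chunk occurrences are non-overlapping positions in the stream", {
  ts <- default_fixture_tokens()
  m <- dm_model(alphabet_size(ts), sensitivity_factor = 0.25)
  for (tr in 1:5) m <- learn_sequence(m, ts$tokens, tr)$model
  for (ch in extract_chunks(m, ts$tokens, c = 0.5)) {
    occ <- sort(ch$occurrences)
    if (length(occ) > 1)
      expect_true(all(diff(occ) >= length(ch$tokens)))
    for (o in occ)
      expect_equal(ts$tokens[o:(o + length(ch$tokens) - 1)], ch$tokens)
  }
})

test_that("hierarchy re-encoding replaces chunks greedily and losslessly", {
  m <- learn_sequence(dm_model(4), c(1, 2, 1, 2, 3, 4))$model
  chunks <- list(list(tokens = c(1L, 2L), occurrences = c(1L, 3L), level = 0L))
  h <- build_hierarchy(c(1, 2, 1, 2, 3, 4), chunks, m)
  expect_equal(h$tokens1, c(5L, 5L, 3L, 4L))        # ABABCD -> u,u,C,D
  expect_equal(h$hmodel$level1$K, 5L)
  expect_equal(expand_units(h$tokens1, h$hmodel), c(1L, 2L, 1L, 2L, 3L, 4L))
  # no chunks: stream unchanged, level-1 model over the original alphabet
  h0 <- build_hierarchy(c(1, 2, 1, 2, 3, 4), list(), m)
  expect_equal(h0$tokens1, c(1L, 2L, 1L, 2L, 3L, 4L))
  expect_equal(h0$hmodel$level1$K, 4L)
  # single chunk covering everything: stream becomes one unit symbol
  whole <- list(list(tokens = c(1L, 2L, 1L, 2L, 3L, 4L), occurrences = 1L,
                     level = 0L))
  hw <- build_hierarchy(c(1, 2, 1, 2, 3, 4), whole, m)
  expect_equal(hw$tokens1, 5L)
})

test_that("longest chunk wins when candidates overlap", {
  m <- learn_sequence(dm_model(4), c(1, 2, 3, 4))$model
  chunks <- list(
    list(tokens = c(1L, 2L), occurrences = 1L, level = 0L),
    list(tokens = c(1L, 2L, 3L), occurrences = 1L, level = 0L))
  h <- build_hierarchy(c(1, 2, 3, 4), chunks, m)
  expect_equal(h$tokens1, c(6L, 4L))  # the 3-token chunk is unit 2 (= 4+2)
  expect_equal(expand_units(h$tokens1, h$hmodel), c(1L, 2L, 3L, 4L))
})

test_that("re-encoded training streams always expand back exactly", {
  for (seed in 1:5) {
    mel <- make_fixture_melody(40, 8, 4, 5, seed = seed)
    ts <- tokenize(mel, "pitch_duration")
    m <- dm_model(alphabet_size(ts), sensitivity_factor = 0.25)
    for (tr in 1:4) m <- learn_sequence(m, ts$tokens, tr)$model
    ch <- extract_chunks(m, ts$tokens, c = 0.5)
    h <- build_hierarchy(ts$tokens, ch, m)
    expect_equal(expand_units(h$tokens1, h$hmodel), ts$tokens)
  }
})
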