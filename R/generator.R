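#' Probabilistically compose a token sequence from a learned model
#'
#' Samples a symbol stream from the level-1 transition distributions of a
#' hierarchical model (falling back to the plain model when no hierarchy was
#' built), expands chunk units to their level-0 token tuples, and truncates
#' to exactly `length` level-0 tokens.  Sampling uses the model's current
#' transition distributions (posterior means by default); deterministic for
#' a fixed seed.
#'
#' @param hmodel a `hierarchical_model` from [build_hierarchy()] or a plain
#'   [dm_model()]
#' @param length number of level-0 tokens to emit (>= 2)
#' @param seed integer RNG seed
#' @param start `"first_training_token"` (default: the first symbol of the
#'   re-encoded training stream) or `"stationary_sample"` (a symbol drawn
#'   from the empirical level-1 symbol frequencies)
#' @param estimator transition estimator used for sampling:
#'   `"posterior_mean"` (default) or `"count_ratio"`
#' @return integer vector of level-0 tokens (class `token_stream` vector)
#' @export
generate_sequence <- function(hmodel, length, seed = 1,
                              start = c("first_training_token",
                                        "stationary_sample"),
                              estimator = c("posterior_mean", "count_ratio")) {
  start <- match.arg(start)
  estimator <- match.arg(estimator)
  if (length < 2) stop("length must be >= 2")
  plain <- inherits(hmodel, "dm_model")
  model <- if (plain) hmodel else hmodel$level1
  tokens1 <- if (plain) attr(hmodel, "training_tokens") else hmodel$tokens1
  if (is.null(tokens1) || !length(tokens1))
    stop("the model carries no training stream to start from")
  ord <- model$order
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  state <- if (start == "first_training_token") {
    tokens1[seq_len(ord)]
  } else {
    freq <- tabulate(tokens1, nbins = model$K)
    sample.int(model$K, ord, replace = TRUE, prob = freq / sum(freq))
  }
  out1 <- state
  expand <- function(s) {
    if (plain || s <= hmodel$K) s else hmodel$unit_map[[s - hmodel$K]]
  }
  n0 <- sum(lengths(lapply(out1, expand)))
  while (n0 < length) {
    p <- sampling_row(model, state, estimator)
    nxt <- sample.int(model$K, 1L, prob = p)
    out1 <- c(out1, nxt)
    n0 <- n0 + length(expand(nxt))
    state <- c(state[-1L], nxt)[seq_len(ord)]
    if (ord == 1L) state <- nxt
  }
  out0 <- unlist(lapply(out1, expand), use.names = FALSE)
  out0[seq_len(length)]
}

sampling_row <- function(model, context, estimator) {
  if (estimator == "posterior_mean") return(predictive_row(model, context))
  n <- count_row(model, context)
  if (sum(n) == 0) rep(1 / model$K, model$K) else n / sum(n)
}

#' Empirical bigram distribution of a token stream
#'
#' Relative frequencies of consecutive token pairs.  Returned as a named
#' numeric vector over "i j" pair keys; values sum to 1.
#'
#' @param tokens integer token vector (or `token_sequence`)
#' @return named probability vector (class `bigram_distribution`)
#' @export
bigram_distribution <- function(tokens) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  n <- length(tokens)
  if (n < 2) stop("need at least two tokens for a bigram distribution")
  keys <- paste(tokens[-n], tokens[-1])
  tab <- table(keys)
  p <- as.numeric(tab) / (n - 1)
  names(p) <- names(tab)
  structure(p, class = "bigram_distribution")
}

#' Average bigram distribution of a corpus
#'
#' Unweighted mean of the per-piece bigram distributions over their union
#' support, renormalized.
#'
#' @param corpus list of token vectors (or a `generated_corpus`)
#' @return named probability vector (class `bigram_distribution`)
#' @export
average_bigram_distribution <- function(corpus) {
  if (inherits(corpus, "generated_corpus")) corpus <- corpus$pieces
  dists <- lapply(corpus, bigram_distribution)
  support <- sort(unique(unlist(lapply(dists, names))))
  acc <- numeric(length(support))
  names(acc) <- support
  for (d in dists) acc[names(d)] <- acc[names(d)] + d
  p <- acc / length(dists)
  structure(p / sum(p), class = "bigram_distribution")
}

#' Jensen-Shannon divergence between two distributions
#'
#' Distributions are aligned on the union of their supports, smoothed with
#' `eps`, and renormalized; the result is symmetric, non-negative and
#' bounded by log(2) nats.
#'
#' @param p,q named probability vectors (e.g. from [bigram_distribution()])
#' @param eps smoothing constant added to every support entry (default 1e-9)
#' @return JS divergence in nats
#' @export
js_divergence <- function(p, q, eps = 1e-9) {
  support <- sort(unique(c(names(p), names(q))))
  if (!length(support)) stop("empty support")
  pv <- qv <- numeric(length(support))
  names(pv) <- names(qv) <- support
  pv[names(p)] <- p
  qv[names(q)] <- q
  pv <- pv + eps; qv <- qv + eps
  pv <- pv / sum(pv); qv <- qv / sum(qv)
  m <- (pv + qv) / 2
  0.5 * sum(pv * log(pv / m)) + 0.5 * sum(qv * log(qv / m))
}

#' JS distance from a distribution to a reference distribution
#' @param dist,reference named probability vectors
#' @param eps smoothing constant
#' @return non-negative JS divergence in nats
#' @export
distance_to_reference <- function(dist, reference, eps = 1e-9) {
  js_divergence(dist, reference, eps = eps)
}

#' Generate a corpus of pieces from one model
#'
#' @param hmodel hierarchical (or plain) model
#' @param n_pieces number of pieces
#' @param length level-0 tokens per piece
#' @param seed root seed; piece i uses `seed + i`
#' @param ... passed to [generate_sequence()]
#' @return a `generated_corpus`: list with `pieces`, `seed`
#' @export
generate_corpus <- function(hmodel, n_pieces, length, seed = 1, ...) {
  pieces <- lapply(seq_len(n_pieces), function(i) {
    generate_sequence(hmodel, length, seed = seed + i, ...)
  })
  structure(list(pieces = pieces, seed = seed), class = "generated_corpus")
}

#' Embed distributions in 2-D with t-SNE
#'
#' Computes pairwise Jensen-Shannon divergences between the distributions
#' and maps them to the plane with a small exact t-distributed stochastic
#' neighbor embedding.  The embedding is for visualization only: distances
#' in the plane are not metric-faithful; use [js_divergence()] for
#' quantitative comparison.
#'
#' @param dists list of named probability vectors
#' @param seed RNG seed (the embedding is stochastic)
#' @param perplexity t-SNE perplexity (default: a third of the number of
#'   points, capped at 10)
#' @param n_iter gradient iterations
#' @return matrix with one (x, y) row per distribution
#' @export
embed_distributions <- function(dists, seed = 1, perplexity = NULL,
                                n_iter = 500) {
  n <- length(dists)
  if (n < 3) stop("need at least three distributions to embed")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- js_divergence(dists[[i]], dists[[j]])
    }
  }
  if (is.null(perplexity)) perplexity <- max(2, min(10, floor((n - 1) / 3)))
  tsne_embed(D, perplexity = perplexity, seed = seed, n_iter = n_iter)
}
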