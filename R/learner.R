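#' Incremental Dirichlet-prior Markov learner
#'
#' `dm_model()` creates a Markov model of fixed order whose transition
#' distributions carry a symmetric Dirichlet prior.  Observations update the
#' model by conjugacy (each observed transition adds one count), so the model
#' exposes not only transition probabilities but also the *reliability* of
#' each probability: the inverse variance of the marginal Beta posterior over
#' that transition.  Reliability grows with evidence, which is what
#' distinguishes this Bayesian learner from a maximum-likelihood n-gram
#' model.
#'
#' Sensitivity regimes: the concentration vector is scaled by
#' `sensitivity_factor` (0.25 hypo-sensitive, 1 normal, 4 hyper-sensitive).
#' With the default `sensitivity_mode = "prior"` the factor scales the prior
#' concentration at initialization and every observation adds +1, so the
#' three regimes accumulate identical counts but differ in how far each
#' observation moves the predictive distribution.  The alternative mode
#' `"increment"` leaves the prior at `base_concentration` and scales the
#' per-observation increment instead.
#'
#' @param K alphabet size (number of categories), at least 2.
#' @param order context length of the Markov model (default 1).
#' @param sensitivity_factor positive scaling of the Dirichlet concentration;
#'   0.25, 1 and 4 give the hypo-, normal- and hyper-sensitive regimes.
#' @param base_concentration base symmetric concentration (default 1).
#' @param sensitivity_mode `"prior"` (default) or `"increment"`; see Details.
#' @return an object of class `dm_model`.
#' @examples
#' m <- dm_model(K = 3)
#' m <- observe(m, context = 1, symbol = 2)
#' transition_estimate(m, context = 1, symbol = 2)
#' @export
dm_model <- function(K, order = 1L, sensitivity_factor = 1,
                     base_concentration = 1,
                     sensitivity_mode = c("prior", "increment")) {
  sensitivity_mode <- match.arg(sensitivity_mode)
  if (!is.numeric(K) || length(K) != 1L || K < 2)
    stop("K must be a single integer >= 2")
  if (!is.numeric(sensitivity_factor) || length(sensitivity_factor) != 1L ||
      sensitivity_factor <= 0)
    stop("sensitivity_factor must be a positive number")
  if (base_concentration <= 0) stop("base_concentration must be positive")
  if (order < 1) stop("order must be >= 1")
  structure(list(
    K = as.integer(K),
    order = as.integer(order),
    sensitivity_factor = sensitivity_factor,
    base_concentration = base_concentration,
    sensitivity_mode = sensitivity_mode,
    rows = list()  # context key -> integer count vector (length K)
  ), class = "dm_model")
}

#' @export
print.dm_model <- function(x, ...) {
  cat(sprintf(
    "Dirichlet-Markov model: K = %d, order = %d, factor = %g (%s mode), %d observed context(s)\n",
    x$K, x$order, x$sensitivity_factor, x$sensitivity_mode, length(x$rows)))
  invisible(x)
}

context_key <- function(context) paste(as.integer(context), collapse = " ")

#' Per-entry prior concentration of a model
#' @keywords internal
prior_concentration <- function(model) {
  if (model$sensitivity_mode == "prior")
    model$base_concentration * model$sensitivity_factor
  else
    model$base_concentration
}

count_increment <- function(model) {
  if (model$sensitivity_mode == "prior") 1 else model$sensitivity_factor
}

.check_tokens <- function(model, tokens) {
  tokens <- as.integer(tokens)
  if (any(tokens < 1L | tokens > model$K))
    stop("token out of alphabet: tokens must lie in 1..K")
  tokens
}

#' Raw observation counts for a context (zeros if never seen)
#' @keywords internal
count_row <- function(model, context) {
  key <- context_key(.check_tokens(model, context))
  r <- model$rows[[key]]
  if (is.null(r)) numeric(model$K) else r
}

#' Concentration vector alpha for a context
#'
#' Prior plus (possibly scaled) observation counts; rows are lazily
#' initialized, so an unseen context returns the uniform prior vector.
#' @param model a `dm_model`
#' @param context token vector of length `order`
#' @return numeric vector of K positive concentrations
#' @export
alpha_row <- function(model, context) {
  prior_concentration(model) + count_increment(model) * count_row(model, context)
}

#' Posterior-mean predictive distribution for a context
#' @inheritParams alpha_row
#' @return probability vector of length K
#' @export
predictive_row <- function(model, context) {
  a <- alpha_row(model, context)
  a / sum(a)
}

#' Record one observed transition
#'
#' Conjugate update: exactly one entry of one context row is incremented;
#' every other row is untouched.
#'
#' @param model a `dm_model`
#' @param context token vector of length `order` (the preceding symbols)
#' @param symbol the observed next token
#' @return the updated model
#' @export
observe <- function(model, context, symbol) {
  context <- .check_tokens(model, context)
  symbol <- .check_tokens(model, symbol)
  if (length(context) != model$order)
    stop("context length must equal model order")
  key <- context_key(context)
  r <- model$rows[[key]]
  if (is.null(r)) r <- numeric(model$K)
  r[symbol] <- r[symbol] + 1
  model$rows[[key]] <- r
  model
}

beta_variance <- function(alpha, i) {
  a0 <- sum(alpha)
  ai <- alpha[i]
  ai * (a0 - ai) / (a0^2 * (a0 + 1))
}

#' Transition probability, variance and reliability
#'
#' Reliability is the inverse of the marginal Beta variance of the
#' transition probability under the current Dirichlet concentrations:
#' `var = alpha_i (alpha_0 - alpha_i) / (alpha_0^2 (alpha_0 + 1))`.
#' The `count_ratio` estimator returns the observed-count fraction
#' (maximum likelihood; 1/K for an unseen context) while `posterior_mean`
#' returns `alpha_i / alpha_0`; reliability always comes from the current
#' concentrations regardless of the estimator.
#'
#' @inheritParams observe
#' @param estimator `"posterior_mean"` (default) or `"count_ratio"`.
#' @return a list with `mean`, `variance`, `reliability`.
#' @export
transition_estimate <- function(model, context, symbol,
                                estimator = c("posterior_mean", "count_ratio")) {
  estimator <- match.arg(estimator)
  symbol <- .check_tokens(model, symbol)
  a <- alpha_row(model, context)
  m <- if (estimator == "posterior_mean") {
    a[symbol] / sum(a)
  } else {
    n <- count_row(model, context)
    if (sum(n) == 0) 1 / model$K else n[symbol] / sum(n)
  }
  v <- beta_variance(a, symbol)
  list(mean = m, variance = v, reliability = 1 / v)
}

#' Bayesian surprise between two predictive distributions
#'
#' Kullback-Leibler divergence `sum(P * log(P/Q))` in nats between the
#' predictive distribution before (`P`) and after (`Q`) a single
#' observation.  Non-negative, zero iff the distributions are equal.
#'
#' @param row_before,row_after strictly positive probability vectors of the
#'   same length, each summing to 1 within 1e-9.
#' @return KL divergence in nats.
#' @export
bayesian_surprise <- function(row_before, row_after) {
  if (length(row_before) != length(row_after))
    stop("distributions must have the same length")
  if (abs(sum(row_before) - 1) > 1e-9 || abs(sum(row_after) - 1) > 1e-9)
    stop("inputs must be normalized probability vectors")
  if (any(row_before <= 0) || any(row_after <= 0))
    stop("inputs must be strictly positive (Dirichlet means always are)")
  sum(row_before * log(row_before / row_after))
}

#' Conditional entropy of the model's predictive distributions
#'
#' `-sum_i w(i) sum_j p(j|i) log2 p(j|i)` in bits, where `p(.|i)` is the
#' current posterior-mean predictive row for context `i` and `w` weights the
#' contexts.  `weights` may be a named vector (names are space-separated
#' context keys) or `NULL`, in which case observed contexts are weighted by
#' their empirical frequency in the training counts.
#'
#' @param model a `dm_model`
#' @param weights probability vector over contexts (must sum to 1), named by
#'   context key, or `NULL` for empirical context weights.
#' @return entropy in bits.
#' @export
conditional_entropy <- function(model, weights = NULL) {
  if (is.null(weights)) {
    if (length(model$rows) == 0) return(log2(model$K))
    tot <- vapply(model$rows, sum, numeric(1))
    weights <- tot / sum(tot)
    names(weights) <- names(model$rows)
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("context weights must sum to 1")
  h <- 0
  for (i in seq_along(weights)) {
    ctx <- as.integer(strsplit(names(weights)[i], " ", fixed = TRUE)[[1]])
    p <- predictive_row(model, ctx)
    h <- h - weights[i] * sum(p * log2(p))
  }
  unname(h)
}

#' Learn a token sequence, tracking per-event Bayesian surprise
#'
#' Iterates over the sequence; for each event the predictive distribution of
#' its context is captured before and after the conjugate update and the
#' Bayesian surprise (KL in nats) between the two is recorded.  A sequence
#' shorter than `order + 1` leaves the model unchanged and yields an empty
#' trace.
#'
#' @param model a `dm_model`
#' @param tokens integer token vector (values in 1..K)
#' @param trial_index integer label stored on the trace
#' @return list with `model` (updated) and `trace` (a `learning_trace`:
#'   data frame of per-event surprises with attributes `total_surprise`,
#'   `trial_index`).
#' @export
learn_sequence <- function(model, tokens, trial_index = 1L) {
  tokens <- .check_tokens(model, tokens)
  n <- length(tokens)
  ord <- model$order
  if (n < ord + 1L) {
    trace <- new_learning_trace(numeric(0), integer(0), trial_index)
    return(list(model = model, trace = trace))
  }
  idx <- (ord + 1L):n
  surprise <- numeric(length(idx))
  for (j in seq_along(idx)) {
    t <- idx[j]
    ctx <- tokens[(t - ord):(t - 1L)]
    before <- predictive_row(model, ctx)
    model <- observe(model, ctx, tokens[t])
    after <- predictive_row(model, ctx)
    surprise[j] <- bayesian_surprise(before, after)
  }
  list(model = model, trace = new_learning_trace(surprise, idx, trial_index))
}

new_learning_trace <- function(surprise, event, trial_index) {
  structure(
    data.frame(event = as.integer(event), surprise = surprise),
    total_surprise = sum(surprise),
    trial_index = as.integer(trial_index),
    class = c("learning_trace", "data.frame"))
}

#' Total Bayesian surprise of a learning trace
#' @param trace a `learning_trace` from [learn_sequence()]
#' @return sum of per-event surprises (nats)
#' @export
total_surprise <- function(trace) attr(trace, "total_surprise")

#' Serialize a model to a JSON string
#'
#' Layout: `K`, `order`, `sensitivity_factor`, `base_concentration`,
#' `sensitivity_mode`, and `rows` as a map from space-separated context key
#' to count vector.
#' @param model a `dm_model`
#' @param path optional file to write to
#' @return JSON string (invisibly if written to file)
#' @export
model_to_json <- function(model, path = NULL) {
  x <- unclass(model)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a model serialized with [model_to_json()]
#' @param json JSON string or path to a JSON file
#' @return a `dm_model`
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  m <- dm_model(x$K, x$order, x$sensitivity_factor, x$base_concentration,
                x$sensitivity_mode)
  m$rows <- lapply(x$rows, as.numeric)
  m
}
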