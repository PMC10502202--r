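#' Score observed transitions by normalized reliability x probability
#'
#' Every (context, symbol) pair with at least one observed count is scored.
#' Transition probabilities (posterior means) and reliabilities are each
#' z-normalized across the observed pairs — subtract the mean, divide by the
#' standard deviation — and the chunking score is the product of the two
#' z-scores.  A dimension with zero variance gets all-zero z-scores.
#'
#' @param model a trained [dm_model()]
#' @return data frame with columns `context` (key string), `symbol`,
#'   `count`, `prob`, `reliability`, `z_prob`, `z_rel`, `product`.
#' @export
score_transitions <- function(model) {
  keys <- names(model$rows)
  out <- list()
  for (key in keys) {
    cnt <- model$rows[[key]]
    obs <- which(cnt > 0)
    if (!length(obs)) next
    ctx <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
    a <- alpha_row(model, ctx)
    a0 <- sum(a)
    v <- a[obs] * (a0 - a[obs]) / (a0^2 * (a0 + 1))
    out[[key]] <- data.frame(
      context = key, symbol = obs, count = cnt[obs],
      prob = a[obs] / a0, reliability = 1 / v,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(context = character(0), symbol = integer(0),
                      count = numeric(0), prob = numeric(0),
                      reliability = numeric(0), z_prob = numeric(0),
                      z_rel = numeric(0), product = numeric(0)))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  zs <- function(x) {
    s <- stats::sd(x)
    if (length(x) < 2 || !is.finite(s) || s == 0) rep(0, length(x))
    else (x - mean(x)) / s
  }
  df$z_prob <- zs(df$prob)
  df$z_rel <- zs(df$reliability)
  df$product <- df$z_prob * df$z_rel
  df
}

#' Extract chunks from a trained model and its training sequence
#'
#' A transition of the training sequence is *chunkable* when its probability
#' z-score and reliability z-score are both positive and their product
#' exceeds the threshold `c`.  Maximal runs of consecutive chunkable
#' transitions are merged into multi-symbol chunks (contiguous sub-phrases
#' of the training sequence); duplicate token tuples are collapsed, so the
#' chunk count is the number of distinct patterns.
#'
#' @param model a trained [dm_model()]
#' @param tokens the token sequence the model was trained on
#' @param c chunking threshold on the z-score product (default 5, matched to
#'   sample lengths of a few dozen notes)
#' @return list of chunks, each a list with `tokens` (tuple, length >= 2),
#'   `occurrences` (start positions in `tokens`), `level`.
#' @export
extract_chunks <- function(model, tokens, c = 5) {
  if (!length(model$rows)) return(list())
  tokens <- .check_tokens(model, tokens)
  n <- length(tokens)
  ord <- model$order
  if (n < ord + 1L) return(list())
  sc <- score_transitions(model)
  if (!nrow(sc)) return(list())
  pass <- sc$z_prob > 0 & sc$z_rel > 0 & sc$product > c
  ok <- paste(sc$context, sc$symbol)[pass]
  # transition t joins tokens[t + ord - 1] -> tokens[t + ord]
  nt <- n - ord
  chunkable <- logical(nt)
  for (t in seq_len(nt)) {
    key <- paste(context_key(tokens[t:(t + ord - 1L)]), tokens[t + ord])
    chunkable[t] <- key %in% ok
  }
  runs <- rle(chunkable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  chunks <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    # run of transitions starts[i]..ends[i] spans tokens starts[i]..ends[i]+ord
    span <- tokens[starts[i]:(ends[i] + ord)]
    key <- context_key(span)
    if (is.null(chunks[[key]])) {
      chunks[[key]] <- list(tokens = span, occurrences = starts[i], level = 0L)
    } else {
      chunks[[key]]$occurrences <- c(chunks[[key]]$occurrences, starts[i])
    }
  }
  unname(chunks)
}

#' Re-encode a sequence with chunk units and train the level-1 model
#'
#' Chunk occurrences are replaced left-to-right by new unit symbols using a
#' greedy longest-then-leftmost match (overlaps are impossible after the
#' replacement is greedy).  The level-1 model is a fresh Dirichlet-Markov
#' model over the extended alphabet (original K symbols followed by one unit
#' symbol per chunk) trained on the re-encoded stream under the same
#' sensitivity regime as `model`.
#'
#' @param tokens token sequence (values in 1..K)
#' @param chunks list of chunks from [extract_chunks()]
#' @param model the level-0 model (provides K and the sensitivity regime)
#' @param n_passes how many times the re-encoded stream is learned by the
#'   level-1 model (mirror the number of level-0 learning trials)
#' @return list with `tokens1` (re-encoded stream), `hmodel`
#'   (a `hierarchical_model`: `level0`, `chunks`, `level1`, `K`,
#'   `unit_map` from unit symbol to token tuple, `tokens1`).
#' @export
build_hierarchy <- function(tokens, chunks, model, n_passes = 1L) {
  tokens <- .check_tokens(model, tokens)
  K <- model$K
  M <- length(chunks)
  # longest-then-leftmost greedy replacement
  if (M) {
    lens <- vapply(chunks, function(ch) length(ch$tokens), integer(1))
    ordc <- order(lens, decreasing = TRUE)
  }
  out <- integer(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    matched <- FALSE
    if (M) {
      for (j in ordc) {
        L <- length(chunks[[j]]$tokens)
        if (i + L - 1L <= n && all(tokens[i:(i + L - 1L)] == chunks[[j]]$tokens)) {
          out <- c(out, K + j)
          i <- i + L
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  level1 <- dm_model(K + M, order = model$order,
                     sensitivity_factor = model$sensitivity_factor,
                     base_concentration = model$base_concentration,
                     sensitivity_mode = model$sensitivity_mode)
  for (p in seq_len(n_passes)) {
    level1 <- learn_sequence(level1, out, trial_index = p)$model
  }
  unit_map <- lapply(chunks, `[[`, "tokens")
  hmodel <- structure(list(level0 = model, chunks = chunks, level1 = level1,
                           K = K, unit_map = unit_map, tokens1 = out),
                      class = "hierarchical_model")
  list(tokens1 = out, hmodel = hmodel)
}

#' Expand level-1 unit symbols back to level-0 tokens
#' @param tokens1 re-encoded token vector (values in 1..(K+M))
#' @param hmodel a `hierarchical_model`
#' @return level-0 token vector
#' @export
expand_units <- function(tokens1, hmodel) {
  K <- hmodel$K
  unlist(lapply(tokens1, function(s) {
    if (s <= K) s else hmodel$unit_map[[s - K]]
  }), use.names = FALSE)
}

#' Number of distinct chunks in a hierarchical model
#' @param hmodel a `hierarchical_model` (or a chunk list)
#' @return integer count of distinct chunk patterns
#' @export
n_chunks <- function(hmodel) {
  if (inherits(hmodel, "hierarchical_model")) length(hmodel$chunks)
  else length(hmodel)
}

#' Export chunks as a data frame (CSV-ready)
#' @param chunks list of chunks from [extract_chunks()]
#' @return data frame with chunk id, pattern, length, occurrence count
#' @export
chunks_to_df <- function(chunks) {
  if (!length(chunks)) {
    return(data.frame(chunk = integer(0), pattern = character(0),
                      length = integer(0), occurrences = integer(0)))
  }
  data.frame(
    chunk = seq_along(chunks),
    pattern = vapply(chunks, function(ch) context_key(ch$tokens), character(1)),
    length = vapply(chunks, function(ch) length(ch$tokens), integer(1)),
    occurrences = vapply(chunks, function(ch) length(ch$occurrences), integer(1)))
}
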