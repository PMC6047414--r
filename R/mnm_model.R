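#' Memory-network model configuration
#'
#' Configures the classifier architecture.  The named systems are
#' reproduced by tuples of these switches: the full knowledge-augmented
#' model uses TransE entity embeddings plus the pair relation embedding,
#' two memory networks with shared attention parameters, and dimension-wise
#' sum pooling; ablations swap entity sources, drop the relation embedding,
#' unshare the attention, switch to max pooling, or collapse to a single
#' memory network.  See [mnm_variant()].
#'
#' @param K Number of computational layers (hops).
#' @param d Embedding dimension (word, entity and relation embeddings share
#'   it).
#' @param entity_source `"transe"` (KB-learned entity vectors, averaged
#'   mention-word fallback for entities absent from the KB) or
#'   `"averaged_words"` (always the mention-word average).
#' @param use_relation_embedding Concatenate the pair's KB relation vector
#'   to the classifier input (zero vector for pairs absent from the KB).
#' @param architecture `"dual"` (two memory networks, one per entity) or
#'   `"single"` (one network; both entity vectors join each memory column).
#' @param attention_sharing `"shared"` (both networks use the same
#'   attention parameters) or `"separate"`.
#' @param pooling `"sum"` (dimension-wise sum of transformed query and
#'   attention output) or `"max"` (dimension-wise max).
#' @param finetune_kb_vectors Train entity/relation vectors instead of
#'   freezing them.
#' @param seed Seed for parameter initialization.
#' @return An `mnm_config` list.
#' @export
mnm_config <- function(K = 4L, d = 100L,
                       entity_source = c("transe", "averaged_words"),
                       use_relation_embedding = TRUE,
                       architecture = c("dual", "single"),
                       attention_sharing = c("shared", "separate"),
                       pooling = c("sum", "max"),
                       finetune_kb_vectors = FALSE, seed = 1L) {
  stopifnot(K >= 1L, d >= 1L)
  structure(list(K = as.integer(K), d = as.integer(d),
                 entity_source = match.arg(entity_source),
                 use_relation_embedding = isTRUE(use_relation_embedding),
                 architecture = match.arg(architecture),
                 attention_sharing = match.arg(attention_sharing),
                 pooling = match.arg(pooling),
                 finetune_kb_vectors = isTRUE(finetune_kb_vectors),
                 seed = as.integer(seed)),
            class = "mnm_config")
}

#' Named model variants
#'
#' @param name One of `"MNM"`, `"AE"`, `"TE"`, `"AE-TR"`, `"MNM-DA"`,
#'   `"MNM-Max"`, `"MNM-Single"`.
#' @param ... Overrides passed to [mnm_config()] (e.g. `K`, `d`, `seed`).
#' @return An `mnm_config`.
#' @export
mnm_variant <- function(name, ...) {
  base <- switch(name,
    "MNM" = list(),
    "AE" = list(entity_source = "averaged_words",
                use_relation_embedding = FALSE),
    "TE" = list(entity_source = "transe", use_relation_embedding = FALSE),
    "AE-TR" = list(entity_source = "averaged_words",
                   use_relation_embedding = TRUE),
    "MNM-DA" = list(attention_sharing = "separate"),
    "MNM-Max" = list(pooling = "max"),
    "MNM-Single" = list(architecture = "single"),
    stop("unknown variant: ", name))
  do.call(mnm_config, utils::modifyList(base, list(...)))
}

#' Position-impact percentage
#'
#' The per-token scalar down-weighting a memory column by its relative
#' distance `p` to the entity mention:
#' `(1 - p/n) - (k/d) * (1 - 2 p/n)`, where `n` is the context length, `k`
#' the current computational layer and `d` the embedding dimension.
#'
#' @param p Relative distance(s), vectorized.
#' @param n Context length.
#' @param k Layer number (1-based).
#' @param d Embedding dimension.
#' @return Numeric vector of the same length as `p`.
#' @export
position_percentage <- function(p, n, k, d) {
  if (n == 0) stop("empty context (n = 0)")
  (1 - p / n) - (k / d) * (1 - 2 * p / n)
}

#' Position-weight a memory matrix
#'
#' Scales memory column `i` by
#' `position_percentage(dists[i], n, k, d)`.  The first network weights by
#' distances to entity 1, the second by distances to entity 2.
#'
#' @param m Memory matrix, `d x n`, one context-word embedding per column.
#' @param dists Integer distances aligned with the columns.
#' @param k Layer number.
#' @param d Embedding dimension.
#' @return A `d x n` matrix.
#' @export
weight_memory <- function(m, dists, k, d) {
  n <- ncol(m)
  per <- position_percentage(dists, n, k, d)
  m * rep(per, each = nrow(m))
}

#' Attention over memory for one query
#'
#' Scores each memory column against the query by
#' `g_i = tanh(Wa [m_i; e] + ba)`, normalizes with softmax, and returns the
#' attention-weighted sum of memory columns.
#'
#' @param m Weighted memory, `d x n`.
#' @param query Query vector; for the single-network architecture the
#'   concatenation of both entity vectors (length `2d`).
#' @param Wa Attention weight row-matrix, `1 x (d + length(query))`.
#' @param ba Attention bias scalar.
#' @return List with `weights` (length-`n` simplex vector), `v_att`
#'   (length-`d` output), and `scores` (the pre-softmax `g`).
#' @export
attention <- function(m, query, Wa, ba) {
  n <- ncol(m)
  if (n == 0L) stop("attention over empty memory")
  d <- nrow(m)
  Wm <- Wa[1L, seq_len(d)]
  Wq <- Wa[1L, -seq_len(d)]
  g <- tanh(as.numeric(Wm %*% m) + sum(Wq * query) + ba)
  a <- exp(g - max(g))
  a <- a / sum(a)
  list(weights = a, v_att = as.numeric(m %*% a), scores = g)
}

#' Query update at the end of a computational layer
#'
#' Combines the linearly transformed query with the attention output:
#' dimension-wise sum `Wt e + v_att`, or dimension-wise max
#' `max(Wt e, v_att)`.
#'
#' @param e Current query (entity) vector.
#' @param v_att Attention output vector.
#' @param Wt `d x d` transformation matrix.
#' @param pooling `"sum"` or `"max"`.
#' @return The new query vector.
#' @export
hop_update <- function(e, v_att, Wt, pooling = "sum") {
  u <- as.numeric(Wt %*% e)
  if (pooling == "sum") u + v_att else pmax(u, v_att)
}

#' Class decision from a probability pair
#'
#' Argmax over the two classes; an exact tie goes to the negative class.
#'
#' @param prob Probability 2-vector `(P(y=0), P(y=1))`.
#' @return Integer 0 or 1.
#' @export
predict_label <- function(prob) as.integer(prob[2L] > prob[1L])

# parameter lookup helpers -- params is a flat named list of tensors
.wa_name <- function(cfg, k, net) {
  if (cfg$architecture == "single" || cfg$attention_sharing == "shared")
    paste0("Wa.", k)
  else paste0("Wa", net, ".", k)
}
.ba_name <- function(cfg, k, net) sub("^Wa", "ba", .wa_name(cfg, k, net))

#' Forward pass for one candidate instance
#'
#' Runs `cfg$K` computational layers.  In the dual architecture each
#' network re-weights the raw memory with its own distances at every layer,
#' attends with its current query (starting from the two entity
#' embeddings), and updates the query; the single architecture keeps one
#' memory (position-weighted by the mean of the two percentage vectors) and
#' one attention whose input joins both queries, updating each query with
#' the shared transformation.  The final queries, concatenated with the
#' pair relation embedding when configured, feed a softmax classifier.
#'
#' @param E Context word-embedding matrix, `d x n`.
#' @param dist1,dist2 Integer distances of each context token to the two
#'   mentions.
#' @param e1,e2 Entity embedding vectors.
#' @param erel Pair relation embedding (ignored unless
#'   `cfg$use_relation_embedding`).
#' @param params Flat named parameter list (see [init_mnm_params()]).
#' @param cfg An [mnm_config()].
#' @param keep_cache Keep per-layer intermediates (for backpropagation).
#' @return List with `prob` (probability 2-vector), `f` (classifier input),
#'   `alphas` (per layer, per network attention weights) and, if requested,
#'   `cache`.
#' @export
mnm_forward <- function(E, dist1, dist2, e1, e2, erel, params, cfg,
                        keep_cache = FALSE) {
  d <- cfg$d; K <- cfg$K
  n <- ncol(E)
  if (n == 0L) stop("instance with empty context")
  cache <- if (keep_cache) vector("list", K) else NULL
  alphas <- vector("list", K)

  if (cfg$architecture == "dual") {
    Q <- list(e1, e2)
    dists <- list(dist1, dist2)
    for (k in seq_len(K)) {
      lay <- list()
      alphas[[k]] <- vector("list", 2L)
      Qnew <- Q
      for (net in 1:2) {
        per <- position_percentage(dists[[net]], n, k, d)
        M <- E * rep(per, each = d)
        Wa <- params[[.wa_name(cfg, k, net)]]
        ba <- params[[.ba_name(cfg, k, net)]]
        att <- attention(M, Q[[net]], Wa, ba)
        Wt <- params[[paste0("Wt.", k)]]
        u <- as.numeric(Wt %*% Q[[net]])
        Qnew[[net]] <- if (cfg$pooling == "sum") u + att$v_att
                       else pmax(u, att$v_att)
        alphas[[k]][[net]] <- att$weights
        if (keep_cache)
          lay[[net]] <- list(per = per, M = M, g = att$scores,
                             alpha = att$weights, v = att$v_att,
                             Qin = Q[[net]], u = u)
      }
      Q <- Qnew
      if (keep_cache) cache[[k]] <- lay
    }
    ctx <- c(Q[[1]], Q[[2]])
  } else {
    Q1 <- e1; Q2 <- e2
    for (k in seq_len(K)) {
      per <- (position_percentage(dist1, n, k, d) +
              position_percentage(dist2, n, k, d)) / 2
      M <- E * rep(per, each = d)
      Wa <- params[[.wa_name(cfg, k, 1L)]]
      ba <- params[[.ba_name(cfg, k, 1L)]]
      att <- attention(M, c(Q1, Q2), Wa, ba)
      Wt <- params[[paste0("Wt.", k)]]
      u1 <- as.numeric(Wt %*% Q1); u2 <- as.numeric(Wt %*% Q2)
      Q1n <- if (cfg$pooling == "sum") u1 + att$v_att else pmax(u1, att$v_att)
      Q2n <- if (cfg$pooling == "sum") u2 + att$v_att else pmax(u2, att$v_att)
      alphas[[k]] <- list(att$weights)
      if (keep_cache)
        cache[[k]] <- list(per = per, M = M, g = att$scores,
                           alpha = att$weights, v = att$v_att,
                           Q1in = Q1, Q2in = Q2, u1 = u1, u2 = u2)
      Q1 <- Q1n; Q2 <- Q2n
    }
    ctx <- c(Q1, Q2)
  }

  f <- if (cfg$use_relation_embedding) c(ctx, erel) else ctx
  logits <- as.numeric(params$Ws %*% f + params$bs)
  ex <- exp(logits - max(logits))
  prob <- ex / sum(ex)
  out <- list(prob = prob, f = f, alphas = alphas)
  if (keep_cache) out$cache <- cache
  out
}
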