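#' TransE training configuration
#'
#' @param dim Embedding dimension for entities and relations.
#' @param margin Margin separating correct from corrupted triples in the
#'   ranking loss.
#' @param lr SGD learning rate.
#' @param epochs Number of passes over the triple set.
#' @param batch_size Minibatch size.
#' @param norm Distance norm, `"L2"` or `"L1"`.
#' @param seed RNG seed; fixes initialization, shuffling and corruption.
#' @return A `transe_config` list.
#' @export
transe_config <- function(dim = 100L, margin = 1.0, lr = 0.01, epochs = 500L,
                          batch_size = 512L, norm = c("L2", "L1"), seed = 1L) {
  norm <- match.arg(norm)
  stopifnot(dim >= 1L, margin > 0, lr > 0, epochs >= 0L, batch_size >= 1L)
  structure(list(dim = as.integer(dim), margin = margin, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 norm = norm, seed = as.integer(seed)),
            class = "transe_config")
}

#' Initialize one entity vector from its mention words
#'
#' The entity vector is the arithmetic mean of its constituent-word
#' vectors.  A word absent from the word-vector table is drawn once from
#' N(0, 0.01) and cached in `cache`; an entity with no usable words gets a
#' fresh N(0, 0.01) draw.
#'
#' @param words Character vector of mention words (lowercased).
#' @param word_vecs Word-vector matrix (words in rows) or `NULL`.
#' @param dim Embedding dimension.
#' @param cache Environment caching draws for out-of-vocabulary words.
#' @return Numeric vector of length `dim`.
#' @export
init_entity_vector <- function(words, word_vecs, dim,
                               cache = new.env(parent = emptyenv())) {
  words <- words[nzchar(words)]
  if (!length(words)) return(stats::rnorm(dim, 0, 0.1))
  vecs <- lapply(words, function(w) {
    if (!is.null(word_vecs) && w %in% rownames(word_vecs))
      return(word_vecs[w, ])
    if (!exists(w, envir = cache, inherits = FALSE))
      assign(w, stats::rnorm(dim, 0, 0.1), envir = cache)
    get(w, envir = cache, inherits = FALSE)
  })
  colMeans(do.call(rbind, vecs))
}

#' Corrupt a triple by replacing its head or tail
#'
#' With probability 1/2 the head is replaced, otherwise the tail, by an
#' entity drawn uniformly.  Sampling is filtered: a corruption that
#' reproduces a known true triple is redrawn, up to 100 tries, after which
#' the last draw is accepted.
#'
#' @param head_id,relation,tail_id The triple to corrupt.
#' @param entity_ids Character vector of all entity IDs.
#' @param triple_keys Character vector (or environment-backed set) of
#'   `head|relation|tail` keys of true triples.
#' @return A list `head_id`, `relation`, `tail_id`.
#' @export
corrupt_triple <- function(head_id, relation, tail_id, entity_ids,
                           triple_keys) {
  for (try in seq_len(100L)) {
    repl_head <- stats::runif(1) < 0.5
    e <- entity_ids[[sample.int(length(entity_ids), 1L)]]
    h <- if (repl_head) e else head_id
    t <- if (repl_head) tail_id else e
    key <- paste(h, relation, t, sep = "|")
    if (!(key %in% triple_keys)) break
  }
  list(head_id = h, relation = relation, tail_id = t)
}

triple_dist <- function(E, R, h, r, t, norm) {
  v <- E[h, ] + R[r, ] - E[t, ]
  if (norm == "L2") sqrt(sum(v * v)) else sum(abs(v))
}

#' TransE margin ranking loss
#'
#' `sum over aligned pairs of max(0, margin + d(h + r, t) - d(h' + r, t'))`
#' where d is the configured norm.  Corrupted triples are aligned one per
#' correct triple.
#'
#' @param pos,neg Data frames of triples (`head_id`, `relation`, `tail_id`)
#'   of equal row count.
#' @param store A `knowledge_store`.
#' @param margin Margin gamma.
#' @param norm `"L2"` or `"L1"`.
#' @return Non-negative scalar.
#' @export
margin_loss <- function(pos, neg, store, margin, norm = "L2") {
  stopifnot(nrow(pos) == nrow(neg))
  E <- store$entity; R <- store$relation
  s <- 0
  for (i in seq_len(nrow(pos))) {
    dp <- triple_dist(E, R, pos$head_id[i], pos$relation[i], pos$tail_id[i],
                      norm)
    dn <- triple_dist(E, R, neg$head_id[i], neg$relation[i], neg$tail_id[i],
                      norm)
    s <- s + max(0, margin + dp - dn)
  }
  s
}

#' Analytic gradient of the margin ranking loss
#'
#' Gradients of [margin_loss()] with respect to the entity and relation
#' matrices, accumulated over the batch.  Only pairs with an active margin
#' (`margin + d_pos - d_neg > 0`) contribute.
#'
#' @inheritParams margin_loss
#' @return List with `loss`, `grad_entity` and `grad_relation` (matrices
#'   shaped like `store$entity` / `store$relation`).
#' @export
margin_loss_grad <- function(pos, neg, store, margin, norm = "L2") {
  stopifnot(nrow(pos) == nrow(neg))
  E <- store$entity; R <- store$relation
  gE <- E * 0; gR <- R * 0
  loss <- 0
  for (i in seq_len(nrow(pos))) {
    vp <- E[pos$head_id[i], ] + R[pos$relation[i], ] - E[pos$tail_id[i], ]
    vn <- E[neg$head_id[i], ] + R[neg$relation[i], ] - E[neg$tail_id[i], ]
    if (norm == "L2") {
      dp <- sqrt(sum(vp^2)); dn <- sqrt(sum(vn^2))
      up <- vp / max(dp, 1e-12); un <- vn / max(dn, 1e-12)
    } else {
      dp <- sum(abs(vp)); dn <- sum(abs(vn))
      up <- sign(vp); un <- sign(vn)
    }
    term <- margin + dp - dn
    if (term > 0) {
      loss <- loss + term
      gE[pos$head_id[i], ] <- gE[pos$head_id[i], ] + up
      gE[pos$tail_id[i], ] <- gE[pos$tail_id[i], ] - up
      gE[neg$head_id[i], ] <- gE[neg$head_id[i], ] - un
      gE[neg$tail_id[i], ] <- gE[neg$tail_id[i], ] + un
      gR[pos$relation[i], ] <- gR[pos$relation[i], ] + up
      gR[neg$relation[i], ] <- gR[neg$relation[i], ] - un
    }
  }
  list(loss = loss, grad_entity = gE, grad_relation = gR)
}

#' Learn entity and relation embeddings from triples
#'
#' TransE treats a relation as a translation in embedding space
#' (`h + r` close to `t` for true triples) and minimizes the margin ranking
#' loss against corrupted triples by minibatch gradient descent.  Entity
#' vectors are initialized from averaged mention-word vectors and
#' renormalized to unit L2 length after every update; relation vectors are
#' initialized from a normal distribution and left unconstrained.
#'
#' @param triples Data frame (`head_id`, `relation`, `tail_id`); duplicates
#'   are removed.
#' @param cfg A [transe_config()].
#' @param word_vecs Optional word-vector matrix used for entity
#'   initialization.
#' @param entity_words Optional named list mapping entity ID to its mention
#'   words; defaults to the lowercased entity ID itself.
#' @return A `knowledge_store`: `entity` and `relation` matrices (IDs in
#'   row names), `pair_index` (unordered pair -> relation labels), `dim`,
#'   `norm`, and the per-epoch `loss_trace`.
#' @export
train_transe <- function(triples, cfg = transe_config(), word_vecs = NULL,
                         entity_words = NULL) {
  if (!nrow(triples)) stop("empty triple set")
  triples <- unique(triples[, c("head_id", "relation", "tail_id")])
  set.seed(cfg$seed)
  d <- cfg$dim
  ents <- sort(unique(c(triples$head_id, triples$tail_id)))
  rels <- sort(unique(triples$relation))

  cache <- new.env(parent = emptyenv())
  E <- t(vapply(ents, function(id) {
    ws <- if (!is.null(entity_words) && !is.null(entity_words[[id]]))
      tolower(entity_words[[id]]) else tolower(id)
    init_entity_vector(ws, word_vecs, d, cache)
  }, numeric(d)))
  E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
  R <- matrix(stats::rnorm(length(rels) * d, 0, 0.1), nrow = length(rels),
              dimnames = list(rels, NULL))

  keys <- paste(triples$head_id, triples$relation, triples$tail_id,
                sep = "|")
  n <- nrow(triples)
  trace <- numeric(cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      pos <- triples[idx, , drop = FALSE]
      neg <- do.call(rbind, lapply(idx, function(i) {
        as.data.frame(corrupt_triple(triples$head_id[i],
                                     triples$relation[i],
                                     triples$tail_id[i], ents, keys),
                      stringsAsFactors = FALSE)
      }))
      lg <- margin_loss_grad(pos, neg,
                             list(entity = E, relation = R),
                             cfg$margin, cfg$norm)
      ep_loss <- ep_loss + lg$loss
      E <- E - cfg$lr * lg$grad_entity
      R <- R - cfg$lr * lg$grad_relation
      touched <- unique(c(pos$head_id, pos$tail_id,
                          neg$head_id, neg$tail_id))
      E[touched, ] <- E[touched, , drop = FALSE] /
        pmax(sqrt(rowSums(E[touched, , drop = FALSE]^2)), 1e-12)
    }
    trace[ep] <- ep_loss
  }

  store <- list(entity = E, relation = R,
                pair_index = build_pair_index(triples),
                dim = d, norm = cfg$norm, loss_trace = trace)
  class(store) <- "knowledge_store"
  store
}

build_pair_index <- function(triples) {
  cp <- canonical_pair(triples$head_id, triples$tail_id)
  key <- paste(cp$gene_a, cp$gene_b, sep = "\r")
  split(triples$relation, key)
}

#' @export
print.knowledge_store <- function(x, ...) {
  cat("knowledge_store:", nrow(x$entity), "entities,",
      nrow(x$relation), "relations, dim", x$dim, "\n")
  cat("  indexed pairs:", length(x$pair_index), "\n")
  if (length(x$loss_trace))
    cat("  final epoch loss:", format(utils::tail(x$loss_trace, 1)), "\n")
  invisible(x)
}

#' Relation vector of an unordered entity pair
#'
#' If the pair appears in the knowledge base (in either direction), the
#' mean of its relation vectors is returned; a pair absent from the KB gets
#' the zero vector.
#'
#' @param store A `knowledge_store`.
#' @param gene_a,gene_b Entity IDs.
#' @return Numeric vector of length `store$dim`.
#' @export
pair_relation_vector <- function(store, gene_a, gene_b) {
  cp <- canonical_pair(gene_a, gene_b)
  key <- paste(cp$gene_a, cp$gene_b, sep = "\r")
  rels <- store$pair_index[[key]]
  if (is.null(rels) || !length(rels)) return(numeric(store$dim))
  m <- store$relation[rels, , drop = FALSE]
  colMeans(m)
}

#' Filtered link-prediction mean rank
#'
#' For every triple, all entities are ranked as candidate tails by
#' `d(h + r, candidate)`; the filtered rank of the true tail excludes other
#' known-true tails ranking above it.  The random-guess expectation is
#' `(n_entities + 1) / 2`.
#'
#' @param store A `knowledge_store`.
#' @param triples Triple data frame to evaluate.
#' @return Mean filtered rank (scalar).
#' @export
transe_mean_rank <- function(store, triples) {
  E <- store$entity; R <- store$relation
  ents <- rownames(E)
  true_key <- paste(triples$head_id, triples$relation, sep = "|")
  true_tails <- split(triples$tail_id, true_key)
  ranks <- numeric(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    q <- E[triples$head_id[i], ] + R[triples$relation[i], ]
    diff <- sweep(E, 2L, q)
    dd <- if (store$norm == "L2") sqrt(rowSums(diff^2)) else rowSums(abs(diff))
    dt <- dd[[triples$tail_id[i]]]
    better <- ents[dd < dt]
    others <- setdiff(true_tails[[paste(triples$head_id[i],
                                        triples$relation[i], sep = "|")]],
                      triples$tail_id[i])
    ranks[i] <- 1L + length(setdiff(better, others))
  }
  mean(ranks)
}
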