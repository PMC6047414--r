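#' Training configuration for the memory-network classifier
#'
#' Defaults follow the published optimizer settings: Adam with learning
#' rate 0.001 and batch size 100.
#'
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Number of epochs.
#' @param shuffle Reshuffle instances every epoch.
#' @param seed RNG seed for shuffling (initialization is seeded by the
#'   model config).
#' @return An `mnm_train_config` list.
#' @export
mnm_train_config <- function(lr = 0.001, batch_size = 100L, epochs = 30L,
                             shuffle = TRUE, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), shuffle = isTRUE(shuffle),
                 seed = as.integer(seed)),
            class = "mnm_train_config")
}

#' Mean cross-entropy loss
#'
#' `-(1/N) * sum log p(y_l | T_l)`, with probabilities clamped at 1e-12
#' before the log.
#'
#' @param probabilities Matrix with one row per instance and two columns
#'   `(P(y=0), P(y=1))`.
#' @param labels Integer vector of 0/1 labels, one per row.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(probabilities, labels) {
  probabilities <- rbind(probabilities)
  if (nrow(probabilities) != length(labels))
    stop("probabilities and labels have different lengths")
  p <- probabilities[cbind(seq_along(labels), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Initialize model parameters
#'
#' Word embeddings are copied from the pre-trained vectors where available
#' and drawn from N(0, 0.01) otherwise; row 1 is the trained
#' out-of-vocabulary token `<unk>`.  Attention rows and the classifier are
#' small random draws; each layer's transformation starts near the
#' identity.
#'
#' @param cfg An [mnm_config()]; `cfg$seed` fixes the draws.
#' @param vocab Character vector of context-token types.
#' @param word_vecs Optional word-vector matrix (words in rows).
#' @return List with `params` (flat named tensor list) and `words`
#'   (embedding row names).
#' @export
init_mnm_params <- function(cfg, vocab, word_vecs = NULL) {
  set.seed(cfg$seed)
  d <- cfg$d
  if (!is.null(word_vecs) && ncol(word_vecs) != d)
    stop("word-vector dimension ", ncol(word_vecs),
         " does not match model dimension ", d)
  words <- c("<unk>", setdiff(unique(vocab), "<unk>"))
  emb <- matrix(stats::rnorm(length(words) * d, 0, 0.1),
                nrow = length(words), dimnames = list(words, NULL))
  if (!is.null(word_vecs)) {
    hit <- intersect(words, rownames(word_vecs))
    if (length(hit)) emb[hit, ] <- word_vecs[hit, , drop = FALSE]
  }
  qdim <- if (cfg$architecture == "single") 2L * d else d
  params <- list(emb = emb)
  for (k in seq_len(cfg$K)) {
    if (cfg$architecture == "dual" && cfg$attention_sharing == "separate") {
      params[[paste0("Wa1.", k)]] <-
        matrix(stats::rnorm(d + qdim, 0, 0.1), 1L)
      params[[paste0("ba1.", k)]] <- 0
      params[[paste0("Wa2.", k)]] <-
        matrix(stats::rnorm(d + qdim, 0, 0.1), 1L)
      params[[paste0("ba2.", k)]] <- 0
    } else {
      params[[paste0("Wa.", k)]] <-
        matrix(stats::rnorm(d + qdim, 0, 0.1), 1L)
      params[[paste0("ba.", k)]] <- 0
    }
    params[[paste0("Wt.", k)]] <-
      diag(d) + matrix(stats::rnorm(d * d, 0, 0.01), d)
  }
  fdim <- if (cfg$use_relation_embedding) 3L * d else 2L * d
  params$Ws <- matrix(stats::rnorm(2L * fdim, 0, 0.1), 2L)
  params$bs <- c(0, 0)
  list(params = params, words = words)
}

#' Derive entity mention words from annotations
#'
#' Maps each gene ID to the lowercased tokens of its most frequent surface
#' form, for averaged-word entity initialization.
#'
#' @param mentions Mention data frame (`gene_id`, `surface`).
#' @return Named list, gene ID to character vector of words.
#' @export
entity_words_from_mentions <- function(mentions) {
  out <- list()
  for (id in unique(mentions$gene_id)) {
    surf <- mentions$surface[mentions$gene_id == id]
    top <- names(sort(table(surf), decreasing = TRUE))[1]
    out[[id]] <- tolower(strsplit(trimws(top), "\\s+")[[1]])
  }
  out
}

# entity vector under the configured source, with averaged-word fallback
# for entities the KB does not contain
.entity_vec <- function(id, cfg, store, word_vecs, entity_words, cache) {
  if (cfg$entity_source == "transe" && !is.null(store) &&
      id %in% rownames(store$entity))
    return(store$entity[id, ])
  ws <- if (!is.null(entity_words) && !is.null(entity_words[[id]]))
    tolower(entity_words[[id]]) else tolower(id)
  init_entity_vector(ws, word_vecs, cfg$d, cache)
}

# build instance tensors (embedding row ids + entity/relation row ids)
.make_tensors <- function(instances, words, ent_ids, rel_keys) {
  lapply(instances, function(inst) {
    ids <- match(inst$context, words)
    ids[is.na(ids)] <- 1L  # <unk>
    key <- paste(inst$gene_a, inst$gene_b, sep = "\r")
    list(ids = ids, dist1 = inst$dist1, dist2 = inst$dist2,
         ei1 = match(inst$gene_a, ent_ids),
         ei2 = match(inst$gene_b, ent_ids),
         ri = match(key, rel_keys),
         label = if (is.null(inst$label)) NA_integer_ else inst$label,
         doc_id = inst$doc_id, gene_a = inst$gene_a, gene_b = inst$gene_b,
         context = inst$context)
  })
}

.instance_forward <- function(tn, params, cfg, keep_cache = FALSE) {
  E <- t(params$emb[tn$ids, , drop = FALSE])
  mnm_forward(E, tn$dist1, tn$dist2,
              params$ent[tn$ei1, ], params$ent[tn$ei2, ],
              params$rel[tn$ri, ], params, cfg, keep_cache = keep_cache)
}

# loss and analytic gradients over a batch of instance tensors.
# Returns grads for every tensor in `params` (including ent/rel; the
# updater decides which are trainable).
mnm_loss_grad <- function(tensors, params, cfg) {
  d <- cfg$d; K <- cfg$K
  N <- length(tensors)
  grads <- lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
  loss <- 0
  for (tn in tensors) {
    fw <- .instance_forward(tn, params, cfg, keep_cache = TRUE)
    y <- tn$label
    loss <- loss - log(max(fw$prob[y + 1L], 1e-12))
    dlog <- fw$prob
    dlog[y + 1L] <- dlog[y + 1L] - 1
    grads$Ws <- grads$Ws + outer(dlog, fw$f)
    grads$bs <- grads$bs + dlog
    df <- as.numeric(t(params$Ws) %*% dlog)
    dctx <- df[seq_len(2L * d)]
    if (cfg$use_relation_embedding)
      grads$rel[tn$ri, ] <- grads$rel[tn$ri, ] + df[(2L * d + 1L):(3L * d)]
    dE <- matrix(0, d, length(tn$ids))

    if (cfg$architecture == "dual") {
      dQ <- list(dctx[seq_len(d)], dctx[d + seq_len(d)])
      for (k in rev(seq_len(K))) {
        Wt <- params[[paste0("Wt.", k)]]
        for (net in 1:2) {
          cc <- fw$cache[[k]][[net]]
          if (cfg$pooling == "sum") {
            du <- dQ[[net]]; dv <- dQ[[net]]
          } else {
            mask <- cc$u >= cc$v
            du <- dQ[[net]] * mask; dv <- dQ[[net]] * (!mask)
          }
          grads[[paste0("Wt.", k)]] <-
            grads[[paste0("Wt.", k)]] + outer(du, cc$Qin)
          dQprev <- as.numeric(t(Wt) %*% du)
          dalpha <- as.numeric(t(cc$M) %*% dv)
          dM <- outer(dv, cc$alpha)
          dg <- cc$alpha * (dalpha - sum(cc$alpha * dalpha))
          dz <- dg * (1 - cc$g^2)
          wa <- .wa_name(cfg, k, net); ban <- .ba_name(cfg, k, net)
          Wm <- params[[wa]][1L, seq_len(d)]
          Wq <- params[[wa]][1L, d + seq_len(d)]
          grads[[wa]] <- grads[[wa]] +
            matrix(c(as.numeric(cc$M %*% dz), sum(dz) * cc$Qin), 1L)
          grads[[ban]] <- grads[[ban]] + sum(dz)
          dM <- dM + outer(Wm, dz)
          dQprev <- dQprev + sum(dz) * Wq
          dE <- dE + dM * rep(cc$per, each = d)
          dQ[[net]] <- dQprev
        }
      }
      grads$ent[tn$ei1, ] <- grads$ent[tn$ei1, ] + dQ[[1]]
      grads$ent[tn$ei2, ] <- grads$ent[tn$ei2, ] + dQ[[2]]
    } else {
      dQ1 <- dctx[seq_len(d)]; dQ2 <- dctx[d + seq_len(d)]
      for (k in rev(seq_len(K))) {
        cc <- fw$cache[[k]]
        Wt <- params[[paste0("Wt.", k)]]
        if (cfg$pooling == "sum") {
          du1 <- dQ1; du2 <- dQ2; dv <- dQ1 + dQ2
        } else {
          m1 <- cc$u1 >= cc$v; m2 <- cc$u2 >= cc$v
          du1 <- dQ1 * m1; du2 <- dQ2 * m2
          dv <- dQ1 * (!m1) + dQ2 * (!m2)
        }
        grads[[paste0("Wt.", k)]] <- grads[[paste0("Wt.", k)]] +
          outer(du1, cc$Q1in) + outer(du2, cc$Q2in)
        dQ1p <- as.numeric(t(Wt) %*% du1)
        dQ2p <- as.numeric(t(Wt) %*% du2)
        dalpha <- as.numeric(t(cc$M) %*% dv)
        dM <- outer(dv, cc$alpha)
        dg <- cc$alpha * (dalpha - sum(cc$alpha * dalpha))
        dz <- dg * (1 - cc$g^2)
        wa <- .wa_name(cfg, k, 1L); ban <- .ba_name(cfg, k, 1L)
        Wm <- params[[wa]][1L, seq_len(d)]
        Wq1 <- params[[wa]][1L, d + seq_len(d)]
        Wq2 <- params[[wa]][1L, 2L * d + seq_len(d)]
        grads[[wa]] <- grads[[wa]] +
          matrix(c(as.numeric(cc$M %*% dz), sum(dz) * cc$Q1in,
                   sum(dz) * cc$Q2in), 1L)
        grads[[ban]] <- grads[[ban]] + sum(dz)
        dM <- dM + outer(Wm, dz)
        dQ1p <- dQ1p + sum(dz) * Wq1
        dQ2p <- dQ2p + sum(dz) * Wq2
        dE <- dE + dM * rep(cc$per, each = d)
        dQ1 <- dQ1p; dQ2 <- dQ2p
      }
      grads$ent[tn$ei1, ] <- grads$ent[tn$ei1, ] + dQ1
      grads$ent[tn$ei2, ] <- grads$ent[tn$ei2, ] + dQ2
    }

    for (u in unique(tn$ids)) {
      cols <- which(tn$ids == u)
      grads$emb[u, ] <- grads$emb[u, ] +
        if (length(cols) == 1L) dE[, cols] else rowSums(dE[, cols])
    }
  }
  grads <- lapply(grads, function(g) g / N)
  list(loss = loss / N, grads = grads)
}

# one Adam step over the named trainable tensors (state updated in place)
.adam_step <- function(params, grads, state, trainable, lr,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in trainable) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

#' Train the memory-network classifier
#'
#' Minimizes the mean cross-entropy over shuffled minibatches with Adam.
#' Word embeddings, attention/transform parameters and the classifier are
#' trained; entity and relation vectors are frozen inputs unless
#' `cfg$finetune_kb_vectors`.
#'
#' @param instances Labeled candidate instances from [build_candidates()].
#' @param cfg An [mnm_config()].
#' @param train_cfg An [mnm_train_config()].
#' @param word_vecs Optional pre-trained word-vector matrix.
#' @param store Optional `knowledge_store` (required for
#'   `entity_source = "transe"` or relation embeddings from the KB).
#' @param entity_words Optional gene-ID to mention-word mapping (see
#'   [entity_words_from_mentions()]).
#' @return An `mnm_model` with the fitted parameters and a per-epoch loss
#'   trace.
#' @export
train_mnm <- function(instances, cfg = mnm_config(),
                      train_cfg = mnm_train_config(), word_vecs = NULL,
                      store = NULL, entity_words = NULL) {
  if (!length(instances)) stop("no training instances")
  labels <- vapply(instances, function(x) x$label %||% NA_integer_, 0L)
  if (anyNA(labels)) stop("training instances must be labeled")
  if (length(unique(labels)) == 1L)
    warning("all training instances have the same label")

  if (!is.null(store) && store$dim != cfg$d)
    stop("knowledge-store dimension ", store$dim,
         " does not match model dimension ", cfg$d)
  vocab <- sort(unique(unlist(lapply(instances, `[[`, "context"))))
  ini <- init_mnm_params(cfg, vocab, word_vecs)
  params <- ini$params

  cache <- new.env(parent = emptyenv())
  ent_ids <- sort(unique(unlist(lapply(instances,
                                       function(x) c(x$gene_a, x$gene_b)))))
  params$ent <- t(vapply(ent_ids, function(id)
    .entity_vec(id, cfg, store, word_vecs, entity_words, cache),
    numeric(cfg$d)))
  rel_keys <- sort(unique(vapply(instances, function(x)
    paste(x$gene_a, x$gene_b, sep = "\r"), "")))
  params$rel <- t(vapply(rel_keys, function(key) {
    if (cfg$use_relation_embedding && !is.null(store)) {
      ab <- strsplit(key, "\r", fixed = TRUE)[[1]]
      pair_relation_vector(store, ab[1], ab[2])
    } else numeric(cfg$d)
  }, numeric(cfg$d)))

  tensors <- .make_tensors(instances, ini$words, ent_ids, rel_keys)

  trainable <- setdiff(names(params), c("ent", "rel"))
  if (cfg$finetune_kb_vectors) trainable <- names(params)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- lapply(params[trainable], function(p) p * 0)
  state$v <- lapply(params[trainable], function(p) p * 0)

  set.seed(train_cfg$seed)
  N <- length(tensors)
  trace <- numeric(train_cfg$epochs)
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- if (train_cfg$shuffle) sample.int(N) else seq_len(N)
    ep_loss <- 0
    for (b0 in seq(1L, N, by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, N)]
      lg <- mnm_loss_grad(tensors[idx], params, cfg)
      params <- .adam_step(params, lg$grads, state, trainable,
                           train_cfg$lr)
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    trace[ep] <- ep_loss / N
  }

  structure(list(cfg = cfg, train_cfg = train_cfg, params = params,
                 words = ini$words, ent_ids = ent_ids, rel_keys = rel_keys,
                 word_vecs = word_vecs, store = store,
                 entity_words = entity_words, oov_cache = cache,
                 loss_trace = trace),
            class = "mnm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mnm_model <- function(x, ...) {
  cat("mnm_model:", x$cfg$architecture, "architecture, K =", x$cfg$K,
      ", d =", x$cfg$d, "\n")
  cat("  entity source:", x$cfg$entity_source,
      "| relation embedding:", x$cfg$use_relation_embedding,
      "| attention:", x$cfg$attention_sharing,
      "| pooling:", x$cfg$pooling, "\n")
  cat("  vocabulary:", length(x$words), "tokens;",
      length(x$ent_ids), "entities\n")
  if (length(x$loss_trace))
    cat("  training loss:", format(x$loss_trace[1], digits = 4), "->",
        format(utils::tail(x$loss_trace, 1), digits = 4), "over",
        length(x$loss_trace), "epochs\n")
  invisible(x)
}

#' Score candidate instances with a trained model
#'
#' Runs the forward pass on each instance (order preserved) and applies the
#' argmax decision.  Tokens outside the training vocabulary map to the
#' trained `<unk>` vector; entities and pairs unseen in training fall back
#' to the knowledge store or averaged-word initialization.
#'
#' @param model An `mnm_model`.
#' @param instances Candidate instances (labels optional and ignored).
#' @param record_attention Also return per-layer, per-network attention
#'   weights.
#' @return Data frame `doc_id`, `gene_a`, `gene_b`, `prob1`, `label`; with
#'   `record_attention`, a list with elements `predictions` and `attention`
#'   (columns `doc_id`, `instance`, `layer`, `network`, `token`, `weight`).
#' @export
predict_instances <- function(model, instances, record_attention = FALSE) {
  cfg <- model$cfg
  params <- model$params
  n <- length(instances)
  preds <- data.frame(doc_id = character(n), gene_a = character(n),
                      gene_b = character(n), prob1 = numeric(n),
                      label = integer(n), stringsAsFactors = FALSE)
  att <- if (record_attention) vector("list", n) else NULL
  for (i in seq_len(n)) {
    inst <- instances[[i]]
    ids <- match(inst$context, model$words)
    ids[is.na(ids)] <- 1L
    e1 <- .lookup_entity(model, inst$gene_a)
    e2 <- .lookup_entity(model, inst$gene_b)
    erel <- .lookup_relation(model, inst$gene_a, inst$gene_b)
    E <- t(params$emb[ids, , drop = FALSE])
    fw <- mnm_forward(E, inst$dist1, inst$dist2, e1, e2, erel, params, cfg)
    preds$doc_id[i] <- inst$doc_id
    preds$gene_a[i] <- inst$gene_a
    preds$gene_b[i] <- inst$gene_b
    preds$prob1[i] <- fw$prob[2L]
    preds$label[i] <- predict_label(fw$prob)
    if (record_attention) {
      rows <- list()
      for (k in seq_len(cfg$K))
        for (net in seq_along(fw$alphas[[k]]))
          rows[[length(rows) + 1L]] <- data.frame(
            doc_id = inst$doc_id, instance = i, layer = k, network = net,
            token = inst$context, weight = fw$alphas[[k]][[net]],
            stringsAsFactors = FALSE)
      att[[i]] <- do.call(rbind, rows)
    }
  }
  if (record_attention)
    list(predictions = preds, attention = do.call(rbind, att))
  else preds
}

.lookup_entity <- function(model, id) {
  i <- match(id, model$ent_ids)
  if (!is.na(i)) return(model$params$ent[i, ])
  .entity_vec(id, model$cfg, model$store, model$word_vecs,
              model$entity_words, model$oov_cache)
}

.lookup_relation <- function(model, a, b) {
  if (!model$cfg$use_relation_embedding) return(numeric(model$cfg$d))
  key <- paste(a, b, sep = "\r")
  i <- match(key, model$rel_keys)
  if (!is.na(i)) return(model$params$rel[i, ])
  if (!is.null(model$store)) pair_relation_vector(model$store, a, b)
  else numeric(model$cfg$d)
}

#' Aggregate instance predictions to document-level pairs
#'
#' A (document, pair) is predicted positive iff at least one of its
#' instances is predicted positive; its score is the maximum instance
#' probability.
#'
#' @param inst_preds Data frame from [predict_instances()].
#' @return Prediction-set data frame (`doc_id`, `gene_a`, `gene_b`,
#'   `score`, `source = "model"`) holding the positive pairs.
#' @export
aggregate_document <- function(inst_preds) {
  empty <- data.frame(doc_id = character(), gene_a = character(),
                      gene_b = character(), score = numeric(),
                      source = character(), stringsAsFactors = FALSE)
  if (!nrow(inst_preds)) return(empty)
  key <- paste(inst_preds$doc_id, inst_preds$gene_a, inst_preds$gene_b,
               sep = "\r")
  pos <- tapply(inst_preds$label, key, function(x) any(x == 1L))
  score <- tapply(inst_preds$prob1, key, max)
  keys <- names(pos)[pos]
  if (!length(keys)) return(empty)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(doc_id = parts[, 1], gene_a = parts[, 2], gene_b = parts[, 3],
             score = as.numeric(score[keys]), source = "model",
             stringsAsFactors = FALSE)
}
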