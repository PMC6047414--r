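# Independent oracles used across the suite.  These deliberately avoid the
# package's vectorized code paths: everything is scalar loops, so they can
# serve as references for the production implementations.

# -- reference forward pass (loop-based, scalar arithmetic) ------------------

ref_position_percentage <- function(p, n, k, d) {
  (1 - p / n) - (k / d) * (1 - 2 * p / n)
}

ref_forward <- function(E, dist1, dist2, e1, e2, erel, params, cfg) {
  d <- cfg$d; K <- cfg$K; n <- ncol(E)
  wa_of <- function(k, net) {
    if (cfg$architecture == "single" || cfg$attention_sharing == "shared")
      list(Wa = params[[paste0("Wa.", k)]], ba = params[[paste0("ba.", k)]])
    else
      list(Wa = params[[paste0("Wa", net, ".", k)]],
           ba = params[[paste0("ba", net, ".", k)]])
  }
  softmax_ref <- function(g) {
    e <- exp(g - max(g))
    e / sum(e)
  }
  matvec <- function(M, v) {
    out <- numeric(nrow(M))
    for (i in seq_len(nrow(M)))
      for (j in seq_len(ncol(M)))
        out[i] <- out[i] + M[i, j] * v[j]
    out
  }
  run_net_dual <- function(q, dists, net) {
    for (k in seq_len(K)) {
      M <- matrix(0, d, n)
      for (i in seq_len(n)) {
        per <- ref_position_percentage(dists[i], n, k, d)
        for (j in seq_len(d)) M[j, i] <- E[j, i] * per
      }
      ab <- wa_of(k, net)
      g <- numeric(n)
      for (i in seq_len(n)) {
        s <- ab$ba
        for (j in seq_len(d)) s <- s + ab$Wa[1, j] * M[j, i]
        for (j in seq_len(d)) s <- s + ab$Wa[1, d + j] * q[j]
        g[i] <- tanh(s)
      }
      a <- softmax_ref(g)
      v <- numeric(d)
      for (i in seq_len(n))
        for (j in seq_len(d)) v[j] <- v[j] + a[i] * M[j, i]
      u <- matvec(params[[paste0("Wt.", k)]], q)
      q <- if (cfg$pooling == "sum") u + v else pmax(u, v)
    }
    q
  }
  if (cfg$architecture == "dual") {
    q1 <- run_net_dual(e1, dist1, 1L)
    q2 <- run_net_dual(e2, dist2, 2L)
  } else {
    q1 <- e1; q2 <- e2
    for (k in seq_len(K)) {
      M <- matrix(0, d, n)
      for (i in seq_len(n)) {
        per <- (ref_position_percentage(dist1[i], n, k, d) +
                ref_position_percentage(dist2[i], n, k, d)) / 2
        for (j in seq_len(d)) M[j, i] <- E[j, i] * per
      }
      ab <- wa_of(k, 1L)
      g <- numeric(n)
      for (i in seq_len(n)) {
        s <- ab$ba
        for (j in seq_len(d)) s <- s + ab$Wa[1, j] * M[j, i]
        for (j in seq_len(d)) s <- s + ab$Wa[1, d + j] * q1[j]
        for (j in seq_len(d)) s <- s + ab$Wa[1, 2 * d + j] * q2[j]
        g[i] <- tanh(s)
      }
      a <- softmax_ref(g)
      v <- numeric(d)
      for (i in seq_len(n))
        for (j in seq_len(d)) v[j] <- v[j] + a[i] * M[j, i]
      u1 <- matvec(params[[paste0("Wt.", k)]], q1)
      u2 <- matvec(params[[paste0("Wt.", k)]], q2)
      q1 <- if (cfg$pooling == "sum") u1 + v else pmax(u1, v)
      q2 <- if (cfg$pooling == "sum") u2 + v else pmax(u2, v)
    }
  }
  f <- if (cfg$use_relation_embedding) c(q1, q2, erel) else c(q1, q2)
  logit <- numeric(2)
  for (r in 1:2) {
    logit[r] <- params$bs[r]
    for (j in seq_along(f)) logit[r] <- logit[r] + params$Ws[r, j] * f[j]
  }
  softmax_ref(logit)
}

# -- brute-force candidate enumeration ---------------------------------------

brute_candidates <- function(documents, mentions, gold = NULL) {
  out <- list()
  for (r in seq_len(nrow(documents))) {
    id <- documents$doc_id[r]
    mm <- mentions[mentions$doc_id == id, , drop = FALSE]
    if (nrow(mm) < 2L) next
    col <- collapse_mentions(
      tokenize_document(documents$title[r], documents$abstract[r]), mm)
    midx <- which(!is.na(col$gene_id))
    found <- list()
    for (i in midx) for (j in midx) {
      if (i >= j) next
      if (col$gene_id[i] == col$gene_id[j]) next
      if (abs(col$sent[j] - col$sent[i]) >= 3) next
      td <- j - i
      if (!(td > 3 && td < 50)) next
      # window: 3 left of i, everything between, 3 right of j
      idx <- c()
      for (q in (i - 3):(j + 3)) {
        if (q < 1 || q > nrow(col) || q == i || q == j) next
        if ((q >= i - 3 && q < i) || (q > i && q < j) ||
            (q > j && q <= j + 3))
          idx <- c(idx, q)
      }
      toks <- c(); d1 <- c(); d2 <- c()
      for (q in idx) {
        tk <- tolower(col$token[q])
        if (!is.na(col$gene_id[q])) tk <- "gene0"
        else if (grepl("^[0-9][0-9.,%]*$", tk)) tk <- "NUMBER"
        else tk <- gsub("*", "", tk, fixed = TRUE)
        if (!nzchar(tk)) next
        toks <- c(toks, tk)
        d1 <- c(d1, max(1L, abs(q - i)))
        d2 <- c(d2, max(1L, abs(q - j)))
      }
      if (!length(toks)) next
      cp <- canonical_pair(col$gene_id[i], col$gene_id[j])
      inst <- list(doc_id = id, gene_a = cp$gene_a, gene_b = cp$gene_b,
                   p1 = i, p2 = j, context = toks,
                   dist1 = as.integer(d1), dist2 = as.integer(d2))
      if (!is.null(gold)) {
        gd <- gold[gold$doc_id == id, , drop = FALSE]
        inst$label <- as.integer(any(gd$gene_a == cp$gene_a &
                                     gd$gene_b == cp$gene_b))
      }
      found[[length(found) + 1L]] <- inst
    }
    if (length(found)) {
      o <- order(vapply(found, `[[`, 0L, "p1"),
                 vapply(found, `[[`, 0L, "p2"))
      out <- c(out, found[o])
    }
  }
  out
}

# -- misc fixtures -----------------------------------------------------------

# a small random knowledge base: 20 entities, 3 relations, 60 unique triples
tiny_kb <- function(seed = 1L, n_ent = 20L, n_rel = 3L, n_tri = 60L) {
  set.seed(seed)
  ents <- paste0("e", seq_len(n_ent))
  rows <- list()
  seen <- character()
  while (length(rows) < n_tri) {
    ht <- sample(ents, 2L)
    rl <- paste0("r", sample.int(n_rel, 1L))
    key <- paste(ht[1], rl, ht[2])
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1L]] <- data.frame(
      head_id = ht[1], relation = rl, tail_id = ht[2],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# a random candidate instance plus matching parameter set, for model tests
random_instance_setup <- function(cfg, n = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(n)) n <- sample(3:12, 1L)
  vocab <- paste0("tok", 1:15)
  inst <- list(doc_id = "d1", gene_a = "A", gene_b = "B",
               p1 = 4L, p2 = 4L + n + 1L,
               context = sample(vocab, n, replace = TRUE),
               dist1 = sample.int(n + 3L, n, replace = TRUE),
               dist2 = sample.int(n + 3L, n, replace = TRUE),
               label = sample(0:1, 1L))
  ini <- ppimnet:::init_mnm_params(cfg, vocab)
  params <- ini$params
  params$ent <- matrix(stats::rnorm(2L * cfg$d, 0, 0.5), 2L,
                       dimnames = list(c("A", "B"), NULL))
  params$rel <- matrix(stats::rnorm(cfg$d, 0, 0.5), 1L)
  tensors <- ppimnet:::.make_tensors(list(inst), ini$words, c("A", "B"),
                                     paste("A", "B", sep = "\r"))
  list(inst = inst, params = params, tensors = tensors, words = ini$words)
}

run_forward <- function(setup, cfg) {
  tn <- setup$tensors[[1]]
  E <- t(setup$params$emb[tn$ids, , drop = FALSE])
  mnm_forward(E, tn$dist1, tn$dist2, setup$params$ent[1, ],
              setup$params$ent[2, ], setup$params$rel[1, ],
              setup$params, cfg)
}

run_ref_forward <- function(setup, cfg) {
  tn <- setup$tensors[[1]]
  E <- t(setup$params$emb[tn$ids, , drop = FALSE])
  ref_forward(E, tn$dist1, tn$dist2, setup$params$ent[1, ],
              setup$params$ent[2, ], setup$params$rel[1, ],
              setup$params, cfg)
}

# numeric gradient of a loss closure by central differences
numeric_gradient <- function(loss_fn, params, names, eps = 1e-5) {
  out <- list()
  for (nm in names) {
    g <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g[i] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

max_rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(b), floor))
}
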