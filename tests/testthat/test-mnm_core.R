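test_that("position percentage follows the printed algebra", {
  # p/n = 0.5 is the symmetry point for every layer and dimension
  for (k in 1:8) expect_equal(position_percentage(5, 10, k, 100), 0.5)
  # p = n collapses to k/d
  expect_equal(position_percentage(10, 10, 3, 100), 3 / 100)
  # direct evaluation
  expect_equal(position_percentage(2, 10, 1, 100), 0.794)
  # vectorized over p
  expect_equal(position_percentage(c(2, 5, 10), 10, 1, 100),
               c(0.794, 0.5, 0.01))
  expect_error(position_percentage(1, 0, 1, 100), "n = 0")
})

test_that("memory weighting scales each column by its percentage", {
  set.seed(3)
  d <- 6L; n <- 9L
  m <- matrix(rnorm(d * n), d, n)
  dists <- sample.int(n, n, replace = TRUE)
  got <- weight_memory(m, dists, k = 2L, d = d)
  for (i in seq_len(n)) {
    per <- position_percentage(dists[i], n, 2L, d)
    expect_equal(got[, i], m[, i] * per)
  }
})

test_that("attention normalizes to a simplex and matches hand computation", {
  # equal scores -> uniform weights
  m <- matrix(rnorm(12), 3, 4)
  att <- attention(m, numeric(3), matrix(0, 1, 6), ba = 0.3)
  expect_equal(att$weights, rep(0.25, 4))

  # d = 1 hand case: g = (tanh 1, tanh 0)
  m1 <- matrix(c(0.5, -0.5), 1, 2)
  att1 <- attention(m1, 0.5, matrix(c(1, 1), 1, 2), ba = 0)
  a1 <- exp(tanh(1)) / (exp(tanh(1)) + exp(0))
  expect_equal(att1$weights[1], a1, tolerance = 1e-12)
  expect_equal(att1$v_att, a1 * 0.5 + (1 - a1) * (-0.5), tolerance = 1e-12)
  expect_equal(sum(att1$weights), 1, tolerance = 1e-12)

  # softmax shift invariance: a constant added to every score (via the
  # bias) leaves the weights unchanged
  set.seed(8)
  m2 <- matrix(rnorm(20), 4, 5)
  Wa <- matrix(rnorm(8), 1, 8)
  q <- rnorm(4)
  w0 <- attention(m2, q, Wa, ba = 0)$scores
  shift <- 1.7
  a_shift <- exp(w0 + shift) / sum(exp(w0 + shift))
  a_base <- exp(w0) / sum(exp(w0))
  expect_equal(a_shift, a_base, tolerance = 1e-12)
})

test_that("hop update is sum or coordinate-wise max of the two streams", {
  d <- 5L
  e <- rnorm(d); v <- rnorm(d)
  expect_equal(hop_update(e, numeric(d), diag(d), "sum"), e)
  got_max <- hop_update(e, v, diag(d), "max")
  expect_true(all(got_max >= e - 1e-12) && all(got_max >= v - 1e-12))
  # coordinate loop oracle
  set.seed(12)
  Wt <- matrix(rnorm(d * d), d)
  u <- as.numeric(Wt %*% e)
  expect_equal(hop_update(e, v, Wt, "sum"), u + v)
  expect_equal(hop_update(e, v, Wt, "max"),
               vapply(1:d, function(i) max(u[i], v[i]), 0))
})

test_that("forward pass matches the loop-based reference implementation", {
  variants <- list(list(), list(pooling = "max"),
                   list(attention_sharing = "separate"),
                   list(architecture = "single"),
                   list(use_relation_embedding = FALSE))
  for (vargs in variants) {
    for (s in 1:6) {
      cfg <- do.call(mnm_config, c(list(K = 3L, d = 5L, seed = s), vargs))
      setup <- random_instance_setup(cfg, seed = 100 + s)
      got <- run_forward(setup, cfg)
      want <- run_ref_forward(setup, cfg)
      expect_equal(got$prob, want, tolerance = 1e-10)
      expect_equal(sum(got$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("zero parameters give an indifferent classifier", {
  cfg <- mnm_config(K = 2L, d = 4L, seed = 1)
  setup <- random_instance_setup(cfg, seed = 9)
  params <- lapply(setup$params, function(p) p * 0)
  tn <- setup$tensors[[1]]
  E <- t(params$emb[tn$ids, , drop = FALSE])
  out <- mnm_forward(E, tn$dist1, tn$dist2, params$ent[1, ], params$ent[2, ],
                     params$rel[1, ], params, cfg)
  expect_equal(out$prob, c(0.5, 0.5))
})

test_that("K = 1 forward equals manual hop composition", {
  cfg <- mnm_config(K = 1L, d = 6L, seed = 4)
  setup <- random_instance_setup(cfg, seed = 21)
  tn <- setup$tensors[[1]]
  params <- setup$params
  E <- t(params$emb[tn$ids, , drop = FALSE])
  out <- mnm_forward(E, tn$dist1, tn$dist2, params$ent[1, ], params$ent[2, ],
                     params$rel[1, ], params, cfg)
  qs <- list()
  for (net in 1:2) {
    dists <- if (net == 1) tn$dist1 else tn$dist2
    M <- weight_memory(E, dists, k = 1L, d = cfg$d)
    att <- attention(M, params$ent[net, ], params[["Wa.1"]],
                     params[["ba.1"]])
    qs[[net]] <- hop_update(params$ent[net, ], att$v_att, params[["Wt.1"]],
                            "sum")
  }
  f <- c(qs[[1]], qs[[2]], params$rel[1, ])
  logits <- as.numeric(params$Ws %*% f + params$bs)
  expect_equal(out$prob, exp(logits) / sum(exp(logits)), tolerance = 1e-12)
})

test_that("memory behaves as a set: joint token permutations are no-ops", {
  cfg <- mnm_config(K = 3L, d = 5L, seed = 2)
  setup <- random_instance_setup(cfg, n = 8L, seed = 31)
  tn <- setup$tensors[[1]]
  params <- setup$params
  E <- t(params$emb[tn$ids, , drop = FALSE])
  base <- mnm_forward(E, tn$dist1, tn$dist2, params$ent[1, ],
                      params$ent[2, ], params$rel[1, ], params, cfg)
  set.seed(5)
  perm <- sample.int(ncol(E))
  out <- mnm_forward(E[, perm], tn$dist1[perm], tn$dist2[perm],
                     params$ent[1, ], params$ent[2, ], params$rel[1, ],
                     params, cfg)
  expect_equal(out$prob, base$prob, tolerance = 1e-12)
})

test_that("shared attention swaps outputs when the entities swap", {
  cfg <- mnm_config(K = 2L, d = 5L, seed = 6)
  setup <- random_instance_setup(cfg, n = 7L, seed = 41)
  tn <- setup$tensors[[1]]
  params <- setup$params
  E <- t(params$emb[tn$ids, , drop = FALSE])
  d <- cfg$d
  fwd <- mnm_forward(E, tn$dist1, tn$dist2, params$ent[1, ], params$ent[2, ],
                     params$rel[1, ], params, cfg)
  swp <- mnm_forward(E, tn$dist2, tn$dist1, params$ent[2, ], params$ent[1, ],
                     params$rel[1, ], params, cfg)
  expect_equal(swp$f[seq_len(d)], fwd$f[d + seq_len(d)], tolerance = 1e-12)
  expect_equal(swp$f[d + seq_len(d)], fwd$f[seq_len(d)], tolerance = 1e-12)
})

test_that("attention weights sum to one in every layer of every pass", {
  for (s in 1:5) {
    cfg <- mnm_config(K = 4L, d = 4L, seed = s)
    setup <- random_instance_setup(cfg, seed = 50 + s)
    out <- run_forward(setup, cfg)
    for (k in seq_len(cfg$K))
      for (a in out$alphas[[k]])
        expect_equal(sum(a), 1, tolerance = 1e-9)
  }
})

test_that("class decision is argmax with a conservative tie-break", {
  expect_equal(predict_label(c(0.7, 0.3)), 0L)
  expect_equal(predict_label(c(0.3, 0.7)), 1L)
  expect_equal(predict_label(c(0.5, 0.5)), 0L)
})

test_that("variant presets reproduce the named configurations", {
  mnm <- mnm_variant("MNM")
  expect_equal(mnm$entity_source, "transe")
  expect_true(mnm$use_relation_embedding)
  expect_equal(mnm$architecture, "dual")
  expect_equal(mnm$attention_sharing, "shared")
  expect_equal(mnm$pooling, "sum")
  expect_equal(mnm$K, 4L)

  ae <- mnm_variant("AE")
  expect_equal(ae$entity_source, "averaged_words")
  expect_false(ae$use_relation_embedding)
  expect_equal(mnm_variant("TE")$entity_source, "transe")
  expect_true(mnm_variant("AE-TR")$use_relation_embedding)
  expect_equal(mnm_variant("MNM-DA")$attention_sharing, "separate")
  expect_equal(mnm_variant("MNM-Max")$pooling, "max")
  expect_equal(mnm_variant("MNM-Single")$architecture, "single")
  expect_error(mnm_variant("bogus"), "unknown variant")
})
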