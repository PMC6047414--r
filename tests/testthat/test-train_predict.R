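test_that("cross-entropy matches closed forms", {
  # confident correct predictions: loss at the clamp floor
  p <- rbind(c(1, 0), c(0, 1))
  expect_lt(cross_entropy(p, c(0L, 1L)), 1e-10 + -log(1 - 1e-12))
  # uniform predictions: ln 2 per instance
  u <- matrix(0.5, 4, 2)
  expect_equal(cross_entropy(u, c(0L, 1L, 0L, 1L)), log(2))
  # hand computation
  h <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4))
  expect_equal(cross_entropy(h, c(0L, 1L, 1L)),
               -(log(0.9) + log(0.8) + log(0.4)) / 3)
  expect_error(cross_entropy(h, c(0L, 1L)), "different lengths")
})

make_training_fixture <- function(n_docs = 40, seed = 17, dim = 8L) {
  cfg <- sim_config(n_docs = n_docs, seed = seed, dim = dim)
  corp <- simulate_corpus(cfg)
  kb <- simulate_kb(cfg, corp$gold)
  wv <- simulate_word_vectors(cfg)
  inst <- build_candidates(corp$documents, corp$mentions, corp$gold)
  store <- train_transe(kb, transe_config(dim = cfg$dim, epochs = 30,
                                          seed = seed),
                        word_vecs = wv)
  list(cfg = cfg, corp = corp, inst = inst, store = store, wv = wv,
       ew = entity_words_from_mentions(corp$mentions))
}

test_that("zero epochs returns the initialization; training is seeded", {
  fx <- make_training_fixture(12)
  mcfg <- mnm_config(K = 2L, d = 8L, seed = 3)
  m0 <- train_mnm(fx$inst, mcfg, mnm_train_config(epochs = 0L, seed = 1),
                  word_vecs = fx$wv, store = fx$store, entity_words = fx$ew)
  ini <- init_mnm_params(mcfg,
                         sort(unique(unlist(lapply(fx$inst, `[[`,
                                                   "context")))),
                         word_vecs = fx$wv)
  for (nm in names(ini$params))
    expect_identical(m0$params[[nm]], ini$params[[nm]])
  expect_length(m0$loss_trace, 0L)

  ma <- train_mnm(fx$inst, mcfg, mnm_train_config(epochs = 3L, seed = 5),
                  word_vecs = fx$wv, store = fx$store, entity_words = fx$ew)
  mb <- train_mnm(fx$inst, mcfg, mnm_train_config(epochs = 3L, seed = 5),
                  word_vecs = fx$wv, store = fx$store, entity_words = fx$ew)
  expect_identical(ma$loss_trace, mb$loss_trace)
  expect_identical(ma$params$emb, mb$params$emb)
})

test_that("training reduces the loss on a learnable corpus", {
  fx <- make_training_fixture(40, dim = 16L)
  model <- train_mnm(fx$inst, mnm_config(K = 2L, d = 16L, seed = 3),
                     mnm_train_config(epochs = 25L, seed = 7),
                     word_vecs = fx$wv, store = fx$store,
                     entity_words = fx$ew)
  expect_lt(utils::tail(model$loss_trace, 1), model$loss_trace[1])
})

test_that("degenerate label sets warn but proceed", {
  fx <- make_training_fixture(12)
  onesided <- lapply(fx$inst, function(x) { x$label <- 1L; x })
  expect_warning(
    train_mnm(onesided, mnm_config(K = 1L, d = 4L, seed = 2),
              mnm_train_config(epochs = 1L, seed = 1)),
    "same label")
})

test_that("instance prediction preserves order and stays in range", {
  fx <- make_training_fixture(25)
  model <- train_mnm(fx$inst, mnm_config(K = 2L, d = 8L, seed = 4),
                     mnm_train_config(epochs = 5L, seed = 9),
                     word_vecs = fx$wv, store = fx$store,
                     entity_words = fx$ew)
  expect_equal(nrow(predict_instances(model, list())), 0L)
  preds <- predict_instances(model, fx$inst)
  expect_equal(nrow(preds), length(fx$inst))
  expect_equal(preds$doc_id, vapply(fx$inst, `[[`, "", "doc_id"))
  expect_true(all(preds$prob1 >= 0 & preds$prob1 <= 1))
  expect_true(all(preds$label %in% 0:1))
  # scoring is stateless: chunked prediction equals one pass
  half <- length(fx$inst) %/% 2
  chunked <- rbind(predict_instances(model, fx$inst[seq_len(half)]),
                   predict_instances(model, fx$inst[-seq_len(half)]))
  expect_equal(chunked$prob1, preds$prob1)
})

test_that("a trained model survives a plain-text save/load round trip", {
  fx <- make_training_fixture(15, dim = 6L)
  model <- train_mnm(fx$inst, mnm_config(K = 2L, d = 6L, seed = 8),
                     mnm_train_config(epochs = 3L, seed = 2),
                     word_vecs = fx$wv, store = fx$store,
                     entity_words = fx$ew)
  dir <- withr::local_tempdir()
  save_mnm_model(model, dir)
  model2 <- load_mnm_model(dir)
  p1 <- predict_instances(model, fx$inst)
  p2 <- predict_instances(model2, fx$inst)
  expect_equal(p2$prob1, p1$prob1, tolerance = 1e-6)
  expect_equal(p2$label, p1$label)
})

test_that("document aggregation is any-positive with max score", {
  ip <- data.frame(doc_id = rep("d1", 3), gene_a = "A", gene_b = "B",
                   prob1 = c(0.9, 0.2, 0.1), label = c(1L, 0L, 0L),
                   stringsAsFactors = FALSE)
  agg <- aggregate_document(ip)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$score, 0.9)
  expect_equal(agg$source, "model")

  ip$label <- 0L
  expect_equal(nrow(aggregate_document(ip)), 0L)
})

test_that("aggregation equals the any() oracle and is monotone", {
  set.seed(44)
  for (rep in 1:10) {
    n <- 30
    ip <- data.frame(
      doc_id = sample(paste0("d", 1:4), n, replace = TRUE),
      gene_a = sample(c("1", "2"), n, replace = TRUE),
      gene_b = sample(c("3", "4"), n, replace = TRUE),
      prob1 = runif(n), label = sample(0:1, n, replace = TRUE),
      stringsAsFactors = FALSE)
    agg <- aggregate_document(ip)
    key <- paste(ip$doc_id, ip$gene_a, ip$gene_b)
    want <- sort(unique(key[ave(ip$label, key, FUN = max) == 1]))
    expect_equal(sort(paste(agg$doc_id, agg$gene_a, agg$gene_b)), want)

    # flipping any instance positive never removes a predicted pair
    flip <- sample.int(n, 1)
    ip2 <- ip; ip2$label[flip] <- 1L
    agg2 <- aggregate_document(ip2)
    expect_true(all(paste(agg$doc_id, agg$gene_a, agg$gene_b) %in%
                    paste(agg2$doc_id, agg2$gene_a, agg2$gene_b)))
  }
})
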