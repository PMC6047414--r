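test_that("sentence support requires strictly more than N co-mentions", {
  g <- function(k) list(paste0("GENE", k), as.character(k))
  three <- doc_from_sentences("d1", list(
    list("The", "proteins", g(1), "and", g(2), "interact"),
    list("Moreover", g(1), "binds", g(2), "strongly"),
    list("Again", g(1), "with", g(2), "here"),
    list("Filler", "sentence", "only")))
  out3 <- sentence_support_pairs(three$documents, three$mentions, 2L)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$gene_a, "1")
  expect_equal(out3$source, "rule")

  two <- doc_from_sentences("d2", list(
    list("The", "proteins", g(1), "and", g(2), "interact"),
    list("Moreover", g(1), "binds", g(2), "strongly"),
    list("But", g(1), "alone", "now")))
  expect_equal(nrow(sentence_support_pairs(two$documents, two$mentions, 2L)),
               0L)
})

test_that("sentence support equals a brute-force sentence-by-pair scan", {
  set.seed(27)
  for (rep in 1:5) {
    genes <- as.character(1:4)
    sents <- lapply(1:8, function(i) {
      picked <- sample(genes, sample(0:3, 1))
      toks <- as.list(c("Filler", sample(letters, 3)))
      for (gid in picked)
        toks[[length(toks) + 1L]] <- list(paste0("GENE", gid), gid)
      toks
    })
    doc <- doc_from_sentences(paste0("r", rep), sents)
    if (is.null(doc$mentions)) next
    got <- sentence_support_pairs(doc$documents, doc$mentions, 2L)
    # oracle: count sentences containing both genes of each pair
    per_sent <- lapply(sents, function(s)
      unique(vapply(Filter(is.list, s), `[[`, "", 2)))
    want <- 0L
    for (a in genes) for (b in genes) {
      if (a >= b) next
      cnt <- sum(vapply(per_sent, function(gs) all(c(a, b) %in% gs), TRUE))
      if (cnt > 2L) {
        want <- want + 1L
        expect_true(any(got$gene_a == a & got$gene_b == b))
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("merging is a provenance-keeping set union", {
  ps <- function(doc, a, b, src) data.frame(
    doc_id = doc, gene_a = a, gene_b = b, score = 0.5, source = src,
    stringsAsFactors = FALSE)
  m <- rbind(ps("d1", "1", "2", "model"), ps("d1", "3", "4", "model"),
             ps("d2", "1", "5", "model"))
  r <- rbind(ps("d3", "1", "2", "rule"), ps("d4", "2", "3", "rule"))
  out <- merge_predictions(m, r)
  expect_equal(nrow(out), 5L)
  expect_setequal(out$source, c("model", "rule"))

  same <- merge_predictions(m, transform(m, source = "rule", score = 1))
  expect_equal(nrow(same), 3L)
  expect_true(all(same$source == "both"))
  expect_true(all(same$score == 1))
})

test_that("merge equals the set-union oracle on random sets", {
  set.seed(61)
  for (rep in 1:10) {
    mk <- function(n, src) data.frame(
      doc_id = sample(paste0("d", 1:3), n, TRUE),
      gene_a = sample(c("1", "2"), n, TRUE),
      gene_b = sample(c("3", "4"), n, TRUE),
      score = runif(n), source = src, stringsAsFactors = FALSE)
    m <- mk(6, "model"); r <- mk(5, "rule")
    out <- merge_predictions(m, r)
    want <- sort(unique(c(paste(m$doc_id, m$gene_a, m$gene_b),
                          paste(r$doc_id, r$gene_a, r$gene_b))))
    expect_equal(sort(paste(out$doc_id, out$gene_a, out$gene_b)), want)
  }
})

test_that("micro evaluation pools counts over documents", {
  gold <- data.frame(doc_id = c("d1", "d1", "d2", "d3"),
                     gene_a = c("1", "3", "1", "2"),
                     gene_b = c("2", "4", "9", "7"),
                     stringsAsFactors = FALSE)
  # perfect predictions
  perfect <- transform(gold, score = 1, source = "model")
  res <- evaluate_micro(perfect, gold)
  expect_equal(c(res$precision, res$recall, res$f1), c(1, 1, 1))

  # 5 predictions, 3 correct, over 4 gold pairs
  preds <- rbind(perfect[1:3, ],
                 data.frame(doc_id = c("d2", "d9"), gene_a = c("5", "1"),
                            gene_b = c("6", "2"), score = 1,
                            source = "model", stringsAsFactors = FALSE))
  res2 <- evaluate_micro(preds, gold)
  expect_equal(res2$precision, 0.6)
  expect_equal(res2$recall, 0.75)
  expect_equal(res2$f1, 2 * 0.6 * 0.75 / 1.35)

  # degenerate conventions
  none <- perfect[0, ]
  res3 <- evaluate_micro(none, gold)
  expect_equal(c(res3$precision, res3$recall, res3$f1), c(0, 0, 0))

  # duplicates deduplicate with a warning
  expect_warning(res4 <- evaluate_micro(rbind(perfect, perfect[1, ]), gold),
                 "deduplicated")
  expect_equal(res4$precision, 1)
})

test_that("micro-F matches an independent confusion-count implementation", {
  set.seed(71)
  for (rep in 1:10) {
    mk <- function(n) data.frame(
      doc_id = sample(paste0("d", 1:4), n, TRUE),
      gene_a = sample(as.character(1:3), n, TRUE),
      gene_b = sample(as.character(4:6), n, TRUE),
      stringsAsFactors = FALSE)
    preds <- unique(mk(12)); gold <- unique(mk(10))
    res <- evaluate_micro(preds, gold)
    pk <- paste(preds$doc_id, preds$gene_a, preds$gene_b)
    gk <- paste(gold$doc_id, gold$gene_a, gold$gene_b)
    tp <- 0L
    for (k in pk) if (k %in% gk) tp <- tp + 1L
    p <- if (length(pk)) tp / length(pk) else 0
    r <- if (length(gk)) tp / length(gk) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(res$f1, f)
    expect_equal(res$tp, tp)
  }
})

test_that("merging with rules never lowers recall", {
  cfg <- sim_config(n_docs = 25, seed = 55)
  corp <- simulate_corpus(cfg)
  model_set <- data.frame(doc_id = corp$gold$doc_id[1:5],
                          gene_a = corp$gold$gene_a[1:5],
                          gene_b = corp$gold$gene_b[1:5],
                          score = 1, source = "model",
                          stringsAsFactors = FALSE)
  rule_set <- sentence_support_pairs(corp$documents, corp$mentions, 2L)
  base <- evaluate_micro(model_set, corp$gold)
  merged <- evaluate_micro(merge_predictions(model_set, rule_set), corp$gold)
  expect_gte(merged$recall, base$recall)
})
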