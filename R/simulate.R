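#' Synthetic corpus configuration
#'
#' Controls a generator that emulates the structure of an annotated PPIm
#' corpus: abstracts with protein mentions laid out at controllable
#' sentence/token distances, document-level gold pairs, interaction
#' trigger words planted near interacting pairs, a knowledge base whose
#' triples are correlated with the document labels, and random word
#' vectors.  Defaults define the reference study conditions used
#' throughout the test suite.
#'
#' @param n_docs Number of documents.
#' @param n_genes Size of the gene pool (IDs `"1"..n_genes`, surfaces
#'   `GENE1..`).
#' @param vocab_size Number of filler word types (Zipf-distributed).
#' @param genes_per_doc Range (min, max) of distinct genes per document.
#' @param tokens_per_sentence Range for filler-sentence length.
#' @param sentences_per_doc Range for the minimum number of sentences per
#'   document (padded with filler sentences).
#' @param positive_rate Probability that a gene pair co-mentioned in a
#'   document is a gold interacting pair.
#' @param trigger_lexicon Interaction/mutation trigger words.
#' @param planting_prob Probability a gold pair's co-mention span contains
#'   a trigger token.
#' @param background_rate Probability a non-gold pair's span contains a
#'   trigger token.
#' @param candidate_share Share of co-mention layouts placed so that the
#'   pair satisfies the candidate distance rules.
#' @param cross_sentence_prob Probability a co-mention spans two adjacent
#'   sentences instead of one.
#' @param kb_consistency Probability a gold pair is backed by a KB triple.
#' @param decoy_rate Decoy (non-gold) triples per gold pair, on average.
#' @param n_relations Number of relation labels in the KB.
#' @param dim Word-vector dimension.
#' @param seed Base RNG seed (corpus, KB and vectors use fixed offsets of
#'   it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_docs = 100L, n_genes = 50L, vocab_size = 200L,
                       genes_per_doc = c(2L, 3L),
                       tokens_per_sentence = c(6L, 12L),
                       sentences_per_doc = c(4L, 8L),
                       positive_rate = 0.5,
                       trigger_lexicon = c("phosphorylation", "mutant",
                                           "binds", "kinase", "interact",
                                           "complex"),
                       planting_prob = 0.9, background_rate = 0.05,
                       candidate_share = 1.0, cross_sentence_prob = 0.2,
                       kb_consistency = 0.9, decoy_rate = 0.5,
                       n_relations = 5L, dim = 32L, seed = 1L) {
  rates <- c(positive_rate, planting_prob, background_rate,
             candidate_share, cross_sentence_prob, kb_consistency)
  stopifnot(all(rates >= 0 & rates <= 1), n_docs >= 1L, n_genes >= 2L,
            vocab_size >= 10L, genes_per_doc[1] >= 2L,
            diff(genes_per_doc) >= 0, diff(tokens_per_sentence) >= 0,
            dim >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

.fillers <- function(cfg) paste0("w", seq_len(cfg$vocab_size))

# uniform integer in [a, b], safe when a == b
.rint <- function(a, b) if (a >= b) a else a + sample.int(b - a + 1L, 1L) - 1L

.zipf_sample <- function(cfg, n) {
  w <- 1 / seq_len(cfg$vocab_size)
  .fillers(cfg)[sample.int(cfg$vocab_size, n, replace = TRUE, prob = w)]
}

.cap <- function(x) {
  substr(x, 1L, 1L) <- toupper(substr(x, 1L, 1L))
  x
}

#' Generate a synthetic annotated corpus
#'
#' Each document receives one co-mention layout per gene pair: the two
#' mentions are placed 5-14 tokens apart within a sentence (or across two
#' adjacent sentences), followed by two buffer sentences so that distinct
#' layouts never satisfy the sentence-distance rule jointly.  Gold pairs
#' get a trigger token inside the between-span with probability
#' `planting_prob`; non-gold pairs with probability `background_rate`.  A
#' `1 - candidate_share` share of layouts is compressed below the minimum
#' token distance so the pair is discarded by the candidate rules.
#'
#' @param cfg A [sim_config()].
#' @return List of data frames: `documents`, `mentions` (PubTator-style
#'   offsets over `title + " " + abstract`), `gold` (`doc_id`, `gene_a`,
#'   `gene_b`).
#' @export
simulate_corpus <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  docs <- list(); ments <- list(); golds <- list()
  for (di in seq_len(cfg$n_docs)) {
    id <- paste0("d", di)
    ngen <- .rint(cfg$genes_per_doc[1], cfg$genes_per_doc[2])
    genes <- sample.int(cfg$n_genes, ngen)
    combos <- utils::combn(genes, 2L)
    # sentences as token vectors; gene tokens tagged via names
    sentences <- list()
    add_sentence <- function(toks) {
      sentences[[length(sentences) + 1L]] <<- toks
    }
    filler_sentence <- function() {
      n <- .rint(cfg$tokens_per_sentence[1], cfg$tokens_per_sentence[2])
      .zipf_sample(cfg, n)
    }
    for (ci in seq_len(ncol(combos))) {
      a <- combos[1L, ci]; b <- combos[2L, ci]
      positive <- stats::runif(1) < cfg$positive_rate
      passes <- stats::runif(1) < cfg$candidate_share
      tok_dist <- if (passes) .rint(5L, 14L) else 2L
      gap <- tok_dist - 1L  # between-span length
      between <- .zipf_sample(cfg, gap)
      plant <- stats::runif(1) <
        (if (positive) cfg$planting_prob else cfg$background_rate)
      if (plant && gap >= 1L)
        between[sample.int(gap, 1L)] <-
          sample(cfg$trigger_lexicon, 1L)
      lead <- .zipf_sample(cfg, .rint(2L, 4L))
      tail_ <- .zipf_sample(cfg, .rint(2L, 4L))
      mA <- stats::setNames(paste0("GENE", a), as.character(a))
      mB <- stats::setNames(paste0("GENE", b), as.character(b))
      cross <- passes && gap >= 4L &&
        stats::runif(1) < cfg$cross_sentence_prob
      if (cross) {
        cut <- .rint(2L, gap - 1L)
        add_sentence(c(lead, mA, between[seq_len(cut)]))
        add_sentence(c(between[seq(cut + 1L, gap)], mB, tail_))
      } else {
        add_sentence(c(lead, mA, between, mB, tail_))
      }
      add_sentence(filler_sentence())
      add_sentence(filler_sentence())
      if (positive)
        golds[[length(golds) + 1L]] <- data.frame(
          doc_id = id, gene_a = as.character(a), gene_b = as.character(b),
          stringsAsFactors = FALSE)
    }
    min_sents <- .rint(cfg$sentences_per_doc[1], cfg$sentences_per_doc[2])
    while (length(sentences) < min_sents) add_sentence(filler_sentence())

    title <- paste0("Protein interaction report ", di, ".")
    # materialize abstract with offsets; abstract starts at nchar(title)+1
    pos <- nchar(title) + 1L
    abstract_parts <- character()
    for (si in seq_along(sentences)) {
      toks <- sentences[[si]]
      toks[1] <- .cap(toks[1])
      for (ti in seq_along(toks)) {
        tok <- toks[ti]
        gene <- names(sentences[[si]])[ti]
        if (!is.null(gene) && !is.na(gene) && nzchar(gene))
          ments[[length(ments) + 1L]] <- data.frame(
            doc_id = id, start = pos, length = nchar(tok), surface = tok,
            type = "Gene", gene_id = gene, stringsAsFactors = FALSE)
        abstract_parts <- c(abstract_parts, tok)
        pos <- pos + nchar(tok) +
          (if (ti < length(toks)) 1L else 0L)  # following space
      }
      abstract_parts[length(abstract_parts)] <-
        paste0(abstract_parts[length(abstract_parts)], ".")
      pos <- pos + 2L  # "." plus inter-sentence space
    }
    abstract <- paste(abstract_parts, collapse = " ")
    docs[[length(docs) + 1L]] <- data.frame(
      doc_id = id, title = title, abstract = abstract,
      stringsAsFactors = FALSE)
  }
  documents <- do.call(rbind, docs)
  mentions <- if (length(ments)) do.call(rbind, ments) else
    data.frame(doc_id = character(), start = integer(), length = integer(),
               surface = character(), type = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  gold <- if (length(golds)) unique(do.call(rbind, golds)) else
    data.frame(doc_id = character(), gene_a = character(),
               gene_b = character(), stringsAsFactors = FALSE)
  if (nrow(gold)) {
    cp <- canonical_pair(gold$gene_a, gold$gene_b)
    gold$gene_a <- cp$gene_a; gold$gene_b <- cp$gene_b
    gold <- unique(gold)
  }
  validate_mentions(documents, mentions)
  list(documents = documents, mentions = mentions, gold = gold)
}

#' Generate a synthetic knowledge base
#'
#' Every unique gold pair becomes a triple with probability
#' `kb_consistency`, under a small relation vocabulary; decoy triples over
#' non-gold pairs are added at `decoy_rate` decoys per gold pair.  No
#' duplicates are emitted.
#'
#' @param cfg A [sim_config()].
#' @param gold Gold-pair data frame from [simulate_corpus()].
#' @return Triple data frame (`head_id`, `relation`, `tail_id`).
#' @export
simulate_kb <- function(cfg, gold) {
  set.seed(cfg$seed + 1000L)
  rels <- paste0("rel", seq_len(cfg$n_relations))
  upairs <- unique(gold[, c("gene_a", "gene_b")])
  rows <- list()
  for (i in seq_len(nrow(upairs))) {
    if (stats::runif(1) < cfg$kb_consistency)
      rows[[length(rows) + 1L]] <- data.frame(
        head_id = upairs$gene_a[i], relation = sample(rels, 1L),
        tail_id = upairs$gene_b[i], stringsAsFactors = FALSE)
  }
  gold_keys <- paste(upairs$gene_a, upairs$gene_b)
  n_decoys <- round(cfg$decoy_rate * max(1L, nrow(upairs)))
  tries <- 0L
  while (n_decoys > 0L && tries < 50L * n_decoys) {
    tries <- tries + 1L
    ab <- sample.int(cfg$n_genes, 2L)
    cp <- canonical_pair(as.character(ab[1]), as.character(ab[2]))
    if (paste(cp$gene_a, cp$gene_b) %in% gold_keys) next
    rows[[length(rows) + 1L]] <- data.frame(
      head_id = cp$gene_a, relation = sample(rels, 1L),
      tail_id = cp$gene_b, stringsAsFactors = FALSE)
    n_decoys <- n_decoys - 1L
  }
  if (!length(rows))
    return(data.frame(head_id = character(), relation = character(),
                      tail_id = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Generate random word vectors
#'
#' Unit-norm vectors at dimension `cfg$dim` for the full generator
#' vocabulary: filler words, trigger words, lowercased gene surfaces and
#' the two mask tokens.
#'
#' @param cfg A [sim_config()].
#' @return Matrix with words in rows (unit L2 norm each).
#' @export
simulate_word_vectors <- function(cfg) {
  set.seed(cfg$seed + 2000L)
  vocab <- c(.fillers(cfg), cfg$trigger_lexicon,
             paste0("gene", seq_len(cfg$n_genes)), "gene0", "NUMBER")
  m <- matrix(stats::rnorm(length(vocab) * cfg$dim), nrow = length(vocab),
              dimnames = list(vocab, NULL))
  m / sqrt(rowSums(m^2))
}

#' Write a complete synthetic dataset to disk
#'
#' Produces the four pipeline inputs under `dir`: `corpus.pubtator`,
#' `gold.tsv`, `triples.tsv`, `vectors.txt`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  corp <- simulate_corpus(cfg)
  kb <- simulate_kb(cfg, corp$gold)
  wv <- simulate_word_vectors(cfg)
  paths <- c(corpus = file.path(dir, "corpus.pubtator"),
             gold = file.path(dir, "gold.tsv"),
             triples = file.path(dir, "triples.tsv"),
             vectors = file.path(dir, "vectors.txt"))
  write_pubtator(corp$documents, corp$mentions, paths[["corpus"]])
  write_pairs_tsv(corp$gold, paths[["gold"]])
  write_triples_tsv(kb, paths[["triples"]])
  write_word_vectors(wv, paths[["vectors"]])
  invisible(paths)
}
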