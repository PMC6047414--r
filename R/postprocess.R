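#' Sentence-support rule
#'
#' A gene-ID pair co-mentioned in strictly more than `support` sentences of
#' a document (both genes mentioned in the same sentence) is declared
#' interacting.  The default threshold of 2 follows the rule used by the
#' top-ranked system on the shared task this pipeline targets.
#'
#' @param documents,mentions Data frames as returned by [read_pubtator()].
#' @param support Sentence-support threshold N (a pair needs > N supporting
#'   sentences).
#' @return Prediction-set data frame (`doc_id`, `gene_a`, `gene_b`,
#'   `score = 1`, `source = "rule"`).
#' @export
sentence_support_pairs <- function(documents, mentions, support = 2L) {
  rows <- list()
  for (r in seq_len(nrow(documents))) {
    id <- documents$doc_id[r]
    mm <- mentions[mentions$doc_id == id, , drop = FALSE]
    if (nrow(mm) < 2L) next
    toks <- tokenize_document(documents$title[r], documents$abstract[r])
    col <- collapse_mentions(toks, mm)
    gm <- col[!is.na(col$gene_id), c("gene_id", "sent"), drop = FALSE]
    counts <- new.env(parent = emptyenv())
    for (s in unique(gm$sent)) {
      genes <- unique(gm$gene_id[gm$sent == s])
      if (length(genes) < 2L) next
      combos <- utils::combn(sort(genes), 2L)
      for (j in seq_len(ncol(combos))) {
        key <- paste(combos[1L, j], combos[2L, j], sep = "\r")
        assign(key, (if (exists(key, counts)) get(key, counts) else 0L) + 1L,
               envir = counts)
      }
    }
    for (key in ls(counts)) {
      if (get(key, counts) > support) {
        ab <- strsplit(key, "\r", fixed = TRUE)[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = id, gene_a = ab[1], gene_b = ab[2], score = 1,
          source = "rule", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(doc_id = character(), gene_a = character(),
                      gene_b = character(), score = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$doc_id, out$gene_a, out$gene_b), , drop = FALSE]
}

#' Merge model and rule predictions
#'
#' Set union on (document, unordered pair); provenance is kept as `model`,
#' `rule`, or `both`, and the score of a pair found by both is the maximum.
#'
#' @param model_set,rule_set Prediction-set data frames.
#' @return Merged prediction-set data frame.
#' @export
merge_predictions <- function(model_set, rule_set) {
  both <- rbind(model_set[, c("doc_id", "gene_a", "gene_b", "score",
                              "source")],
                rule_set[, c("doc_id", "gene_a", "gene_b", "score",
                             "source")])
  if (!nrow(both)) return(both)
  key <- paste(both$doc_id, both$gene_a, both$gene_b, sep = "\r")
  out <- both[!duplicated(key), , drop = FALSE]
  okey <- key[!duplicated(key)]
  src <- tapply(both$source, key, function(s)
    if (length(unique(s)) > 1L) "both" else unique(s))
  score <- tapply(both$score, key, max)
  out$source <- as.character(src[okey])
  out$score <- as.numeric(score[okey])
  rownames(out) <- NULL
  out[order(out$doc_id, out$gene_a, out$gene_b), , drop = FALSE]
}

#' Micro-averaged exact-match evaluation
#'
#' Pools true positives, false positives and false negatives over all
#' documents (every unordered gene-ID pair weighted equally), then computes
#' precision, recall and F1.  Zero denominators give 0.  A duplicate
#' predicted pair within a document is counted once, with a warning.
#'
#' @param predictions Prediction-set data frame (`doc_id`, `gene_a`,
#'   `gene_b`).
#' @param gold Gold-pair data frame (`doc_id`, `gene_a`, `gene_b`).
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_micro <- function(predictions, gold) {
  pkey <- unique_pred_keys(predictions)
  gkey <- paste(gold$doc_id, gold$gene_a, gold$gene_b, sep = "\r")
  gkey <- unique(gkey)
  tp <- sum(pkey %in% gkey)
  fp <- length(pkey) - tp
  fn <- length(gkey) - tp
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f)
}

unique_pred_keys <- function(predictions) {
  if (!nrow(predictions)) return(character())
  cp <- canonical_pair(predictions$gene_a, predictions$gene_b)
  key <- paste(predictions$doc_id, cp$gene_a, cp$gene_b, sep = "\r")
  if (anyDuplicated(key))
    warning("duplicate predicted pair(s) within a document; deduplicated")
  unique(key)
}
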