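#' Mention-pair distance rules
#'
#' A mention pair survives iff the sentence distance is strictly less than 3
#' and the token distance (between the collapsed mention-head positions,
#' measured before mention removal) is strictly more than 3 and strictly
#' less than 50.
#'
#' @param sent1,sent2 0-based sentence indices of the two mentions.
#' @param p1,p2 Token positions of the two mentions in the collapsed stream.
#' @return Logical vector.
#' @export
apply_distance_rules <- function(sent1, sent2, p1, p2) {
  td <- abs(p2 - p1)
  abs(sent2 - sent1) < 3 & td > 3 & td < 50
}

#' Enumerate candidate mention pairs in one document
#'
#' All unordered pairs of protein mentions with distinct gene IDs.  In
#' training mode each pair is labeled 1 iff its gene-ID pair is in the
#' document's gold set (distant labeling), else 0.
#'
#' @param collapsed Collapsed token stream from [collapse_mentions()].
#' @param gold Data frame of gold pairs for this document (`gene_a`,
#'   `gene_b`, canonicalized), or `NULL` for prediction mode.
#' @return Data frame `p1`, `p2` (token positions, `p1 < p2`), `sent1`,
#'   `sent2`, `gene_a`, `gene_b` and (training mode) `label`.
#' @export
enumerate_mention_pairs <- function(collapsed, gold = NULL) {
  idx <- which(!is.na(collapsed$gene_id))
  empty <- data.frame(p1 = integer(), p2 = integer(), sent1 = integer(),
                      sent2 = integer(), gene_a = character(),
                      gene_b = character(), stringsAsFactors = FALSE)
  if (!is.null(gold)) empty$label <- integer()
  if (length(idx) < 2L) return(empty)
  combos <- utils::combn(idx, 2L)
  p1 <- combos[1L, ]; p2 <- combos[2L, ]
  g1 <- collapsed$gene_id[p1]; g2 <- collapsed$gene_id[p2]
  keep <- g1 != g2
  if (!any(keep)) return(empty)
  p1 <- p1[keep]; p2 <- p2[keep]
  cp <- canonical_pair(collapsed$gene_id[p1], collapsed$gene_id[p2])
  out <- data.frame(p1 = p1, p2 = p2,
                    sent1 = collapsed$sent[p1], sent2 = collapsed$sent[p2],
                    gene_a = cp$gene_a, gene_b = cp$gene_b,
                    stringsAsFactors = FALSE)
  if (!is.null(gold)) {
    key <- paste(out$gene_a, out$gene_b)
    out$label <- as.integer(key %in% paste(gold$gene_a, gold$gene_b))
  }
  out
}

.numeric_regex <- "^[0-9][0-9.,%]*$"

#' Build the masked context of a candidate pair
#'
#' The context is the three tokens left of the first mention, the tokens
#' between the two mentions, and the three tokens right of the second
#' mention (fewer at a document edge; no padding).  The pair's own mentions
#' are removed; any other protein mention becomes `"gene0"`; numeric tokens
#' become `"NUMBER"`; configured special characters are stripped (a token
#' reduced to the empty string is dropped); everything is lowercased.
#' `dist1`/`dist2` are token-count distances from each kept token to the
#' removed mention slots (minimum 1).
#'
#' @param collapsed Collapsed token stream.
#' @param p1,p2 Token positions of the pair (`p1 < p2`).
#' @param special_chars Characters removed from context tokens.
#' @return List with `context` (character), `dist1`, `dist2` (integer), or
#'   `NULL` if masking leaves an empty context.
#' @export
build_context <- function(collapsed, p1, p2, special_chars = "*") {
  n_tok <- nrow(collapsed)
  idx <- c(seq.int(max(1L, p1 - 3L), p1 - 1L),
           if (p2 - p1 > 1L) seq.int(p1 + 1L, p2 - 1L),
           if (p2 < n_tok) seq.int(p2 + 1L, min(n_tok, p2 + 3L)))
  idx <- idx[idx >= 1L & idx <= n_tok]
  if (!length(idx)) return(NULL)
  toks <- tolower(collapsed$token[idx])
  is_gene <- !is.na(collapsed$gene_id[idx])
  toks[is_gene] <- "gene0"
  num <- !is_gene & grepl(.numeric_regex, toks)
  toks[num] <- "NUMBER"
  if (length(special_chars)) {
    plain <- !is_gene & !num
    for (ch in special_chars)
      toks[plain] <- gsub(ch, "", toks[plain], fixed = TRUE)
  }
  keep <- nzchar(toks)
  if (!any(keep)) return(NULL)
  idx <- idx[keep]
  list(context = toks[keep],
       dist1 = pmax(1L, abs(idx - p1)),
       dist2 = pmax(1L, abs(idx - p2)))
}

#' Generate candidate instances from annotated documents
#'
#' The full pre-processing pipeline: tokenize and segment each document,
#' collapse mentions, enumerate mention pairs with distinct gene IDs, apply
#' the sentence/token distance rules, and build masked contexts.  With
#' `gold` supplied, instances carry distant labels; without, labels are
#' absent (prediction mode).
#'
#' @param documents,mentions Data frames as returned by [read_pubtator()].
#' @param gold Gold pairs data frame (`doc_id`, `gene_a`, `gene_b`) or
#'   `NULL`.
#' @param special_chars Characters stripped from context tokens.
#' @return A list of candidate instances; each is a list with `doc_id`,
#'   `gene_a`, `gene_b`, `p1`, `p2`, `context`, `dist1`, `dist2` and
#'   optionally `label`.
#' @export
build_candidates <- function(documents, mentions, gold = NULL,
                             special_chars = "*") {
  out <- list()
  for (r in seq_len(nrow(documents))) {
    id <- documents$doc_id[r]
    mm <- mentions[mentions$doc_id == id, , drop = FALSE]
    if (nrow(mm) < 2L) next
    toks <- tokenize_document(documents$title[r], documents$abstract[r])
    col <- collapse_mentions(toks, mm)
    gd <- if (is.null(gold)) NULL else
      gold[gold$doc_id == id, c("gene_a", "gene_b"), drop = FALSE]
    pairs <- enumerate_mention_pairs(col, gd)
    if (!nrow(pairs)) next
    keep <- apply_distance_rules(pairs$sent1, pairs$sent2,
                                 pairs$p1, pairs$p2)
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) next
    pairs <- pairs[order(pairs$p1, pairs$p2), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      ctx <- build_context(col, pairs$p1[k], pairs$p2[k], special_chars)
      if (is.null(ctx)) next
      inst <- list(doc_id = id, gene_a = pairs$gene_a[k],
                   gene_b = pairs$gene_b[k],
                   p1 = pairs$p1[k], p2 = pairs$p2[k],
                   context = ctx$context, dist1 = ctx$dist1,
                   dist2 = ctx$dist2)
      if (!is.null(gold)) inst$label <- pairs$label[k]
      out[[length(out) + 1L]] <- inst
    }
  }
  out
}
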