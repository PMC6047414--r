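#' Sentence segmentation
#'
#' Deterministic rule-based splitter: a sentence boundary is a `.`, `?` or
#' `!` followed by whitespace and an uppercase letter or digit.  Spans are
#' 0-based, half-open character offsets over the document text
#' (`title + " " + abstract`).
#'
#' @param text Character scalar.
#' @return Data frame with columns `index` (0-based sentence index),
#'   `start`, `end` (0-based, half-open offsets).
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  nch <- nchar(text)
  if (nch == 0L)
    return(data.frame(index = integer(), start = integer(), end = integer()))
  # boundary: terminator, whitespace, then an uppercase/digit start
  m <- gregexpr("[.?!](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  ends0 <- if (m[1] == -1L) integer() else as.integer(m)  # 1-based pos of terminator
  starts <- 1L
  for (e in ends0) {
    rest <- substr(text, e + 1L, nch)
    ws <- attr(regexpr("^\\s+", rest), "match.length")
    starts <- c(starts, e + ws + 1L)
  }
  ends <- c(ends0, nch)
  data.frame(index = seq_along(starts) - 1L,
             start = starts - 1L, end = ends)
}

# one token: alphanumeric run (allowing internal .,'-% joins as in "3.5" or
# "p53-binding"), else a single non-space character
.token_regex <- "[A-Za-z0-9]+(?:['.,%-][A-Za-z0-9]+)*%?|\\S"

#' Tokenize a document
#'
#' Splits on whitespace and splits punctuation off word edges; internal
#' punctuation inside alphanumeric runs (e.g. `3.5`, `p53-binding`) is kept.
#' Each token is assigned to the sentence containing its first character.
#'
#' @param title,abstract The document's two text fields.
#' @return Data frame with columns `token`, `start` (0-based offset into
#'   `title + " " + abstract`), `sent` (0-based sentence index).
#' @export
tokenize_document <- function(title, abstract) {
  text <- doc_text(title, abstract)
  sents <- segment_sentences(text)
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(), start = integer(),
                      sent = integer(), stringsAsFactors = FALSE))
  starts <- as.integer(m) - 1L
  toks <- regmatches(text, list(m))[[1]]
  sent <- findInterval(starts, sents$start) - 1L
  sent[sent < 0L] <- 0L
  data.frame(token = toks, start = starts, sent = sent,
             stringsAsFactors = FALSE)
}

#' Collapse protein mentions to single tokens
#'
#' Every token overlapping a mention span is absorbed into one pseudo-token
#' carrying the mention's gene ID, positioned at the mention start (a
#' multi-token mention becomes one word in the stream).  A mention whose
#' span overlaps an earlier mention is skipped with a warning.
#'
#' @param tokens Token data frame from [tokenize_document()].
#' @param mentions Mentions of one document (`start`, `length`, `surface`,
#'   `gene_id`).
#' @return Data frame `token`, `start`, `sent`, `gene_id` (`NA` for plain
#'   words); row order is document order, row number is the token position.
#' @export
collapse_mentions <- function(tokens, mentions) {
  tokens$gene_id <- NA_character_
  if (!nrow(mentions)) return(tokens)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  tok_end <- tokens$start + nchar(tokens$token)  # half-open
  drop <- rep(FALSE, nrow(tokens))
  claimed <- rep(FALSE, nrow(tokens))
  out <- tokens
  for (r in seq_len(nrow(mentions))) {
    ms <- mentions$start[r]; me <- ms + mentions$length[r]
    cover <- which(tokens$start < me & tok_end > ms)
    if (!length(cover)) {
      warning("mention '", mentions$surface[r], "' matched no token; skipped")
      next
    }
    if (any(claimed[cover])) {
      warning("overlapping mention '", mentions$surface[r], "' skipped")
      next
    }
    claimed[cover] <- TRUE
    head_i <- cover[1]
    out$token[head_i] <- mentions$surface[r]
    out$gene_id[head_i] <- mentions$gene_id[r]
    out$sent[head_i] <- tokens$sent[head_i]
    if (length(cover) > 1L) drop[cover[-1]] <- TRUE
  }
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
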