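# Build a one-document corpus from sentences given as token lists; a gene
# mention is written list(surface, gene_id), a plain word as a string.
doc_from_sentences <- function(doc_id, sentences) {
  title <- "Fixture title."
  pos <- nchar(title) + 1L
  parts <- character(); ments <- list()
  for (sent in sentences) {
    for (ti in seq_along(sent)) {
      tok <- sent[[ti]]
      if (is.list(tok)) {
        ments[[length(ments) + 1L]] <- data.frame(
          doc_id = doc_id, start = pos, length = nchar(tok[[1]]),
          surface = tok[[1]], type = "Gene", gene_id = tok[[2]],
          stringsAsFactors = FALSE)
        tok <- tok[[1]]
      }
      parts <- c(parts, tok)
      pos <- pos + nchar(tok) + (if (ti < length(sent)) 1L else 0L)
    }
    parts[length(parts)] <- paste0(parts[length(parts)], ".")
    pos <- pos + 2L
  }
  list(documents = data.frame(doc_id = doc_id, title = title,
                              abstract = paste(parts, collapse = " "),
                              stringsAsFactors = FALSE),
       mentions = do.call(rbind, ments))
}
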