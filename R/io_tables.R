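#' Canonicalize an unordered gene-ID pair
#'
#' Relations are undirected at evaluation time, so pairs are stored with the
#' two gene IDs sorted lexicographically.
#'
#' @param a,b Character vectors of gene IDs (recycled to common length).
#' @return A two-column data frame `gene_a`, `gene_b` with `gene_a <= gene_b`.
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- b < a
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
}

#' Read document-level gold interaction pairs
#'
#' Three-column TSV: `doc_id`, `gene_id`, `gene_id`.  Pairs are unordered:
#' rows (d, A, B) and (d, B, A) collapse to one record, as do exact
#' duplicates.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `doc_id`, `gene_a`, `gene_b`
#'   (canonicalized, deduplicated).
#' @export
read_pairs_tsv <- function(path) {
  stopifnot(file.exists(path))
  tab <- read_tsv_cols(path, 3L, c("doc_id", "gene_a", "gene_b"))
  if (!nrow(tab)) return(tab)
  cp <- canonical_pair(tab$gene_a, tab$gene_b)
  tab$gene_a <- cp$gene_a; tab$gene_b <- cp$gene_b
  if (any(tab$gene_a == tab$gene_b))
    stop("gold pair with identical gene IDs in '", path, "'")
  unique(tab)
}

#' @rdname read_pairs_tsv
#' @param pairs Data frame with columns `doc_id`, `gene_a`, `gene_b`.
#' @export
write_pairs_tsv <- function(pairs, path) {
  write_tsv_plain(pairs[, c("doc_id", "gene_a", "gene_b")], path)
}

#' Read knowledge-base triples
#'
#' Three-column TSV: head entity ID, relation label, tail entity ID.  Exact
#' duplicate rows are removed (triple selection is strict, without
#' redundancy); load order is otherwise preserved.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `head_id`, `relation`, `tail_id`.
#' @export
read_triples_tsv <- function(path) {
  stopifnot(file.exists(path))
  tab <- read_tsv_cols(path, 3L, c("head_id", "relation", "tail_id"))
  if (!nrow(tab)) return(tab)
  if (any(!nzchar(tab$head_id) | !nzchar(tab$relation) | !nzchar(tab$tail_id)))
    stop("empty field in triple file '", path, "'")
  unique(tab)
}

#' @rdname read_triples_tsv
#' @param triples Data frame with columns `head_id`, `relation`, `tail_id`.
#' @export
write_triples_tsv <- function(triples, path) {
  write_tsv_plain(triples[, c("head_id", "relation", "tail_id")], path)
}

#' Read word vectors in word2vec text format
#'
#' Each line is a word followed by `dim` whitespace-separated floats.  An
#' optional header line of two integers (vocabulary size, dimension) is
#' tolerated and skipped.
#'
#' @param path Path to the vector file.
#' @param dim Expected embedding dimension; a line with a different number
#'   of components is a format error.
#' @return A numeric matrix with one row per word; row names are the words.
#' @export
read_word_vectors <- function(path, dim) {
  stopifnot(file.exists(path), dim >= 1L)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(matrix(numeric(), 0L, dim, dimnames = list(character(), NULL)))
  first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.integer(first))))
    lines <- lines[-1L]
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf != dim + 1L))
    stop(sprintf("word-vector line with %d values where %d expected",
                 nf[which(nf != dim + 1L)[1]] - 1L, dim))
  words <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim))
  mat <- if (dim == 1L) matrix(vals, ncol = 1L) else t(vals)
  rownames(mat) <- words
  mat
}

#' @rdname read_word_vectors
#' @param vectors Numeric matrix with words as row names.
#' @param header Write the word2vec `<count> <dim>` header line.
#' @export
write_word_vectors <- function(vectors, path, header = TRUE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (header)
    writeLines(paste(nrow(vectors), ncol(vectors)), con, useBytes = TRUE)
  vals <- apply(vectors, 1L, function(v)
    paste(formatC(v, format = "g", digits = 8), collapse = " "))
  writeLines(paste(rownames(vectors), vals), con, useBytes = TRUE)
  invisible(path)
}

#' Read/write prediction sets
#'
#' Predictions are (document, unordered gene-ID pair) records with a score
#' and a provenance tag: `model` (classifier), `rule` (sentence-support
#' rule) or `both` (after merging).
#'
#' @param path Path to the 5-column TSV
#'   (`doc_id`, `gene_a`, `gene_b`, `score`, `source`).
#' @return Data frame with those columns, pairs canonicalized.
#' @export
read_predictions_tsv <- function(path) {
  stopifnot(file.exists(path))
  tab <- read_tsv_cols(path, 5L,
                       c("doc_id", "gene_a", "gene_b", "score", "source"))
  tab$score <- as.numeric(tab$score)
  if (!nrow(tab)) return(tab)
  cp <- canonical_pair(tab$gene_a, tab$gene_b)
  tab$gene_a <- cp$gene_a; tab$gene_b <- cp$gene_b
  tab
}

#' @rdname read_predictions_tsv
#' @param predictions Data frame with columns `doc_id`, `gene_a`, `gene_b`,
#'   `score`, `source`.
#' @export
write_predictions_tsv <- function(predictions, path) {
  out <- predictions[, c("doc_id", "gene_a", "gene_b", "score", "source")]
  out$score <- formatC(out$score, format = "g", digits = 8)
  write_tsv_plain(out, path)
}

#' Write an attention-weight dump
#'
#' One row per (instance, layer, network, context token):
#' `doc_id`, `instance`, `layer`, `network`, `token`, `weight`.
#'
#' @param attention Data frame with the columns above (as produced by
#'   [predict_instances()] with `record_attention = TRUE`).
#' @param path Output TSV path.
#' @export
write_attention_tsv <- function(attention, path) {
  out <- attention[, c("doc_id", "instance", "layer", "network",
                       "token", "weight")]
  out$weight <- formatC(out$weight, format = "g", digits = 8)
  write_tsv_plain(out, path)
}

#' Read/write candidate instances as JSON lines
#'
#' One JSON object per line with fields `doc_id`, `gene_a`, `gene_b`, `p1`,
#' `p2`, `context` (array of token strings), `dist1`, `dist2` and, for
#' training data, `label`.
#'
#' @param instances A candidate-instance list as built by
#'   [build_candidates()].
#' @param path File path.
#' @export
write_instances <- function(instances, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (inst in instances) {
    rec <- inst[c("doc_id", "gene_a", "gene_b", "p1", "p2",
                  "context", "dist1", "dist2")]
    if (!is.null(inst$label)) rec$label <- inst$label
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_instances
#' @export
read_instances <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    rec$context <- as.character(rec$context)
    rec$dist1 <- as.integer(rec$dist1)
    rec$dist2 <- as.integer(rec$dist2)
    rec$p1 <- as.integer(rec$p1); rec$p2 <- as.integer(rec$p2)
    if (!is.null(rec$label)) rec$label <- as.integer(rec$label)
    rec
  })
}

# -- internal TSV helpers ----------------------------------------------------

read_tsv_cols <- function(path, ncol, names) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(rep(list(character()), ncol), names),
                         stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < ncol)
  if (length(short))
    stop(sprintf("row %d of '%s' has fewer than %d columns",
                 short[1], path, ncol))
  cols <- lapply(seq_len(ncol), function(j) vapply(parts, `[[`, "", j))
  as.data.frame(stats::setNames(cols, names), stringsAsFactors = FALSE)
}

write_tsv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df))
    writeLines(do.call(paste, c(as.list(df), sep = "\t")), con,
               useBytes = TRUE)
  else writeLines(character(), con, useBytes = TRUE)
  invisible(path)
}
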