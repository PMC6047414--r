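#' Read a PubTator-style annotated abstract file
#'
#' Parses the plain-text interchange format used for annotated abstracts:
#' for each document a `id|t|title` line, a `id|a|abstract` line, then zero
#' or more tab-separated annotation lines
#' `id<TAB>start<TAB>end<TAB>surface<TAB>type<TAB>gene_id`; documents are
#' separated by blank lines.  Offsets are 0-based, half-open, computed over
#' the string `title + " " + abstract`.
#'
#' @param path Path to a PubTator-style text file.
#' @param validate If `TRUE` (default), every annotation's surface string is
#'   checked against the text slice at its offsets and a mismatch is an error.
#' @return A list with two data frames: `documents` (columns `doc_id`,
#'   `title`, `abstract`) and `mentions` (columns `doc_id`, `start`,
#'   `length`, `surface`, `type`, `gene_id`).
#' @export
read_pubtator <- function(path, validate = TRUE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")

  docs <- list()
  ments <- list()
  cur <- NULL  # list(doc_id, title, abstract)

  flush_doc <- function() {
    if (!is.null(cur)) docs[[length(docs) + 1L]] <<- cur
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) { flush_doc(); next }
    m <- regmatches(ln, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", ln))[[1]]
    if (length(m) == 4L) {
      id <- m[2]
      if (is.null(cur)) cur <- list(doc_id = id, title = "", abstract = "")
      if (cur$doc_id != id) { flush_doc(); cur <- list(doc_id = id, title = "", abstract = "") }
      if (m[3] == "t") cur$title <- m[4] else cur$abstract <- m[4]
      next
    }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) >= 6L) {
      start <- suppressWarnings(as.integer(fields[2]))
      end <- suppressWarnings(as.integer(fields[3]))
      if (is.na(start) || is.na(end) || end <= start)
        stop(sprintf("malformed annotation line %d in '%s': bad offsets", i, path))
      ments[[length(ments) + 1L]] <- data.frame(
        doc_id = fields[1], start = start, length = end - start,
        surface = fields[4], type = fields[5], gene_id = fields[6],
        stringsAsFactors = FALSE)
      next
    }
    stop(sprintf("malformed line %d in '%s': %s", i, path,
                 substr(ln, 1L, 60L)))
  }
  flush_doc()

  documents <- if (length(docs)) {
    data.frame(doc_id = vapply(docs, `[[`, "", "doc_id"),
               title = vapply(docs, `[[`, "", "title"),
               abstract = vapply(docs, `[[`, "", "abstract"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(doc_id = character(), title = character(),
               abstract = character(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(documents$doc_id))
    stop("duplicate doc_id in '", path, "'")
  mentions <- if (length(ments)) do.call(rbind, ments) else
    data.frame(doc_id = character(), start = integer(), length = integer(),
               surface = character(), type = character(),
               gene_id = character(), stringsAsFactors = FALSE)

  if (validate && nrow(mentions)) validate_mentions(documents, mentions)
  list(documents = documents, mentions = mentions)
}

#' Document text under the offset convention
#'
#' @param title,abstract Character scalars (or vectors of equal length).
#' @return `title + " " + abstract`, the string over which mention offsets
#'   are interpreted.
#' @export
doc_text <- function(title, abstract) paste(title, abstract)

validate_mentions <- function(documents, mentions) {
  text <- stats::setNames(doc_text(documents$title, documents$abstract),
                          documents$doc_id)
  bad <- character()
  for (r in seq_len(nrow(mentions))) {
    tx <- text[[mentions$doc_id[r]]]
    if (is.null(tx)) { bad <- c(bad, mentions$doc_id[r]); next }
    sl <- substr(tx, mentions$start[r] + 1L,
                 mentions$start[r] + mentions$length[r])
    if (!identical(sl, mentions$surface[r])) bad <- c(bad, mentions$doc_id[r])
  }
  if (length(bad))
    stop("mention offset/surface mismatch in document(s): ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Write documents and mentions as PubTator-style text
#'
#' Inverse of [read_pubtator()]; writing then re-reading is lossless.
#'
#' @param documents,mentions Data frames as returned by [read_pubtator()].
#' @param path Output file path.
#' @export
write_pubtator <- function(documents, mentions, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in seq_len(nrow(documents))) {
    id <- documents$doc_id[r]
    blk <- c(paste0(id, "|t|", documents$title[r]),
             paste0(id, "|a|", documents$abstract[r]))
    mm <- mentions[mentions$doc_id == id, , drop = FALSE]
    if (nrow(mm)) {
      mm <- mm[order(mm$start), , drop = FALSE]
      blk <- c(blk, paste(mm$doc_id, mm$start, mm$start + mm$length,
                          mm$surface, mm$type, mm$gene_id, sep = "\t"))
    }
    writeLines(c(blk, ""), con, useBytes = TRUE)
  }
  invisible(path)
}
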