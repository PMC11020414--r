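#' Annotated article corpora as sparse binary matrices
#'
#' A `medsom_corpus` holds N article records, each annotated with a set of
#' vocabulary terms, as an N x D sparse binary document-term matrix (class
#' `dgCMatrix`).  Row i has a 1 in exactly the columns of record i's terms,
#' so the row sum equals the record's annotation count D_a.
#'
#' @param records list of records, each a list with elements `article_id`
#'   (scalar character) and `term_ids` (character vector); or a data.frame
#'   with columns `article_id` and `term_ids` (list column).
#' @param vocab a `medsom_vocabulary` giving the column space.
#' @param strict if `TRUE`, a term absent from `vocab` is an error naming the
#'   record and term; if `FALSE` (lenient), unknown terms are dropped
#'   silently and records left with no known terms are dropped with a
#'   warning.
#' @return a `medsom_corpus`: list with `article_ids` (character N),
#'   `matrix` (N x D `dgCMatrix`, binary), `N`, `vocab_digest`, and
#'   `dropped_ids` (ids of records dropped for having no retained terms).
#' @export
vectorize_corpus <- function(records, vocab, strict = FALSE) {
  records <- as_record_list(records)
  n <- length(records)
  ids <- vapply(records, function(r) as.character(r$article_id), "")
  term_sets <- lapply(records, function(r) unique(as.character(r$term_ids)))

  cols <- lapply(seq_len(n), function(i) {
    idx <- term_index(vocab, term_sets[[i]])
    if (anyNA(idx)) {
      if (strict) {
        bad <- term_sets[[i]][is.na(idx)]
        stopf("record %s has term(s) not in vocabulary: %s",
              ids[i], paste(bad, collapse = ", "))
      }
      idx <- idx[!is.na(idx)]
    }
    sort(idx)
  })
  keep <- lengths(cols) > 0
  dropped <- ids[!keep]
  if (length(dropped) > 0) {
    warnf("dropping %d record(s) with no retained annotations: %s",
          length(dropped), paste(utils::head(dropped, 10), collapse = ", "))
  }
  cols <- cols[keep]
  ids <- ids[keep]
  n <- length(ids)
  mat <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lengths(cols)),
    j = unlist(cols, use.names = FALSE) %||% integer(),
    x = 1,
    dims = c(n, vocab$D),
    dimnames = list(ids, vocab$terms$term_id)
  )
  structure(
    list(article_ids = ids, matrix = mat, N = n,
         vocab_digest = vocab_digest(vocab), dropped_ids = dropped),
    class = "medsom_corpus"
  )
}

as_record_list <- function(records) {
  if (inherits(records, "medsom_corpus")) return(corpus_records(records))
  if (is.data.frame(records)) {
    stopifnot(all(c("article_id", "term_ids") %in% names(records)))
    return(lapply(seq_len(nrow(records)), function(i) {
      list(article_id = records$article_id[i], term_ids = records$term_ids[[i]])
    }))
  }
  records
}

#' Recover the record list of a corpus
#'
#' @param corpus a `medsom_corpus`.
#' @param vocab optional vocabulary; defaults to the matrix's column names.
#' @return list of records (`article_id`, `term_ids`), in corpus order.
#' @export
corpus_records <- function(corpus, vocab = NULL) {
  term_ids <- if (is.null(vocab)) colnames(corpus$matrix) else vocab$terms$term_id
  m <- methods::as(corpus$matrix, "TsparseMatrix")
  js <- split(m@j + 1L, factor(m@i + 1L, levels = seq_len(corpus$N)))
  lapply(seq_len(corpus$N), function(i) {
    list(article_id = corpus$article_ids[i], term_ids = term_ids[sort(js[[i]])])
  })
}

#' @export
print.medsom_corpus <- function(x, ...) {
  cat(sprintf("<medsom_corpus> N = %d articles x D = %d terms; %d nonzeros\n",
              x$N, ncol(x$matrix), length(x$matrix@x)))
  invisible(x)
}

#' Per-record annotation counts
#'
#' @param corpus a `medsom_corpus`.
#' @return integer vector of row sums (D_a per article).
#' @export
annotation_counts <- function(corpus) {
  as.integer(Matrix::rowSums(corpus$matrix))
}

#' Remove rarely used terms and re-vectorize
#'
#' Drops vocabulary terms annotating fewer than `min_count` articles of
#' `corpus` (the paper-scale default used for Medline is 100), then rebuilds
#' the corpus against the reduced vocabulary.  Records left with no
#' annotations are dropped and their ids reported.  Idempotent for a fixed
#' `min_count`.
#'
#' @param vocab a `medsom_vocabulary`.
#' @param corpus a `medsom_corpus` vectorized against `vocab`.
#' @param min_count nonnegative integer; terms kept iff their annotation
#'   count is `>= min_count`.
#' @return list with `vocab` (reduced, `annotation_count` refreshed),
#'   `corpus` (re-vectorized), and `summary` (list: `removed_terms`,
#'   `dropped_article_ids`).
#' @export
filter_rare_terms <- function(vocab, corpus, min_count) {
  stopifnot(min_count >= 0)
  counts <- as.integer(Matrix::colSums(corpus$matrix))
  keep <- counts >= min_count
  terms <- vocab$terms[keep, , drop = FALSE]
  terms$annotation_count <- counts[keep]
  reduced <- new_vocabulary(terms, domain_prefixes = vocab$domain_prefixes)
  sub <- corpus$matrix[, keep, drop = FALSE]
  row_keep <- Matrix::rowSums(sub) > 0
  dropped <- corpus$article_ids[!row_keep]
  sub <- sub[row_keep, , drop = FALSE]
  out <- structure(
    list(article_ids = corpus$article_ids[row_keep], matrix = sub,
         N = sum(row_keep), vocab_digest = vocab_digest(reduced),
         dropped_ids = dropped),
    class = "medsom_corpus"
  )
  list(
    vocab = reduced,
    corpus = out,
    summary = list(
      removed_terms = vocab$terms$term_id[!keep],
      dropped_article_ids = dropped
    )
  )
}

#' Read/write annotated corpora
#'
#' Two interchangeable on-disk formats:
#' * JSONL — one object per line, `{"article_id": "...", "mesh": ["...", ...]}`;
#' * TSV — header plus two columns `article_id` and `mesh`
#'   (semicolon-separated term ids).
#'
#' A write-then-read round trip preserves record order and every nonzero
#' coordinate; duplicate terms within one record are deduplicated with a
#' warning at read time.
#'
#' @param corpus a `medsom_corpus` (or record list for `write_corpus`).
#' @param path file path; format chosen by extension (`.jsonl` vs `.tsv`)
#'   unless `format` is given.
#' @param vocab vocabulary to vectorize against when reading.
#' @param format `"jsonl"` or `"tsv"`.
#' @param strict passed to [vectorize_corpus()].
#' @return `read_corpus` returns a `medsom_corpus`; `write_corpus` returns
#'   `path` invisibly.
#' @export
write_corpus <- function(corpus, path, format = guess_corpus_format(path)) {
  records <- as_record_list(corpus)
  ids <- vapply(records, function(r) as.character(r$article_id), "")
  terms <- lapply(records, function(r) as.character(r$term_ids))
  if (format == "jsonl") {
    lines <- vapply(seq_along(ids), function(i) {
      jsonlite::toJSON(list(article_id = ids[i], mesh = terms[[i]]),
                       auto_unbox = TRUE)
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    body <- if (length(ids) == 0) character() else
      paste0(ids, "\t", vapply(terms, paste, "", collapse = ";"))
    writeLines(c("article_id\tmesh", body), path, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, vocab, format = guess_corpus_format(path),
                        strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (format == "jsonl") {
    records <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$article_id)) {
        stopf("malformed JSONL at %s line %d", path, i)
      }
      list(article_id = rec$article_id, term_ids = as.character(rec$mesh))
    })
  } else {
    if (length(lines) == 0 || lines[1] != "article_id\tmesh") {
      stopf("malformed TSV corpus at %s line 1: expected header 'article_id\\tmesh'", path)
    }
    body <- lines[-1]
    records <- lapply(seq_along(body), function(i) {
      parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !nzchar(parts[1])) {
        stopf("malformed TSV corpus at %s line %d", path, i + 1)
      }
      list(article_id = parts[1],
           term_ids = strsplit(parts[2], ";", fixed = TRUE)[[1]])
    })
  }
  ndup <- sum(vapply(records, function(r) anyDuplicated(r$term_ids) > 0, logical(1)))
  if (ndup > 0) {
    warnf("%d record(s) in %s contained duplicate terms; deduplicated", ndup, path)
  }
  vectorize_corpus(records, vocab, strict = strict)
}

guess_corpus_format <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "tsv"
}

#' Subset a corpus by article id
#'
#' @param corpus a `medsom_corpus`.
#' @param article_ids ids to keep (order taken from `article_ids`).
#' @return a `medsom_corpus` restricted to the matching records.
#' @export
corpus_subset <- function(corpus, article_ids) {
  idx <- match(article_ids, corpus$article_ids)
  if (anyNA(idx)) {
    stopf("unknown article id(s): %s",
          paste(utils::head(article_ids[is.na(idx)], 5), collapse = ", "))
  }
  structure(
    list(article_ids = corpus$article_ids[idx],
         matrix = corpus$matrix[idx, , drop = FALSE],
         N = length(idx), vocab_digest = corpus$vocab_digest,
         dropped_ids = character()),
    class = "medsom_corpus"
  )
}
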