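#' Parse a free-text reference string
#'
#' Best-effort heuristic split of a citation such as
#' `"Smith J. A study of X. J Clin Y. 1990"` into the three fields used for
#' bibliographic matching: the first author's surname, the title, and the
#' journal.  Segments are taken between sentence-ending periods; the leading
#' segment is the author block (first surname = first token of the first
#' comma-separated author), the next is the title, the next the journal.
#' All fields are lower-cased, punctuation-stripped and whitespace-collapsed.
#' Parse failures leave fields empty and set `flagged`.
#'
#' @param raw_text nonempty citation string.
#' @param edition_id optional label carried through to reports.
#' @return list with `edition_id`, `raw_text`, `first_author_surname`,
#'   `title`, `journal`, `flagged`.
#' @export
parse_reference <- function(raw_text, edition_id = NA_character_) {
  stopifnot(is.character(raw_text), length(raw_text) == 1, nzchar(raw_text))
  segs <- squish(strsplit(raw_text, "\\.\\s+")[[1]])
  segs <- segs[nzchar(segs)]
  out <- list(edition_id = edition_id, raw_text = raw_text,
              first_author_surname = "", title = "", journal = "",
              flagged = TRUE)
  if (length(segs) >= 3) {
    first_author <- squish(strsplit(segs[1], ",", fixed = TRUE)[[1]][1])
    surname <- strsplit(normalize_field(first_author), " ", fixed = TRUE)[[1]][1]
    title <- normalize_field(segs[2])
    # drop a trailing bare-year segment so the journal is the last text block
    jseg <- segs[3]
    journal <- normalize_field(jseg)
    if (!is.na(surname) && nzchar(surname) && nzchar(title) && nzchar(journal)) {
      out$first_author_surname <- surname
      out$title <- title
      out$journal <- journal
      out$flagged <- FALSE
    }
  }
  out
}

#' Read references / bibliographic records from disk
#'
#' References: TSV with columns `edition_id`, `raw_text`.  Records: TSV with
#' columns `article_id`, `first_author`, `title`, `journal`, `mesh`
#' (semicolon-separated term ids), or JSONL with the same keys (`mesh` an
#' array).
#'
#' @param path file path.
#' @return `read_references`: list of parsed references.
#'   `read_bib_records`: list of records (`article_id`,
#'   `first_author_surname`, `title`, `journal`, `term_ids`), fields
#'   normalized for matching, original `title_raw`/`journal_raw` retained.
#' @export
read_references <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  stopifnot(all(c("edition_id", "raw_text") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    parse_reference(df$raw_text[i], edition_id = df$edition_id[i])
  })
}

#' @rdname read_references
#' @export
read_bib_records <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  } else {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
    stopifnot(all(c("article_id", "first_author", "title", "journal", "mesh") %in% names(df)))
    recs <- lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, ])
      r$mesh <- strsplit(r$mesh, ";", fixed = TRUE)[[1]]
      r
    })
  }
  recs <- lapply(recs, function(r) {
    list(
      article_id = as.character(r$article_id),
      first_author_surname = strsplit(normalize_field(r$first_author), " ")[[1]][1],
      title = normalize_field(r$title),
      journal = normalize_field(r$journal),
      title_raw = r$title, journal_raw = r$journal,
      first_author_raw = r$first_author,
      term_ids = as.character(r$mesh)
    )
  })
  ids <- vapply(recs, `[[`, "", "article_id")
  if (anyDuplicated(ids)) {
    stopf("duplicate article_id in bibliographic records: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs
}

# normalized Levenshtein similarity in [0, 1]
string_similarity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  1 - as.numeric(utils::adist(a, b)) / max(nchar(a), nchar(b))
}

#' Match one parsed reference against the record set
#'
#' Candidates are the records sharing the normalized first-author surname.
#' A candidate passes when its normalized-title similarity is at least
#' `title_threshold` and its normalized-journal similarity at least
#' `journal_threshold` (normalized Levenshtein ratio).  Exactly one passing
#' candidate is accepted; none or several are rejected with a reason
#' (`"surname"`, `"title"`, `"journal"`, `"ambiguous"`, `"parse"`).
#' Deterministic and independent of record order.
#'
#' @param ref a parsed reference (see [parse_reference()]).
#' @param records list of bibliographic records (see [read_bib_records()]).
#' @param title_threshold,journal_threshold acceptance thresholds in [0, 1]
#'   (defaults 0.90 / 0.80; set both to 1 for exact matching).
#' @return list with `matched` (logical), `article_id` (or NA) and `reason`
#'   (NA when matched).
#' @export
match_reference <- function(ref, records,
                            title_threshold = 0.90, journal_threshold = 0.80) {
  if (isTRUE(ref$flagged)) {
    return(list(matched = FALSE, article_id = NA_character_, reason = "parse"))
  }
  surnames <- vapply(records, `[[`, "", "first_author_surname")
  cand <- records[!is.na(surnames) & surnames == ref$first_author_surname]
  if (length(cand) == 0) {
    return(list(matched = FALSE, article_id = NA_character_, reason = "surname"))
  }
  tsim <- vapply(cand, function(r) string_similarity(ref$title, r$title), numeric(1))
  jsim <- vapply(cand, function(r) string_similarity(ref$journal, r$journal), numeric(1))
  pass <- tsim >= title_threshold & jsim >= journal_threshold
  if (sum(pass) == 1) {
    return(list(matched = TRUE, article_id = cand[[which(pass)]]$article_id,
                reason = NA_character_))
  }
  if (sum(pass) > 1) {
    return(list(matched = FALSE, article_id = NA_character_, reason = "ambiguous"))
  }
  reason <- if (!any(tsim >= title_threshold)) "title" else "journal"
  list(matched = FALSE, article_id = NA_character_, reason = reason)
}

#' Match every reference and keep per-edition bookkeeping
#'
#' @param refs list of parsed references (with `edition_id` set).
#' @inheritParams match_reference
#' @return a `match_report`: list with `details` (data.frame: edition_id,
#'   raw_text, matched, article_id, reason) and `by_edition` (data.frame:
#'   edition_id, n_total, n_matched, n_unmatched; the two counts always sum
#'   to the total).
#' @export
match_references <- function(refs, records,
                             title_threshold = 0.90, journal_threshold = 0.80) {
  rows <- lapply(refs, function(ref) {
    m <- match_reference(ref, records, title_threshold, journal_threshold)
    data.frame(edition_id = as.character(ref$edition_id),
               raw_text = ref$raw_text,
               matched = m$matched, article_id = m$article_id,
               reason = m$reason, stringsAsFactors = FALSE)
  })
  details <- do.call(rbind, rows) %||%
    data.frame(edition_id = character(), raw_text = character(),
               matched = logical(), article_id = character(),
               reason = character())
  eds <- unique(details$edition_id)
  by_edition <- do.call(rbind, lapply(eds, function(e) {
    d <- details[details$edition_id == e, ]
    data.frame(edition_id = e, n_total = nrow(d),
               n_matched = sum(d$matched), n_unmatched = sum(!d$matched),
               stringsAsFactors = FALSE)
  }))
  structure(list(details = details, by_edition = by_edition),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("<match_report>\n")
  print(x$by_edition, row.names = FALSE)
  invisible(x)
}

#' Build per-edition corpora from matched references
#'
#' Each edition yields the corpus of its matched records, deduplicated by
#' article id within the edition (an article cited twice contributes one
#' record), vectorized against `vocab` and ready for projection.
#'
#' @param report a `match_report` from [match_references()].
#' @param records the bibliographic record list (supplies term ids).
#' @param vocab a `medsom_vocabulary`.
#' @param strict passed to [vectorize_corpus()].
#' @return named list of `medsom_corpus`, one per edition id (empty editions
#'   yield a zero-record corpus).
#' @export
build_edition_corpora <- function(report, records, vocab, strict = FALSE) {
  rec_by_id <- stats::setNames(records, vapply(records, `[[`, "", "article_id"))
  eds <- unique(report$details$edition_id)
  out <- lapply(eds, function(e) {
    d <- report$details
    ids <- unique(d$article_id[d$edition_id == e & d$matched])
    recs <- lapply(ids, function(id) {
      list(article_id = id, term_ids = rec_by_id[[id]]$term_ids)
    })
    vectorize_corpus(recs, vocab, strict = strict)
  })
  stats::setNames(out, eds)
}
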