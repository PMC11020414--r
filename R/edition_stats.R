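#' Citations per chapter
#'
#' Total citation count divided by chapter count, rounded half-up to one
#' decimal (the convention of printed textbook summary tables).
#'
#' @param citations_total nonnegative citation count(s).
#' @param chapters positive chapter count(s).
#' @return numeric, one decimal.
#' @export
citations_per_chapter <- function(citations_total, chapters) {
  if (any(chapters <= 0)) stopf("chapters must be > 0")
  round_half_up(citations_total / chapters, 1)
}

#' Citation persistence between consecutive editions
#'
#' Percentage of the *current* edition's indexed citations that were already
#' present in the previous edition: `100 * |curr & prev| / |curr|`, rounded
#' half-up to a whole percent.  Undefined (NA) for an empty current set —
#' and by convention for a first edition, which has no predecessor.
#'
#' @param prev_ids,curr_ids character vectors of article ids (treated as
#'   sets).
#' @return whole-percent value in [0, 100], or NA.
#' @export
persistence_pct <- function(prev_ids, curr_ids) {
  curr <- unique(as.character(curr_ids))
  if (length(curr) == 0) return(NA_real_)
  prev <- unique(as.character(prev_ids))
  round_half_up(100 * length(intersect(curr, prev)) / length(curr), 0)
}

#' Read edition metadata from TSV
#'
#' Expects columns `edition`, `year`, `pages`, `chapters`, `new_chapters`,
#' `removed_chapters`, `citations_total`, `citations_indexed`, and
#' optionally `persistence_pct` (observed values; `NA` where undefined,
#' e.g. the first edition).  The package ships such a fixture for the ten
#' editions of a standard psychiatric textbook under
#' `system.file("extdata", "ksctp_editions.tsv", package = "medsom")`.
#'
#' @param path TSV path.
#' @return data.frame with numeric columns (NA for absent values).
#' @export
read_edition_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  need <- c("edition", "year", "chapters", "citations_total")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("edition metadata lacks column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(stats::na.omit(df$chapters) <= 0)) stopf("chapters must be > 0")
  df
}

#' Edition-level organizational statistics
#'
#' Recomputes, for each edition, citations per chapter (one decimal,
#' half-up) and carries the per-edition persistence; then aggregates the
#' means of new chapters, removed/merged chapters, and persistence over the
#' editions where each is defined.  The first edition is excluded from all
#' three means: it has no predecessor, so persistence is undefined and its
#' "new" chapters are trivially the whole book.
#' Means are rounded half-up to one decimal (chapter counts)
#' and to a whole percent (persistence).  A pure function of its inputs.
#'
#' @param meta edition metadata data.frame (see [read_edition_metadata()]).
#' @param persistence optional numeric vector overriding
#'   `meta$persistence_pct` (e.g. recomputed from matched citation sets via
#'   [persistence_pct()]).
#' @return list with `per_edition` (data.frame: edition, year,
#'   citations_per_chapter, persistence_pct) and `aggregates` (list:
#'   mean_new_chapters, mean_removed_chapters, mean_persistence_pct).
#' @export
edition_stats <- function(meta, persistence = NULL) {
  if (nrow(meta) < 2) stopf("edition statistics need >= 2 editions")
  pers <- persistence %||% meta$persistence_pct %||% rep(NA_real_, nrow(meta))
  per_edition <- data.frame(
    edition = meta$edition,
    year = meta$year,
    citations_per_chapter = citations_per_chapter(meta$citations_total, meta$chapters),
    persistence_pct = pers,
    stringsAsFactors = FALSE
  )
  mean_defined <- function(x, digits) {
    x <- x[-1]            # first edition has no predecessor
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    round_half_up(mean(x), digits)
  }
  list(
    per_edition = per_edition,
    aggregates = list(
      mean_new_chapters = mean_defined(meta$new_chapters, 1),
      mean_removed_chapters = mean_defined(meta$removed_chapters, 1),
      mean_persistence_pct = mean_defined(pers, 0)
    )
  )
}

#' Recompute persistence from per-edition citation id sets
#'
#' @param id_sets ordered list (first edition first) of character vectors of
#'   matched article ids per edition.
#' @return numeric vector aligned with `id_sets`; NA for the first edition.
#' @export
persistence_series <- function(id_sets) {
  n <- length(id_sets)
  out <- rep(NA_real_, n)
  if (n >= 2) {
    for (e in 2:n) out[e] <- persistence_pct(id_sets[[e - 1]], id_sets[[e]])
  }
  out
}
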