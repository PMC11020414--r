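#' Controlled vocabularies
#'
#' A `medsom_vocabulary` is an ordered set of controlled-vocabulary terms
#' (MeSH-like), each carrying one or more dot-separated tree-number paths
#' placing it in the vocabulary hierarchy.  Terms whose tree paths fall under
#' one of the configured *domain* subtree prefixes (e.g. the subtree holding
#' psychiatric headings) are flagged `is_domain`.  Column order of the
#' document-term matrix is the file/construction order of the retained terms,
#' never sorted, so codebooks are reproducible across runs.
#'
#' @param terms data.frame with columns `term_id`, `label`, `tree_paths`
#'   (list column or semicolon-joined character), optional `admin` (logical)
#'   and `annotation_count`.
#' @param domain_prefixes character vector of tree-number prefixes defining
#'   the domain subtree(s); a term is in-domain iff any of its tree paths
#'   starts with one of these prefixes (prefix match on whole dot components).
#' @return an object of class `medsom_vocabulary` with elements `terms`
#'   (data.frame, one row per retained term, columns `term_id`, `label`,
#'   `tree_paths` list column, `is_domain`, `annotation_count`), `D` (number
#'   of retained terms) and `domain_prefixes`.
#' @export
new_vocabulary <- function(terms, domain_prefixes = character()) {
  stopifnot(is.data.frame(terms), all(c("term_id", "label", "tree_paths") %in% names(terms)))
  term_id <- as.character(terms$term_id)
  dup <- term_id[duplicated(term_id)]
  if (length(dup) > 0) {
    stopf("duplicate term_id in vocabulary: %s", paste(unique(dup), collapse = ", "))
  }
  paths <- terms$tree_paths
  if (!is.list(paths)) {
    paths <- lapply(strsplit(as.character(paths), ";", fixed = TRUE), squish_paths)
  }
  is_domain <- vapply(paths, path_in_domain, logical(1), prefixes = domain_prefixes)
  ann <- if ("annotation_count" %in% names(terms)) as.integer(terms$annotation_count) else rep(0L, nrow(terms))
  out <- list(
    terms = data.frame(
      term_id = term_id,
      label = as.character(terms$label),
      is_domain = is_domain,
      annotation_count = ann,
      stringsAsFactors = FALSE
    ),
    D = nrow(terms),
    domain_prefixes = as.character(domain_prefixes)
  )
  out$terms$tree_paths <- paths
  class(out) <- "medsom_vocabulary"
  out
}

squish_paths <- function(p) squish(p[nzchar(squish(p))])

# A term is in-domain when any tree path starts with any configured prefix
# (plain string prefix: "F" catches the whole F subtree).
path_in_domain <- function(paths, prefixes) {
  if (length(prefixes) == 0 || length(paths) == 0) return(FALSE)
  any(vapply(paths, function(p) any(startsWith(p, prefixes)), logical(1)))
}

#' @export
print.medsom_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<medsom_vocabulary> D = %d terms (%d in-domain; prefixes: %s)\n",
    x$D, sum(x$terms$is_domain),
    if (length(x$domain_prefixes)) paste(x$domain_prefixes, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Column indices of term ids in a vocabulary
#'
#' @param vocab a `medsom_vocabulary`.
#' @param term_ids character vector.
#' @return integer indices (NA for unknown terms), 1-based.
#' @export
term_index <- function(vocab, term_ids) {
  match(as.character(term_ids), vocab$terms$term_id)
}

#' Read a vocabulary from TSV
#'
#' Expects a header line and columns `term_id`, `label`, `tree_paths`
#' (semicolon-separated tree numbers) and optionally `admin` (0/1 or
#' true/false).  Administrative terms are excluded from the vocabulary and
#' from the column index.  Column order is file order.
#'
#' @param path TSV file path.
#' @inheritParams new_vocabulary
#' @return a `medsom_vocabulary`.
#' @export
read_vocabulary <- function(path, domain_prefixes = character()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  need <- c("term_id", "label", "tree_paths")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("vocabulary file %s lacks column(s): %s", path, paste(missing, collapse = ", "))
  }
  if ("admin" %in% names(df)) {
    adm <- tolower(df$admin) %in% c("1", "true", "t", "yes")
    df <- df[!adm, , drop = FALSE]
  }
  if ("annotation_count" %in% names(df)) {
    df$annotation_count <- as.integer(df$annotation_count)
  }
  new_vocabulary(df, domain_prefixes = domain_prefixes)
}

#' Write a vocabulary to TSV
#'
#' Inverse of [read_vocabulary()]; `admin` terms were already dropped at read
#' time so none are written.
#'
#' @param vocab a `medsom_vocabulary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- data.frame(
    term_id = vocab$terms$term_id,
    label = vocab$terms$label,
    tree_paths = vapply(vocab$terms$tree_paths, paste, "", collapse = ";"),
    annotation_count = vocab$terms$annotation_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
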