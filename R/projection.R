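#' Project a document set onto a trained codebook
#'
#' Maps every article of `corpus` to the grid coordinates of its best
#' matching unit and tallies a per-node density grid.  Articles with zero
#' annotations cannot be projected and are rejected with a report.
#'
#' @param corpus a `medsom_corpus` vectorized against the codebook's
#'   vocabulary (digest mismatch raises an error).
#' @param codebook a trained `som_codebook`.
#' @param label free-text label for the projected set (e.g. `"edition 3"`).
#' @return a `som_projection`: list with `articles` (data.frame: article_id,
#'   row, col, bmu_index), `density` (R x C integer matrix), `label`, and
#'   `rejected_ids`.
#' @export
project_corpus <- function(corpus, codebook, label = "") {
  if (!is.null(codebook$provenance$vocab_digest) &&
      !is.null(corpus$vocab_digest) &&
      !identical(codebook$provenance$vocab_digest, corpus$vocab_digest)) {
    stopf("vocabulary digest mismatch: corpus %s vs codebook %s",
          corpus$vocab_digest, codebook$provenance$vocab_digest)
  }
  da <- annotation_counts(corpus)
  rejected <- corpus$article_ids[da == 0]
  keep <- da > 0
  X <- corpus$matrix[keep, , drop = FALSE]
  ids <- corpus$article_ids[keep]
  bm <- bmu_all(X, codebook$W)
  co <- codebook$grid$coords
  articles <- data.frame(
    article_id = ids,
    row = co[bm$b1, 1],
    col = co[bm$b1, 2],
    bmu_index = bm$b1,
    stringsAsFactors = FALSE
  )
  density <- matrix(0L, codebook$grid$rows, codebook$grid$cols)
  tab <- tabulate(bm$b1, nbins = codebook$grid$M)
  density[cbind(co[, 1], co[, 2])] <- tab
  structure(list(articles = articles, density = density, label = label,
                 grid = codebook$grid, rejected_ids = rejected),
            class = "som_projection")
}

#' @export
print.som_projection <- function(x, ...) {
  cat(sprintf("<som_projection> %s%d articles on %dx%d grid (%d nodes occupied)\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              nrow(x$articles), x$grid$rows, x$grid$cols,
              sum(x$density > 0)))
  invisible(x)
}

#' Write a projection to TSV
#'
#' @param projection a `som_projection`.
#' @param path output path; columns article_id, row, col, plus `cluster`
#'   when `labels` is supplied.
#' @param labels optional integer cluster labels aligned with
#'   `projection$articles`.
#' @return `path`, invisibly.
#' @export
write_projection_tsv <- function(projection, path, labels = NULL) {
  df <- projection$articles
  if (!is.null(labels)) df$cluster <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a density grid to TSV
#'
#' Long format: row, col, count, for nodes with nonzero counts.
#'
#' @inheritParams write_projection_tsv
#' @export
write_density_tsv <- function(projection, path) {
  nz <- which(projection$density > 0, arr.ind = TRUE)
  df <- data.frame(row = nz[, 1], col = nz[, 2],
                   count = projection$density[nz])
  df <- df[order(df$row, df$col), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
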