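#' Grid geometry of a self-organizing map
#'
#' Nodes live on an R x C rectangular grid.  Coordinates are (row, col),
#' 1-based; the linear index of node (r, c) is `(r - 1) * C + c` (row-major).
#'
#' @param rows,cols positive integers.
#' @return a `som_grid` object with `rows`, `cols`, `M = rows * cols`, and
#'   `coords` (M x 2 matrix of node row/col positions in linear-index order).
#' @export
som_grid <- function(rows, cols = rows) {
  stopifnot(rows >= 1, cols >= 1)
  rows <- as.integer(rows); cols <- as.integer(cols)
  coords <- cbind(
    row = rep(seq_len(rows), each = cols),
    col = rep(seq_len(cols), times = rows)
  )
  structure(list(rows = rows, cols = cols, M = rows * cols, coords = coords),
            class = "som_grid")
}

#' Training schedule for batch SOM
#'
#' The neighborhood width shrinks geometrically over epochs:
#' `sigma(e) = sigma0 / decay_base^e` for epoch `e = 1..epochs`, so the first
#' epoch already trains below `sigma0`.  With the defaults used at
#' literature-map scale (sigma0 = 175 on a 350-per-side grid, base 1.7,
#' 20 epochs) the width starts at half the grid and drops below one grid
#' unit around epoch 10.
#'
#' @param epochs number of training epochs (default 20).
#' @param sigma0 initial neighborhood width in grid units; conventionally
#'   half the grid side.
#' @param decay_base geometric decay base, > 1 (default 1.7).
#' @param seed integer RNG seed controlling codebook initialization.
#' @return a `som_schedule` object.
#' @export
som_schedule <- function(epochs = 20, sigma0, decay_base = 1.7, seed = 1L) {
  stopifnot(epochs >= 1, sigma0 > 0, decay_base > 1)
  structure(list(epochs = as.integer(epochs), sigma0 = sigma0,
                 decay_base = decay_base, seed = as.integer(seed)),
            class = "som_schedule")
}

#' Neighborhood widths of a schedule
#'
#' @param schedule a `som_schedule`.
#' @param epochs epochs to evaluate (default all).
#' @return numeric vector `sigma0 / decay_base^e`, strictly decreasing.
#' @export
sigma_at <- function(schedule, epochs = seq_len(schedule$epochs)) {
  schedule$sigma0 / schedule$decay_base^epochs
}

#' Initialize a codebook from sampled articles
#'
#' Each node weight vector is a uniformly sampled (with replacement) article
#' vector from the corpus, plus small seeded jitter to break exact ties
#' between nodes; weights are clamped back to [0, 1] so the batch-update
#' convexity invariant holds from the start.  Deterministic given
#' `schedule$seed`.
#'
#' @param corpus a nonempty `medsom_corpus`.
#' @param grid a `som_grid`.
#' @param schedule a `som_schedule` (supplies the seed).
#' @param jitter jitter half-range (default 1e-3; 0 disables).
#' @return a `som_codebook`: list with `W` (M x D dense weight matrix),
#'   `grid`, `schedule`, `te_history` (numeric, empty before training),
#'   `epoch_of_origin` (0 for the initial state) and `provenance`
#'   (vocabulary digest + schedule).
#' @export
init_codebook <- function(corpus, grid, schedule, jitter = 1e-3) {
  if (corpus$N == 0) stopf("cannot initialize a codebook from an empty corpus")
  stopifnot(grid$M >= 2)
  W <- with_seed(schedule$seed, {
    idx <- sample.int(corpus$N, grid$M, replace = TRUE)
    W <- as.matrix(corpus$matrix[idx, , drop = FALSE])
    dimnames(W) <- NULL
    if (jitter > 0) {
      W <- W + matrix(stats::runif(length(W), -jitter, jitter), nrow(W))
      W[W < 0] <- 0
      W[W > 1] <- 1
    }
    W
  })
  structure(
    list(W = W, grid = grid, schedule = schedule,
         te_history = numeric(), epoch_of_origin = 0L,
         provenance = list(vocab_digest = corpus$vocab_digest,
                           schedule = unclass(schedule), jitter = jitter)),
    class = "som_codebook"
  )
}

#' @export
print.som_codebook <- function(x, ...) {
  cat(sprintf("<som_codebook> %dx%d grid (M = %d), D = %d; trained epochs: %d\n",
              x$grid$rows, x$grid$cols, x$grid$M, ncol(x$W),
              length(x$te_history)))
  if (length(x$te_history) > 0) {
    cat(sprintf("  topographic error: best %.4f at epoch %d\n",
                min(x$te_history), which.min(x$te_history)))
  }
  invisible(x)
}

# First and second best matching units for every row of a sparse binary
# matrix X (N x D) against dense weights W (M x D).  Exploits
# ||x - w||^2 = ||x||^2 + ||w||^2 - 2 x.w, so X is touched only at its
# nonzeros.  Ties break to the lowest linear node index; the second BMU
# excludes only the first.  Articles are processed in chunks to bound the
# N x M distance block.
bmu_all <- function(X, W, chunk = 2048L) {
  if (ncol(X) != ncol(W)) {
    stopf("dimension mismatch: input has D = %d, codebook has D = %d",
          ncol(X), ncol(W))
  }
  n <- nrow(X)
  w2 <- rowSums(W * W)
  b1 <- integer(n); b2 <- integer(n)
  d1 <- numeric(n); d2 <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Xc <- X[idx, , drop = FALSE]
    x2 <- Matrix::rowSums(Xc * Xc)
    # dist2 is |idx| x M: row i = squared distances of article i to all nodes
    cross <- as.matrix(Matrix::tcrossprod(Xc, W))
    dist2 <- sweep(-2 * cross, 2, w2, `+`) + x2
    f <- max.col(-dist2, ties.method = "first")
    d1[idx] <- dist2[cbind(seq_along(idx), f)]
    dist2[cbind(seq_along(idx), f)] <- Inf
    s <- max.col(-dist2, ties.method = "first")
    d2[idx] <- dist2[cbind(seq_along(idx), s)]
    b1[idx] <- f; b2[idx] <- s
  }
  list(b1 = b1, b2 = b2, dist2_1 = pmax(d1, 0), dist2_2 = pmax(d2, 0))
}

#' Best and second-best matching unit of one input vector
#'
#' @param x binary input vector (length D, sparse or dense) or a 1 x D
#'   matrix.
#' @param codebook a `som_codebook`.
#' @return list with `first`/`second` (linear node indices, 1-based),
#'   `first_dist2`/`second_dist2` (squared Euclidean distances) and
#'   `first_coord`/`second_coord` ((row, col) pairs).  Ties break to the
#'   lowest linear index; `second` excludes only `first`.
#' @export
find_bmu <- function(x, codebook) {
  X <- if (inherits(x, "Matrix") && nrow(x) == 1) x else Matrix::Matrix(x, nrow = 1, sparse = TRUE)
  r <- bmu_all(X, codebook$W)
  list(first = r$b1[1], second = r$b2[1],
       first_dist2 = r$dist2_1[1], second_dist2 = r$dist2_2[1],
       first_coord = codebook$grid$coords[r$b1[1], ],
       second_coord = codebook$grid$coords[r$b2[1], ])
}

# Kernel matrix H (M x M): H[b, j] = neighborhood weight of node j around a
# BMU at node b, for Euclidean grid distance d and width sigma.
neighborhood_matrix <- function(grid, sigma, kernel = c("gaussian", "bubble")) {
  kernel <- match.arg(kernel)
  co <- grid$coords
  d2 <- outer(co[, 1], co[, 1], `-`)^2 + outer(co[, 2], co[, 2], `-`)^2
  if (kernel == "gaussian") exp(-d2 / (2 * sigma^2)) else (d2 <= sigma^2) * 1
}

#' One batch training epoch
#'
#' Kohonen batch update for sparse binary input: every article is assigned
#' its BMU under the *pre-epoch* codebook, neighborhood-weighted sums
#' `S_j = sum_i h(b1(i), j) x_i` and `Z_j = sum_i h(b1(i), j)` are
#' accumulated, and at epoch end each node moves to `S_j / Z_j`.  Nodes with
#' `Z_j <= eps` keep their previous weights (dead-node rule).  Because all
#' assignments use the pre-epoch codebook, the update is invariant to
#' article order, and on binary input every new weight is a convex
#' combination of article vectors, hence stays in [0, 1].
#'
#' @param codebook a `som_codebook`.
#' @param corpus a `medsom_corpus` with matching D.
#' @param sigma_e neighborhood width for this epoch, > 0.
#' @param kernel `"gaussian"` (default) or `"bubble"`.
#' @param eps dead-node threshold on the denominator (default 1e-12).
#' @return the updated `som_codebook` (epoch counter advanced).
#' @export
batch_epoch <- function(codebook, corpus, sigma_e,
                        kernel = c("gaussian", "bubble"), eps = 1e-12) {
  stopifnot(sigma_e > 0)
  kernel <- match.arg(kernel)
  M <- codebook$grid$M
  bm <- bmu_all(corpus$matrix, codebook$W)
  counts <- tabulate(bm$b1, nbins = M)
  # aggregate article vectors by BMU node, then smear through the kernel
  Bind <- Matrix::sparseMatrix(i = seq_len(corpus$N), j = bm$b1, x = 1,
                               dims = c(corpus$N, M))
  Tm <- Matrix::crossprod(Bind, corpus$matrix)      # M x D: per-node input sums
  H <- neighborhood_matrix(codebook$grid, sigma_e, kernel)
  S <- as.matrix(H %*% Tm)
  Z <- as.vector(H %*% counts)
  live <- Z > eps
  Wnew <- codebook$W
  Wnew[live, ] <- S[live, , drop = FALSE] / Z[live]
  if (!all(is.finite(Wnew))) {
    stopf("batch_epoch produced non-finite weights (check eps / input)")
  }
  codebook$W <- Wnew
  codebook$epoch_of_origin <- codebook$epoch_of_origin + 1L
  codebook
}

#' Topographic error
#'
#' Fraction of articles whose first and second BMUs are not adjacent on the
#' grid.  Adjacency defaults to the 8-neighborhood (Chebyshev distance 1);
#' `"rook"` restricts to the 4-neighborhood.
#'
#' @param codebook a `som_codebook`.
#' @param corpus a nonempty `medsom_corpus`.
#' @param adjacency `"queen"` (8-neighborhood, default) or `"rook"`.
#' @return a value in [0, 1]; 0 means perfect topology preservation.
#' @export
topographic_error <- function(codebook, corpus, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  if (corpus$N == 0) stopf("topographic error undefined for an empty corpus")
  bm <- bmu_all(corpus$matrix, codebook$W)
  co <- codebook$grid$coords
  dr <- abs(co[bm$b1, 1] - co[bm$b2, 1])
  dc <- abs(co[bm$b1, 2] - co[bm$b2, 2])
  adj <- if (adjacency == "queen") pmax(dr, dc) <= 1 else (dr + dc) <= 1
  mean(!adj)
}

#' Train a batch SOM with topographic-error model selection
#'
#' Runs `schedule$epochs` batch epochs with shrinking neighborhood width
#' `sigma(e) = sigma0 / decay_base^e`, computes the topographic error after
#' each epoch, and returns the post-epoch codebook with the lowest
#' topographic error (earliest epoch on ties).  Bit-reproducible for a fixed
#' seed.
#'
#' @inheritParams batch_epoch
#' @param grid a `som_grid`.
#' @param schedule a `som_schedule`.
#' @param adjacency passed to [topographic_error()].
#' @param jitter passed to [init_codebook()].
#' @param verbose emit one log line per epoch (epoch, sigma, TE).
#' @return the selected `som_codebook`; `te_history` holds the per-epoch
#'   topographic errors of the full run and `epoch_of_origin` the selected
#'   epoch.
#' @export
som_train <- function(corpus, grid, schedule,
                      kernel = c("gaussian", "bubble"),
                      adjacency = c("queen", "rook"),
                      jitter = 1e-3, verbose = FALSE) {
  kernel <- match.arg(kernel)
  adjacency <- match.arg(adjacency)
  cb <- init_codebook(corpus, grid, schedule, jitter = jitter)
  sigmas <- sigma_at(schedule)
  te <- numeric(schedule$epochs)
  best <- NULL
  for (e in seq_len(schedule$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    cb <- batch_epoch(cb, corpus, sigmas[e], kernel = kernel)
    te[e] <- topographic_error(cb, corpus, adjacency = adjacency)
    if (verbose) {
      message(sprintf("epoch %2d  sigma %8.4f  topographic_error %.4f  (%.2fs)",
                      e, sigmas[e], te[e], proc.time()[["elapsed"]] - t0))
    }
    if (is.null(best) || te[e] < min(te[seq_len(e - 1)])) {
      best <- cb
      best$epoch_of_origin <- e
    }
  }
  best$te_history <- te
  best$provenance$kernel <- kernel
  best$provenance$adjacency <- adjacency
  best
}

#' Classify nodes as domain versus non-domain
#'
#' A node is domain-positive iff the mean of its weights over the in-domain
#' vocabulary columns strictly exceeds the mean over the remaining columns
#' (so a perfectly uniform node is non-domain).
#'
#' @param codebook a `som_codebook`.
#' @param vocab the `medsom_vocabulary` the codebook was trained against.
#' @return logical vector of length M in linear node-index order.
#' @export
classify_nodes <- function(codebook, vocab) {
  check_digest(codebook, vocab)
  dom <- vocab$terms$is_domain
  if (!any(dom)) stopf("no domain terms in vocabulary; node classification undefined")
  if (all(dom)) stopf("no non-domain terms in vocabulary; node classification undefined")
  rowMeans(codebook$W[, dom, drop = FALSE]) >
    rowMeans(codebook$W[, !dom, drop = FALSE])
}

check_digest <- function(codebook, obj) {
  have <- if (inherits(obj, "medsom_vocabulary")) vocab_digest(obj) else obj$vocab_digest
  want <- codebook$provenance$vocab_digest
  if (!is.null(want) && !is.null(have) && !identical(want, have)) {
    warnf("vocabulary digest mismatch: codebook trained against %s, supplied %s",
          want, have)
  }
  invisible(TRUE)
}

#' Save/load a codebook
#'
#' Text container: a JSON header line (geometry, schedule, epoch of origin,
#' topographic-error history, provenance) followed by one tab-separated row
#' of weights per node, printed with `%.17g` so 64-bit doubles round-trip
#' exactly.  [export_codebook_tsv()] writes a plain M-row TSV of the weight
#' matrix for interoperability.
#'
#' @param codebook a `som_codebook`.
#' @param path file path.
#' @param vocab optional vocabulary checked against the stored digest at
#'   load time (mismatch is a warning).
#' @return `write_codebook` returns `path` invisibly; `read_codebook`
#'   returns the `som_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  header <- jsonlite::toJSON(list(
    container = "medsom_codebook", version = 1L,
    rows = codebook$grid$rows, cols = codebook$grid$cols,
    D = ncol(codebook$W),
    epoch_of_origin = codebook$epoch_of_origin,
    te_history = codebook$te_history,
    schedule = unclass(codebook$schedule),
    provenance = codebook$provenance
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(as.character(header), con)
  apply(codebook$W, 1, function(w) {
    writeLines(paste(sprintf("%.17g", w), collapse = "\t"), con)
  })
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path, vocab = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) NULL)
  if (is.null(hdr) || !identical(hdr$container, "medsom_codebook")) {
    stopf("%s is not a medsom codebook container", path)
  }
  M <- hdr$rows * hdr$cols
  if (length(lines) != M + 1) {
    stopf("corrupt codebook %s: expected %d weight rows, found %d",
          path, M, length(lines) - 1)
  }
  W <- matrix(0, M, hdr$D)
  for (j in seq_len(M)) {
    w <- as.numeric(strsplit(lines[j + 1], "\t", fixed = TRUE)[[1]])
    if (length(w) != hdr$D || anyNA(w)) {
      stopf("corrupt codebook %s: bad weight row %d", path, j)
    }
    W[j, ] <- w
  }
  sch <- som_schedule(epochs = hdr$schedule$epochs, sigma0 = hdr$schedule$sigma0,
                      decay_base = hdr$schedule$decay_base, seed = hdr$schedule$seed)
  cb <- structure(
    list(W = W, grid = som_grid(hdr$rows, hdr$cols), schedule = sch,
         te_history = as.numeric(hdr$te_history),
         epoch_of_origin = as.integer(hdr$epoch_of_origin),
         provenance = hdr$provenance),
    class = "som_codebook"
  )
  if (!is.null(vocab)) check_digest(cb, vocab)
  cb
}

#' @rdname write_codebook
#' @export
export_codebook_tsv <- function(codebook, path) {
  df <- as.data.frame(codebook$W)
  names(df) <- paste0("w", seq_len(ncol(df)))
  co <- codebook$grid$coords
  out <- cbind(data.frame(node = seq_len(codebook$grid$M),
                          row = co[, 1], col = co[, 2]), df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
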