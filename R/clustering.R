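#' K-means on grid positions
#'
#' Lloyd's algorithm with k-means++ seeding, run `restarts` times with
#' derived seeds; the restart with the lowest within-cluster sum of squares
#' (WSS) wins.  Duplicate points are legal and each counts (many articles
#' share a node).  An empty cluster is repaired by moving its center to the
#' point currently farthest from its assigned center.  Deterministic given
#' `seed`.
#'
#' @param points numeric matrix (n x 2) of (row, col) grid coordinates, or a
#'   `som_projection`.
#' @param k number of clusters, `1 <= k <=` number of distinct points.
#' @param restarts number of seeded restarts (default 10).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per restart.
#' @return list with `centers` (k x 2), `labels` (integer n, 1..k), `wss`
#'   (total within-cluster sum of squares), `iterations`.
#' @export
kmeans_grid <- function(points, k, restarts = 10, seed = 1L, max_iter = 100L) {
  pts <- as_points(points)
  n <- nrow(pts)
  ndistinct <- nrow(unique(pts))
  if (k < 1) stopf("k must be >= 1")
  if (k > ndistinct) {
    stopf("k = %d exceeds the %d distinct points available", k, ndistinct)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seed + r - 1L, lloyd_once(pts, k, max_iter))
    if (is.null(best) || fit$wss < best$wss - 1e-12) best <- fit
  }
  best
}

as_points <- function(points) {
  if (inherits(points, "som_projection")) {
    points <- cbind(points$articles$row, points$articles$col)
  }
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  stopifnot(ncol(pts) == 2, nrow(pts) >= 1)
  dimnames(pts) <- NULL
  pts
}

# squared Euclidean distances of every point to every center (n x k)
dist2_to <- function(pts, centers) {
  outer(pts[, 1], centers[, 1], `-`)^2 + outer(pts[, 2], centers[, 2], `-`)^2
}

kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(0, k, 2)
  centers[1, ] <- pts[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- dist2_to(pts, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        # all remaining mass at chosen centers: fall back to a distinct point
        cand <- which(!duplicated(pts) & d2 == 0)
        centers[j, ] <- pts[sample.int(n, 1), ]
      } else {
        pick <- sample.int(n, 1, prob = d2 / sum(d2))
        centers[j, ] <- pts[pick, ]
      }
      d2 <- pmin(d2, dist2_to(pts, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

lloyd_once <- function(pts, k, max_iter) {
  n <- nrow(pts)
  centers <- kmeanspp_init(pts, k)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to(pts, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: seize the point farthest from its center
    for (j in which(tabulate(new_labels, k) == 0)) {
      cur <- d2[cbind(seq_len(n), new_labels)]
      far <- which.max(cur)
      new_labels[far] <- j
      centers[j, ] <- pts[far, ]
      d2[, j] <- dist2_to(pts, centers[j, , drop = FALSE])[, 1]
    }
    if (it > 1 && all(new_labels == labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(pts[labels == j, , drop = FALSE])
    }
  }
  d2 <- dist2_to(pts, centers)
  labels <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_len(n), labels)])
  list(centers = centers, labels = labels, wss = wss, iterations = it)
}

#' Within-cluster sum-of-squares curve over k
#'
#' Runs [kmeans_grid()] for `k = 1..k_max` and records the best WSS at each
#' k.  `wss[1]` equals the total sum of squares about the grand centroid.
#'
#' @inheritParams kmeans_grid
#' @param k_max largest k scanned (default 12; capped at the number of
#'   distinct points).
#' @return a `wss_curve`: data.frame with columns `k` and `wss`, with the
#'   elbow-chosen k in attribute `chosen_k` (see [elbow_select()]).
#' @export
wss_curve <- function(points, k_max = 12, restarts = 10, seed = 1L) {
  pts <- as_points(points)
  k_max <- min(k_max, nrow(unique(pts)))
  wss <- vapply(seq_len(k_max), function(k) {
    kmeans_grid(pts, k, restarts = restarts, seed = seed)$wss
  }, numeric(1))
  curve <- data.frame(k = seq_len(k_max), wss = wss)
  class(curve) <- c("wss_curve", "data.frame")
  attr(curve, "chosen_k") <- elbow_select(curve)
  curve
}

#' Elbow selection of the cluster count
#'
#' Picks the k whose point (k, wss(k)) lies farthest (perpendicular
#' distance) from the chord joining the first and last points of the WSS
#' curve; ties go to the smaller k.  A flat or perfectly linear curve has no
#' elbow: returns 1 with a warning.
#'
#' @param curve a `wss_curve` or data.frame with columns `k` and `wss`
#'   (at least 3 rows).
#' @return the chosen k (integer).
#' @export
elbow_select <- function(curve) {
  k <- curve$k; w <- curve$wss
  stopifnot(length(k) >= 3)
  x1 <- k[1]; y1 <- w[1]
  x2 <- k[length(k)]; y2 <- w[length(k)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * k - (x2 - x1) * w + x2 * y1 - y2 * x1) / len
  if (!is.finite(len) || len == 0 || max(d) < 1e-9) {
    warnf("WSS curve has no elbow (flat or linear); returning k = 1")
    return(1L)
  }
  as.integer(k[which.max(d)])
}

#' Characterize clusters by defining terms and exemplar articles
#'
#' For each cluster: the `n_top` most frequent vocabulary terms among member
#' articles (ties broken alphabetically by label), then each member article
#' scored by how many of those top terms annotate it, and the `n_top`
#' highest-scoring articles reported (ties broken by ascending article id).
#' Clusters smaller than `n_top` report all members without padding.
#'
#' @param labels integer cluster labels (1..k) aligned with the rows of
#'   `corpus`.
#' @param corpus the projected `medsom_corpus` (same article order as the
#'   projection used for clustering).
#' @param vocab the `medsom_vocabulary`.
#' @param n_top list length (default 10).
#' @return list of per-cluster summaries, each with `cluster`, `size`,
#'   `top_terms` (data.frame: term_id, label, count) and `exemplars`
#'   (data.frame: article_id, score).
#' @export
characterize_clusters <- function(labels, corpus, vocab, n_top = 10) {
  stopifnot(length(labels) == corpus$N)
  k <- max(labels)
  lapply(seq_len(k), function(cl) {
    member <- which(labels == cl)
    sub <- corpus$matrix[member, , drop = FALSE]
    counts <- as.integer(Matrix::colSums(sub))
    present <- which(counts > 0)
    ord <- present[order(-counts[present], vocab$terms$label[present])]
    top <- utils::head(ord, n_top)
    top_terms <- data.frame(
      term_id = vocab$terms$term_id[top],
      label = vocab$terms$label[top],
      count = counts[top],
      stringsAsFactors = FALSE
    )
    score <- as.integer(Matrix::rowSums(sub[, top, drop = FALSE]))
    ids <- corpus$article_ids[member]
    aord <- order(-score, ids)
    ex <- utils::head(aord, n_top)
    list(cluster = cl, size = length(member), top_terms = top_terms,
         exemplars = data.frame(article_id = ids[ex], score = score[ex],
                                stringsAsFactors = FALSE))
  })
}

#' Bivariate normal confidence ellipse of a point cloud
#'
#' Mean and sample covariance of the points, with the radial scale factor
#' `sqrt(qchisq(level, df = 2))` that makes the ellipse
#' `mean + scale * chol(cov) . unit circle` cover `level` of a bivariate
#' normal (the `stat_ellipse` construction; at level 0.95, scale^2 = 5.99).
#'
#' @param points n x 2 matrix, n >= 3, not collinear.
#' @param level coverage level in (0, 1), default 0.95.
#' @param name label used in degeneracy error messages.
#' @return list with `mean` (length 2), `cov` (2 x 2), `scale`, and `path`
#'   (100 x 2 polygon of the ellipse outline).
#' @export
normal_ellipse <- function(points, level = 0.95, name = "points") {
  pts <- as_points(points)
  stopifnot(level > 0, level < 1)
  if (nrow(pts) < 3) stopf("ellipse for %s needs >= 3 points", name)
  mu <- colMeans(pts)
  S <- stats::cov(pts)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-12 * max(abs(ev$values), 1)) {
    stopf("degenerate (collinear) point cloud for %s; ellipse undefined", name)
  }
  scale <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = 100)
  circ <- cbind(cos(theta), sin(theta))
  axes <- ev$vectors %*% diag(sqrt(ev$values))
  path <- sweep(scale * circ %*% Matrix::t(axes), 2, mu, `+`)
  list(mean = mu, cov = S, scale = scale, path = path)
}

#' Full projection-clustering pipeline for one document set
#'
#' Projects the corpus, scans the WSS curve, picks k by the elbow rule (or
#' uses `force_k`), fits the final k-means, and attaches cluster
#' characterizations and per-cluster 95% ellipses (skipped with a warning
#' for degenerate clusters).
#'
#' @inheritParams project_corpus
#' @inheritParams kmeans_grid
#' @param vocab the `medsom_vocabulary`, used for cluster characterization.
#' @param force_k fix the cluster count instead of the elbow choice.
#' @param k_max elbow scan bound.
#' @param level ellipse coverage level.
#' @param n_top passed to [characterize_clusters()].
#' @return a `cluster_model`: list with `projection`, `curve`, `k`,
#'   `centers`, `labels`, `wss`, `clusters` (characterizations), `ellipses`.
#' @export
cluster_projection <- function(corpus, codebook, vocab, label = "",
                               force_k = NULL, k_max = 12, restarts = 10,
                               seed = 1L, level = 0.95, n_top = 10) {
  proj <- project_corpus(corpus, codebook, label = label)
  pts <- as_points(proj)
  curve <- wss_curve(pts, k_max = k_max, restarts = restarts, seed = seed)
  k <- if (is.null(force_k)) attr(curve, "chosen_k") else as.integer(force_k)
  fit <- kmeans_grid(pts, k, restarts = restarts, seed = seed)
  chars <- characterize_clusters(fit$labels,
                                 corpus_subset(corpus, proj$articles$article_id),
                                 vocab, n_top = n_top)
  structure(
    list(projection = proj, curve = curve, k = k, centers = fit$centers,
         labels = fit$labels, wss = fit$wss, clusters = chars,
         ellipses = cluster_ellipses(pts, fit$labels, level = level)),
    class = "cluster_model"
  )
}

cluster_ellipses <- function(pts, labels, level = 0.95) {
  lapply(seq_len(max(labels)), function(cl) {
    sub <- pts[labels == cl, , drop = FALSE]
    tryCatch(normal_ellipse(sub, level = level, name = sprintf("cluster %d", cl)),
             error = function(e) {
               warnf("cluster %d: %s", cl, conditionMessage(e))
               NULL
             })
  })
}

#' Cross-edition cluster overlap report
#'
#' For every ordered pair of editions, clusters are matched greedily by
#' centroid distance (closest available pair first); each matched pair is
#' reported with its centroid distance and the Jaccard overlap of the grid
#' node sets its member articles occupy.  When the editions were clustered
#' with different k, leftover clusters are flagged unmatched.
#'
#' @param models named list of fitted models, each a list with at least
#'   `centers` (k x 2), `labels`, and `projection` (a `som_projection`) —
#'   e.g. outputs of [cluster_projection()].  All editions must be projected
#'   on the same codebook.
#' @return data.frame: edition_a, edition_b, cluster_a, cluster_b (NA when
#'   unmatched), centroid_dist, jaccard.
#' @export
overlap_report <- function(models) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  node_sets <- lapply(models, function(m) {
    split(m$projection$articles$bmu_index, m$labels)
  })
  out <- list()
  eds <- names(models)
  for (a in eds) for (b in eds) {
    ca <- models[[a]]$centers; cb <- models[[b]]$centers
    d <- outer(seq_len(nrow(ca)), seq_len(nrow(cb)), Vectorize(function(i, j) {
      sqrt(sum((ca[i, ] - cb[j, ])^2))
    }))
    pairs <- greedy_match(d)
    rows <- lapply(seq_len(nrow(pairs)), function(p) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      sa <- unique(node_sets[[a]][[i]]); sb <- unique(node_sets[[b]][[j]])
      data.frame(edition_a = a, edition_b = b, cluster_a = i, cluster_b = j,
                 centroid_dist = d[i, j],
                 jaccard = length(intersect(sa, sb)) / length(union(sa, sb)),
                 stringsAsFactors = FALSE)
    })
    un_a <- setdiff(seq_len(nrow(ca)), pairs[, 1])
    un_b <- setdiff(seq_len(nrow(cb)), pairs[, 2])
    extra <- c(
      lapply(un_a, function(i) data.frame(edition_a = a, edition_b = b,
                                          cluster_a = i, cluster_b = NA_integer_,
                                          centroid_dist = NA_real_, jaccard = NA_real_,
                                          stringsAsFactors = FALSE)),
      lapply(un_b, function(j) data.frame(edition_a = a, edition_b = b,
                                          cluster_a = NA_integer_, cluster_b = j,
                                          centroid_dist = NA_real_, jaccard = NA_real_,
                                          stringsAsFactors = FALSE))
    )
    out <- c(out, rows, extra)
  }
  do.call(rbind, out)
}

# Greedy bipartite matching on a distance matrix: repeatedly take the
# globally closest unmatched pair.  Returns a matrix with columns (i, j).
greedy_match <- function(d) {
  n <- min(nrow(d), ncol(d))
  pairs <- matrix(0L, n, 2)
  used_i <- logical(nrow(d)); used_j <- logical(ncol(d))
  for (p in seq_len(n)) {
    dd <- d
    dd[used_i, ] <- Inf
    dd[, used_j] <- Inf
    best <- arrayInd(which.min(dd), dim(dd))
    pairs[p, ] <- best
    used_i[best[1]] <- TRUE
    used_j[best[2]] <- TRUE
  }
  pairs
}
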