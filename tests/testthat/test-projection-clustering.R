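test_that("projection equals per-article BMU calls and fills the density grid", {
  rc <- random_corpus(20, n_terms = 15, seed = 17)
  cb <- som_train(rc$corpus, som_grid(5),
                  som_schedule(epochs = 2, sigma0 = 2.5, seed = 17))
  proj <- project_corpus(rc$corpus, cb, label = "fixture")
  expect_equal(sum(proj$density), 20)
  for (i in seq_len(rc$corpus$N)) {
    b <- find_bmu(rc$corpus$matrix[i, ], cb)
    expect_equal(proj$articles$bmu_index[i], b$first)
    expect_equal(c(proj$articles$row[i], proj$articles$col[i]),
                 unname(b$first_coord))
  }
  # two identical articles: same coordinates, density 2 at that node
  vocab <- rc$vocab
  two <- vectorize_corpus(list(
    list(article_id = "x1", term_ids = c("T00001", "T00002")),
    list(article_id = "x2", term_ids = c("T00001", "T00002"))
  ), vocab)
  p2 <- project_corpus(two, cb)
  expect_equal(p2$articles$bmu_index[1], p2$articles$bmu_index[2])
  expect_equal(max(p2$density), 2)
  expect_equal(sum(p2$density), 2)
})

test_that("projection rejects corpora from a different vocabulary", {
  rc <- random_corpus(10, n_terms = 15, seed = 18)
  cb <- som_train(rc$corpus, som_grid(4),
                  som_schedule(epochs = 1, sigma0 = 2, seed = 18))
  other <- random_corpus(5, n_terms = 15, seed = 99)
  expect_error(project_corpus(other$corpus, cb), "digest mismatch")
})

test_that("k-means closed forms: k = 1 centroid, separated pairs, duplicates", {
  pts <- rbind(c(0, 0), c(0, 2), c(10, 10), c(10, 12))
  one <- kmeans_grid(pts, 1, restarts = 3, seed = 1)
  expect_equal(one$centers[1, ], colMeans(pts))
  expect_equal(one$wss, sum(sweep(pts, 2, colMeans(pts))^2))

  two <- kmeans_grid(pts, 2, restarts = 5, seed = 1)
  expect_setequal(split(seq_len(4), two$labels), list(c(1L, 2L), c(3L, 4L)))
  expect_equal(two$wss, 2 + 2)   # hand sum: each pair contributes 2*1^2

  dup <- kmeans_grid(rbind(c(3, 3), c(3, 3), c(3, 3)), 1, seed = 2)
  expect_equal(dup$wss, 0)

  expect_error(kmeans_grid(rbind(c(1, 1), c(1, 1)), 2, seed = 1),
               "distinct points")
})

test_that("k-means WSS attains the exhaustive-assignment optimum on tiny instances", {
  set.seed(77)
  for (rep in 1:6) {
    n <- sample(5:8, 1); k <- sample(2:3, 1)
    pts <- matrix(runif(2 * n, 0, 10), n, 2)
    got <- kmeans_grid(pts, k, restarts = 20, seed = rep)$wss
    want <- exhaustive_kmeans_wss(pts, k)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("k-means agrees with stats::kmeans as an independent cross-check", {
  set.seed(55)
  pts <- rbind(matrix(rnorm(40, 2, .5), , 2), matrix(rnorm(40, 8, .5), , 2))
  ours <- kmeans_grid(pts, 2, restarts = 10, seed = 5)
  ref <- stats::kmeans(pts, 2, nstart = 10, algorithm = "Lloyd")
  expect_equal(ours$wss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("WSS curve starts at total SS and never increases", {
  set.seed(66)
  pts <- matrix(runif(120, 0, 20), , 2)
  cv <- wss_curve(pts, k_max = 8, restarts = 10, seed = 6)
  tss <- sum(sweep(pts, 2, colMeans(pts))^2)
  expect_equal(cv$wss[1], tss)
  expect_true(all(diff(cv$wss) <= 1e-9))
})

test_that("elbow picks the chord-distance maximizer, smaller k on ties", {
  expect_equal(elbow_select(data.frame(k = 1:5, wss = c(100, 20, 18, 17, 16))), 2L)
  expect_equal(elbow_select(data.frame(k = 1:5, wss = c(50, 30, 10, 9, 8))), 3L)
  expect_warning(k <- elbow_select(data.frame(k = 1:5, wss = c(40, 30, 20, 10, 0))),
                 "no elbow")
  expect_equal(k, 1L)
  expect_warning(kc <- elbow_select(data.frame(k = 1:4, wss = rep(5, 4))),
                 "no elbow")
  expect_equal(kc, 1L)
})

test_that("elbow recovers G separated Gaussian clusters for G in 2:4", {
  for (G in 2:4) {
    set.seed(100 + G)
    centers <- matrix(c(0, 0, 12, 0, 0, 12, 12, 12), , 2, byrow = TRUE)[1:G, , drop = FALSE]
    pts <- do.call(rbind, lapply(seq_len(G), function(g)
      cbind(rnorm(60, centers[g, 1], 1), rnorm(60, centers[g, 2], 1))))
    cv <- wss_curve(pts, k_max = 10, restarts = 10, seed = G)
    expect_equal(attr(cv, "chosen_k"), G)
  }
})

test_that("cluster characterization counts terms and ranks exemplars with tie rules", {
  vocab <- tiny_vocab()
  recs <- list(
    list(article_id = "a1", term_ids = c("T1", "T2")),
    list(article_id = "a2", term_ids = c("T1", "T2", "T4")),
    list(article_id = "a3", term_ids = c("T1", "T5")),
    list(article_id = "a4", term_ids = c("T4", "T5")),
    list(article_id = "a5", term_ids = "T6")
  )
  corpus <- vectorize_corpus(recs, vocab)
  labels <- c(1L, 1L, 1L, 2L, 2L)
  out <- characterize_clusters(labels, corpus, vocab, n_top = 2)
  # cluster 1 counts: T1 = 3, T2 = 2, T4 = 1, T5 = 1 -> top 2 = T1, T2
  expect_equal(out[[1]]$top_terms$term_id, c("T1", "T2"))
  expect_equal(out[[1]]$top_terms$count, c(3L, 2L))
  # scores vs top set {T1,T2}: a1 = 2, a2 = 2, a3 = 1; ties by id order
  expect_equal(out[[1]]$exemplars$article_id, c("a1", "a2"))
  expect_equal(out[[1]]$exemplars$score, c(2L, 2L))
  # cluster 2: T4, T5, T6 all count 1 -> alphabetical by label
  lab2 <- out[[2]]$top_terms$label
  expect_equal(lab2, sort(lab2))
  # every article carries cluster's top term -> count equals cluster size
  all_t1 <- vectorize_corpus(lapply(1:4, function(i)
    list(article_id = paste0("b", i), term_ids = "T1")), vocab)
  o2 <- characterize_clusters(rep(1L, 4), all_t1, vocab, n_top = 3)
  expect_equal(o2[[1]]$top_terms$term_id[1], "T1")
  expect_equal(o2[[1]]$top_terms$count[1], 4L)
  # fewer members than n_top: no padding
  expect_lte(nrow(out[[2]]$exemplars), 2)
})

test_that("characterization is invariant to article order up to tie rules", {
  rc <- random_corpus(30, n_terms = 12, seed = 23)
  labels <- rep(1:3, each = 10)
  a <- characterize_clusters(labels, rc$corpus, rc$vocab, n_top = 5)
  perm <- sample(30)
  shuffled <- corpus_subset(rc$corpus, rc$corpus$article_ids[perm])
  b <- characterize_clusters(labels[perm], shuffled, rc$vocab, n_top = 5)
  for (cl in 1:3) {
    expect_equal(a[[cl]]$top_terms, b[[cl]]$top_terms)
    expect_equal(a[[cl]]$exemplars, b[[cl]]$exemplars)
  }
})

test_that("normal ellipse has chi-square scale, equivariance, and degeneracy guard", {
  set.seed(19)
  pts <- matrix(rnorm(4000), , 2)
  e <- normal_ellipse(pts, level = 0.95)
  expect_equal(e$scale^2, stats::qchisq(0.95, 2))
  expect_equal(e$scale^2, 5.99, tolerance = 0.01)
  expect_equal(unname(e$cov), diag(2), tolerance = 0.15)

  shifted <- sweep(pts, 2, c(100, -50), `+`)
  e2 <- normal_ellipse(shifted)
  expect_equal(e2$cov, e$cov)
  expect_equal(unname(e2$mean), unname(e$mean) + c(100, -50))

  tiny <- normal_ellipse(pts, level = 1e-9)
  expect_lt(tiny$scale, 1e-3)

  line <- cbind(1:10, 2 * (1:10))
  expect_error(normal_ellipse(line, name = "cluster 3"), "cluster 3")
})

test_that("overlap report: identity pairs are exact, disjoint sets score zero", {
  rc <- random_corpus(60, n_terms = 15, seed = 29)
  cb <- som_train(rc$corpus, som_grid(6),
                  som_schedule(epochs = 3, sigma0 = 3, seed = 29))
  model <- cluster_projection(rc$corpus, cb, rc$vocab, force_k = 2,
                              k_max = 3, restarts = 5, seed = 29)
  rep2 <- overlap_report(list(e1 = model, e2 = model))
  self <- rep2[rep2$edition_a == "e1" & rep2$edition_b == "e1", ]
  expect_true(all(self$centroid_dist[!is.na(self$centroid_dist)] == 0))
  expect_true(all(self$jaccard[!is.na(self$jaccard)] == 1))

  # hand-built models with disjoint occupied node sets
  mk <- function(nodes, centers) {
    list(centers = centers,
         labels = rep(1L, length(nodes)),
         projection = list(articles = data.frame(bmu_index = nodes)))
  }
  m1 <- mk(c(1, 2), matrix(c(1, 1), 1)); m2 <- mk(c(8, 9), matrix(c(3, 3), 1))
  ov <- overlap_report(list(a = m1, b = m2))
  ab <- ov[ov$edition_a == "a" & ov$edition_b == "b", ]
  expect_equal(ab$jaccard, 0)
  expect_equal(ab$centroid_dist, sqrt(8))
})
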