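# Shared fixture builders; everything is generated in code, no files.

tiny_vocab <- function(n = 6, domain_prefixes = "F") {
  terms <- data.frame(
    term_id = paste0("T", seq_len(n)),
    label = paste("Term", letters[seq_len(n)]),
    tree_paths = c("F01.100", "A01.200", "B02.300;F02.900",
                   "C03.400", "D04.500", "E05.600")[seq_len(n)],
    stringsAsFactors = FALSE
  )
  new_vocabulary(terms, domain_prefixes = domain_prefixes)
}

tiny_records <- function() {
  list(
    list(article_id = "a1", term_ids = c("T1", "T2")),
    list(article_id = "a2", term_ids = c("T2", "T3", "T4")),
    list(article_id = "a3", term_ids = "T5")
  )
}

# random corpus over a fresh synthetic vocabulary; returns list(vocab, corpus)
random_corpus <- function(n_articles, n_terms = 30, seed = 1,
                          max_terms_per_article = 6) {
  vocab <- make_vocabulary(n_terms, max(1, n_terms %/% 5), seed = seed)
  set.seed(seed + 1000)
  records <- lapply(seq_len(n_articles), function(i) {
    k <- sample.int(max_terms_per_article, 1)
    list(article_id = sprintf("r%04d", i),
         term_ids = sample(vocab$terms$term_id, k))
  })
  list(vocab = vocab, corpus = vectorize_corpus(records, vocab))
}

# dense brute-force BMU oracle: straight double loop over nodes
brute_bmu <- function(x, W) {
  d2 <- apply(W, 1, function(w) sum((x - w)^2))
  b1 <- which.min(d2)
  d2b <- d2
  d2b[b1] <- Inf
  b2 <- which.min(d2b)
  list(b1 = b1, b2 = b2, d1 = d2[b1], d2 = d2[b2])
}

# naive batch-SOM epoch oracle: explicit per-article, per-node loops
naive_epoch <- function(W, X, grid, sigma, eps = 1e-12) {
  M <- nrow(W)
  S <- matrix(0, M, ncol(W))
  Z <- numeric(M)
  for (i in seq_len(nrow(X))) {
    x <- as.numeric(X[i, ])
    b <- brute_bmu(x, W)$b1
    for (j in seq_len(M)) {
      dg2 <- sum((grid$coords[b, ] - grid$coords[j, ])^2)
      h <- exp(-dg2 / (2 * sigma^2))
      S[j, ] <- S[j, ] + h * x
      Z[j] <- Z[j] + h
    }
  }
  Wn <- W
  for (j in seq_len(M)) if (Z[j] > eps) Wn[j, ] <- S[j, ] / Z[j]
  Wn
}

# exhaustive k-means optimum: best WSS over all k^n assignments with
# centers at part centroids
exhaustive_kmeans_wss <- function(pts, k) {
  n <- nrow(pts)
  stopifnot(k^n <= 1e6)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    wss <- 0
    for (j in seq_len(k)) {
      sub <- pts[lab == j, , drop = FALSE]
      ctr <- colMeans(sub)
      wss <- wss + sum(sweep(sub, 2, ctr)^2)
    }
    if (wss < best) best <- wss
  }
  best
}
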