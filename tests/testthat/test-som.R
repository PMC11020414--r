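test_that("grid geometry and linear indexing are consistent", {
  g <- som_grid(3, 4)
  expect_equal(g$M, 12)
  expect_equal(g$coords[1, ], c(row = 1, col = 1))
  expect_equal(g$coords[(2 - 1) * 4 + 3, ], c(row = 2, col = 3))
  expect_equal(nrow(g$coords), 12)
})

test_that("sigma schedule follows the geometric decay and its unit crossing", {
  sch <- som_schedule(epochs = 20, sigma0 = 175, decay_base = 1.7)
  s <- sigma_at(sch)
  expect_equal(s[1], 175 / 1.7)
  expect_equal(s[20], 175 / 1.7^20)
  expect_true(all(diff(s) < 0))
  crossing <- which(s < 1)[1]          # computed, not hard-coded
  expect_equal(crossing, which(175 / 1.7^(1:20) < 1)[1])
  expect_lte(crossing, 12)
})

test_that("codebook initialization is seeded, article-based, and deterministic", {
  rc <- random_corpus(50, seed = 3)
  g <- som_grid(5)
  sch <- som_schedule(epochs = 2, sigma0 = 2.5, seed = 11)
  cb1 <- init_codebook(rc$corpus, g, sch)
  cb2 <- init_codebook(rc$corpus, g, sch)
  expect_identical(cb1$W, cb2$W)
  expect_true(all(cb1$W >= 0 & cb1$W <= 1))

  # one-article corpus without jitter: every node is that article
  one <- vectorize_corpus(list(list(article_id = "a", term_ids = "T00001")),
                          rc$vocab)
  cb <- init_codebook(one, g, sch, jitter = 0)
  expect_true(all(apply(cb$W, 1, function(w)
    identical(w, as.numeric(one$matrix[1, ])))))

  # sampled indices match an independent seeded sampler trace
  idx_oracle <- with(list(), {
    set.seed(11); sample.int(50, 25, replace = TRUE)
  })
  cb0 <- init_codebook(rc$corpus, g, sch, jitter = 0)
  expect_identical(cb0$W, unname(as.matrix(rc$corpus$matrix[idx_oracle, ])))

  empty <- vectorize_corpus(list(), rc$vocab)
  expect_error(init_codebook(empty, g, sch), "empty corpus")
})

test_that("sparse BMU search equals dense brute force, including ties", {
  set.seed(42)
  for (rep in 1:20) {
    M <- sample(4:50, 1); D <- sample(5:20, 1)
    W <- matrix(runif(M * D), M, D)
    g <- som_grid(ceiling(sqrt(M)), ceiling(M / ceiling(sqrt(M))))
    g$M <- M; g$coords <- g$coords[1:M, , drop = FALSE]
    cb <- structure(list(W = W, grid = g, provenance = list()),
                    class = "som_codebook")
    x <- as.numeric(runif(D) < 0.3)
    got <- find_bmu(x, cb)
    want <- brute_bmu(x, W)
    expect_equal(got$first, want$b1)
    expect_equal(got$second, want$b2)
    expect_equal(got$first_dist2, want$d1, tolerance = 1e-9)
    expect_equal(got$second_dist2, want$d2, tolerance = 1e-9)
  }

  # exact hit and tie rules
  W <- rbind(c(1, 0), c(1, 0), c(0, 1))
  cb <- structure(list(W = W, grid = som_grid(1, 3), provenance = list()),
                  class = "som_codebook")
  hit <- find_bmu(c(1, 0), cb)
  expect_equal(hit$first, 1)            # tie with node 2 -> lowest index
  expect_equal(hit$second, 2)
  expect_equal(hit$first_dist2, 0)

  Wsame <- matrix(0.5, 4, 3)
  cbs <- structure(list(W = Wsame, grid = som_grid(2, 2), provenance = list()),
                   class = "som_codebook")
  tie <- find_bmu(c(1, 0, 0), cbs)
  expect_equal(tie$first, 1)
  expect_equal(tie$second, 2)

  expect_error(find_bmu(c(1, 0), cbs), "dimension mismatch")
})

test_that("batch epoch matches the naive per-article oracle", {
  rc <- random_corpus(12, n_terms = 8, seed = 5)
  g <- som_grid(2, 3)
  sch <- som_schedule(epochs = 1, sigma0 = 1.4, seed = 2)
  cb <- init_codebook(rc$corpus, g, sch)
  upd <- batch_epoch(cb, rc$corpus, sigma_e = 1.4)
  expect_equal(upd$W, naive_epoch(cb$W, as.matrix(rc$corpus$matrix), g, 1.4),
               tolerance = 1e-12)
})

test_that("batch epoch limits: huge sigma averages, tiny sigma moves only BMUs", {
  vocab <- tiny_vocab()
  one <- vectorize_corpus(list(list(article_id = "a", term_ids = c("T1", "T4"))),
                          vocab)
  g <- som_grid(3)
  sch <- som_schedule(epochs = 1, sigma0 = 1, seed = 1)
  cb <- init_codebook(one, g, sch, jitter = 1e-3)
  up <- batch_epoch(cb, one, sigma_e = 1e6)
  x <- as.numeric(one$matrix[1, ])
  expect_true(max(abs(sweep(up$W, 2, x))) < 1e-6)

  # sigma -> 0+: only the BMU node moves (h ~ indicator)
  rc <- random_corpus(5, n_terms = 10, seed = 9)
  cb2 <- init_codebook(rc$corpus, som_grid(4), som_schedule(1, 2, seed = 3))
  b1 <- vapply(seq_len(rc$corpus$N), function(i)
    find_bmu(rc$corpus$matrix[i, ], cb2)$first, integer(1))
  up2 <- batch_epoch(cb2, rc$corpus, sigma_e = 1e-4)
  untouched <- setdiff(seq_len(16), b1)
  expect_identical(up2$W[untouched, ], cb2$W[untouched, ])
})

test_that("weights stay in [0,1] and epochs are article-order invariant", {
  rc <- random_corpus(60, n_terms = 20, seed = 8)
  g <- som_grid(6)
  sch <- som_schedule(epochs = 3, sigma0 = 3, seed = 4)
  cb <- init_codebook(rc$corpus, g, sch)
  for (sigma in c(3, 1.5, 0.5)) {
    cb <- batch_epoch(cb, rc$corpus, sigma)
    expect_true(all(cb$W >= 0 & cb$W <= 1))
  }
  # permute article order; the batch update must not change
  cb0 <- init_codebook(rc$corpus, g, sch)
  perm <- sample(rc$corpus$N)
  shuffled <- corpus_subset(rc$corpus, rc$corpus$article_ids[perm])
  a <- batch_epoch(cb0, rc$corpus, 1.2)
  b <- batch_epoch(cb0, shuffled, 1.2)
  expect_equal(a$W, b$W, tolerance = 1e-12)
})

test_that("topographic error matches a brute-force recount and its extremes", {
  # construct a codebook where every article's two best nodes are adjacent
  g <- som_grid(2, 2)
  W <- rbind(c(1, 0, 0), c(0.9, 0.1, 0), c(0, 1, 0), c(0, 0, 1))
  cb <- structure(list(W = W, grid = g, provenance = list()),
                  class = "som_codebook")
  vocab <- tiny_vocab(3)
  adj <- vectorize_corpus(list(list(article_id = "a", term_ids = "T1")), vocab)
  expect_equal(topographic_error(cb, adj), 0)       # nodes 1,2 adjacent

  # opposite corners on a 3x3: b1 = node 1, b2 = node 9
  g3 <- som_grid(3)
  W3 <- matrix(0.5, 9, 3)
  W3[1, ] <- c(1, 0, 0); W3[9, ] <- c(0.9, 0.1, 0)
  cb3 <- structure(list(W = W3, grid = g3, provenance = list()),
                   class = "som_codebook")
  expect_equal(topographic_error(cb3, adj), 1)

  # mixed random fixture vs independent recount
  rc <- random_corpus(30, n_terms = 12, seed = 6)
  cb4 <- init_codebook(rc$corpus, som_grid(4),
                       som_schedule(1, 2, seed = 5))
  got <- topographic_error(cb4, rc$corpus)
  X <- as.matrix(rc$corpus$matrix)
  bad <- 0
  for (i in seq_len(nrow(X))) {
    o <- brute_bmu(X[i, ], cb4$W)
    c1 <- cb4$grid$coords[o$b1, ]; c2 <- cb4$grid$coords[o$b2, ]
    if (max(abs(c1 - c2)) > 1) bad <- bad + 1
  }
  expect_equal(got, bad / nrow(X))
  expect_gte(got, 0); expect_lte(got, 1)
})

test_that("training selects the minimum-TE epoch and is bit-reproducible", {
  rc <- random_corpus(80, n_terms = 25, seed = 10)
  g <- som_grid(6)
  sch <- som_schedule(epochs = 5, sigma0 = 3, decay_base = 1.7, seed = 12)
  cb1 <- som_train(rc$corpus, g, sch)
  cb2 <- som_train(rc$corpus, g, sch)
  expect_identical(cb1$W, cb2$W)
  expect_length(cb1$te_history, 5)
  expect_equal(cb1$epoch_of_origin, which.min(cb1$te_history))

  sch1 <- som_schedule(epochs = 1, sigma0 = 3, seed = 12)
  one <- som_train(rc$corpus, g, sch1)
  expect_equal(one$epoch_of_origin, 1L)
  expect_length(one$te_history, 1)
})

test_that("planted topics end up closer within than between on the map", {
  vocab <- make_vocabulary(100, 20, seed = 21)
  topics <- make_topics(vocab, 4, seed = 21)
  sim <- make_corpus(vocab, topics, 400, seed = 21)
  cb <- som_train(sim$corpus, som_grid(10),
                  som_schedule(epochs = 10, sigma0 = 5, seed = 21))
  expect_lte(min(cb$te_history), cb$te_history[1] + 1e-12)
  proj <- project_corpus(sim$corpus, cb)
  pts <- cbind(proj$articles$row, proj$articles$col)
  lab <- sim$truth$topic
  dmat <- as.matrix(dist(pts))
  same <- outer(lab, lab, `==`) & upper.tri(dmat)
  diff_ <- outer(lab, lab, `!=`) & upper.tri(dmat)
  expect_lt(mean(dmat[same]), mean(dmat[diff_]))
})

test_that("node classification compares domain and non-domain weight means", {
  vocab <- tiny_vocab()          # T1, T3 are domain
  dom_cols <- which(vocab$terms$is_domain)
  W <- rbind(
    c(1, 0, 0, 0, 0, 0),         # weight on domain col only -> positive
    rep(0.5, 6),                 # uniform -> strict inequality fails
    c(0, 1, 0, 1, 1, 0)          # non-domain heavy -> negative
  )
  cb <- structure(list(W = W, grid = som_grid(1, 3),
                       provenance = list(vocab_digest = NULL)),
                  class = "som_codebook")
  expect_equal(classify_nodes(cb, vocab), c(TRUE, FALSE, FALSE))

  # random fixture vs hand-computed mean comparison
  set.seed(31)
  W5 <- matrix(runif(30), 5, 6)
  cb5 <- structure(list(W = W5, grid = som_grid(1, 5),
                        provenance = list(vocab_digest = NULL)),
                   class = "som_codebook")
  want <- rowMeans(W5[, dom_cols]) > rowMeans(W5[, -dom_cols])
  expect_equal(classify_nodes(cb5, vocab), want)

  nodom <- tiny_vocab(domain_prefixes = character())
  expect_error(classify_nodes(cb, nodom), "no domain terms")
})

test_that("codebook container round-trips bitwise and rejects corruption", {
  rc <- random_corpus(30, n_terms = 10, seed = 14)
  g <- som_grid(4)
  sch <- som_schedule(epochs = 2, sigma0 = 2, seed = 7)
  cb <- som_train(rc$corpus, g, sch)
  path <- withr::local_tempfile(fileext = ".medsom")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_identical(back$W, cb$W)
  expect_equal(back$te_history, cb$te_history)
  expect_equal(back$epoch_of_origin, cb$epoch_of_origin)
  expect_equal(back$grid$M, cb$grid$M)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_codebook_tsv(cb, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), cb$grid$M)

  # truncation is a format error, not silent garbage
  lines <- readLines(path)
  writeLines(lines[1:(length(lines) - 2)], path)
  expect_error(read_codebook(path), "corrupt|expected")

  writeLines("not a codebook", path)
  expect_error(read_codebook(path), "not a medsom codebook")

  # digest mismatch between codebook and another vocabulary warns
  path2 <- withr::local_tempfile(fileext = ".medsom")
  write_codebook(cb, path2)
  other <- make_vocabulary(10, 2, seed = 99)
  expect_warning(read_codebook(path2, other), "digest mismatch")
})
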