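#' Generate a synthetic hierarchical vocabulary
#'
#' Builds an ordered vocabulary of `n_terms` terms with dot-path tree
#' numbers emulating a controlled-vocabulary hierarchy.  Exactly `n_domain`
#' terms are placed under the domain subtree (prefix `"F"` by default,
#' mirroring a "Psychiatry and Psychology"-style top-level category); the
#' rest are spread over non-domain top-level letters.  Deterministic per
#' seed.
#'
#' @param n_terms total number of terms.
#' @param n_domain number of in-domain terms, `<= n_terms`.
#' @param seed integer seed.
#' @param domain_prefix top-level tree letter of the domain subtree.
#' @return a `medsom_vocabulary` with `is_domain` true for exactly
#'   `n_domain` terms.
#' @export
make_vocabulary <- function(n_terms, n_domain, seed = 1L, domain_prefix = "F") {
  stopifnot(n_domain >= 0, n_domain <= n_terms)
  with_seed(seed, {
    others <- setdiff(LETTERS[1:8], domain_prefix)
    if (n_domain > 0) {
      dom_slots <- sort(sample.int(n_terms, n_domain))
      top <- character(n_terms)
      top[dom_slots] <- domain_prefix
      top[setdiff(seq_len(n_terms), dom_slots)] <-
        sample(others, n_terms - n_domain, replace = TRUE)
    } else {
      top <- sample(others, n_terms, replace = TRUE)
    }
    mid <- sample.int(20, n_terms, replace = TRUE)
    leaf <- sample.int(900, n_terms, replace = TRUE) + 99
    terms <- data.frame(
      term_id = sprintf("T%05d", seq_len(n_terms)),
      label = sprintf("Term %05d", seq_len(n_terms)),
      tree_paths = sprintf("%s%02d.%d", top, mid, leaf),
      stringsAsFactors = FALSE
    )
    new_vocabulary(terms, domain_prefixes = domain_prefix)
  })
}

#' Topic specifications for planted-topic corpora
#'
#' Carves `n_topics` pairwise-disjoint signature term sets out of a
#' vocabulary.  Articles of a topic draw each annotation from the topic's
#' signature with probability `signature_prob`, otherwise uniformly from
#' the whole vocabulary (background).
#'
#' @param vocab a `medsom_vocabulary`.
#' @param n_topics number of planted topics.
#' @param signature_size terms per topic signature; the default (6) is below
#'   the mean annotation count (9), so a typical article expresses its whole
#'   topic signature and topics are well separated in input space.
#' @param signature_prob probability in (0, 1] that an annotation comes
#'   from the signature (default 0.9).
#' @param seed integer seed.
#' @return list of topic specs (`topic_id`, `signature` term indices,
#'   `signature_prob`).
#' @export
make_topics <- function(vocab, n_topics, signature_size = 6,
                        signature_prob = 0.9, seed = 1L) {
  stopifnot(signature_prob > 0, signature_prob <= 1,
            n_topics * signature_size <= vocab$D)
  with_seed(seed, {
    pool <- sample.int(vocab$D, n_topics * signature_size)
    lapply(seq_len(n_topics), function(g) {
      list(topic_id = g,
           signature = sort(pool[((g - 1) * signature_size + 1):(g * signature_size)]),
           signature_prob = signature_prob)
    })
  })
}

#' Generate a planted-topic annotated corpus
#'
#' Each article draws a topic uniformly, an annotation count from a
#' Poisson(`mean_annotations`) truncated at 1 (the literature-scale default
#' is 9 annotations per article), and each annotation from the topic
#' signature with probability `signature_prob`, else uniformly from the
#' vocabulary; duplicate draws collapse, so realized counts can fall
#' slightly below the draw.  Ground-truth topic labels are returned.
#'
#' @param vocab a `medsom_vocabulary`.
#' @param topics topic specs from [make_topics()].
#' @param n_articles number of articles.
#' @param mean_annotations Poisson mean (default 9).
#' @param seed integer seed.
#' @return list with `corpus` (a `medsom_corpus`) and `truth` (list:
#'   `topic` integer labels aligned with the corpus, `params`, `seed`).
#' @export
make_corpus <- function(vocab, topics, n_articles, mean_annotations = 9,
                        seed = 1L) {
  stopifnot(mean_annotations >= 1, n_articles >= 1)
  with_seed(seed, {
    g <- sample.int(length(topics), n_articles, replace = TRUE)
    counts <- pmax(1L, stats::rpois(n_articles, mean_annotations))
    records <- vector("list", n_articles)
    for (i in seq_len(n_articles)) {
      tp <- topics[[g[i]]]
      from_sig <- stats::runif(counts[i]) < tp$signature_prob
      cols <- integer(counts[i])
      if (any(from_sig)) {
        cols[from_sig] <- sample(tp$signature, sum(from_sig), replace = TRUE)
      }
      if (any(!from_sig)) {
        cols[!from_sig] <- sample.int(vocab$D, sum(!from_sig), replace = TRUE)
      }
      records[[i]] <- list(article_id = sprintf("A%06d", i),
                           term_ids = vocab$terms$term_id[unique(cols)])
    }
    corpus <- vectorize_corpus(records, vocab, strict = TRUE)
    list(corpus = corpus,
         truth = list(topic = g,
                      params = list(n_articles = n_articles,
                                    mean_annotations = mean_annotations,
                                    n_topics = length(topics),
                                    signature_prob = topics[[1]]$signature_prob),
                      seed = seed))
  })
}

#' Generate multi-edition reference id sets with planted persistence
#'
#' Edition 1 is a uniform sample of `sizes[1]` corpus article ids.  Each
#' later edition keeps every id of its predecessor independently with
#' probability `persistence_rate`, then fills up to its size with fresh ids
#' drawn from the corpus *excluding the previous edition*, so the measured
#' persistence of edition e (`100 * |e & e-1| / |e|`) is a pure binomial
#' draw at the planted rate.
#'
#' @param corpus a `medsom_corpus` (or character vector of ids).
#' @param n_editions number of editions.
#' @param sizes edition sizes (recycled to length `n_editions`).
#' @param persistence_rate probability in [0, 1] a citation persists.
#' @param seed integer seed.
#' @return list with `editions` (list of id vectors) and `truth` (planted
#'   rate, sizes, seed).
#' @export
make_editions <- function(corpus, n_editions, sizes, persistence_rate,
                          seed = 1L) {
  stopifnot(persistence_rate >= 0, persistence_rate <= 1, n_editions >= 1)
  ids <- if (inherits(corpus, "medsom_corpus")) corpus$article_ids else as.character(corpus)
  sizes <- rep_len(sizes, n_editions)
  if (any(sizes > length(ids))) {
    stopf("requested edition size %d exceeds corpus size %d",
          max(sizes), length(ids))
  }
  with_seed(seed, {
    editions <- vector("list", n_editions)
    editions[[1]] <- sample(ids, sizes[1])
    if (n_editions > 1) {
      for (e in 2:n_editions) {
        prev <- editions[[e - 1]]
        kept <- prev[stats::runif(length(prev)) < persistence_rate]
        if (length(kept) > sizes[e]) kept <- kept[seq_len(sizes[e])]
        pool <- setdiff(ids, prev)
        need <- sizes[e] - length(kept)
        if (need > length(pool)) {
          stopf("corpus too small to fill edition %d with fresh ids", e)
        }
        editions[[e]] <- c(kept, sample(pool, need))
      }
    }
    list(editions = editions,
         truth = list(persistence_rate = persistence_rate, sizes = sizes,
                      seed = seed))
  })
}

#' Synthesize verbatim reference strings from bibliographic records
#'
#' Emits `"<first_author>. <title>. <journal>. <year>"` per record — the
#' format [parse_reference()] parses exactly, so matching these against
#' their own record set succeeds at 100% with default thresholds.
#'
#' @param records bibliographic record list (see [read_bib_records()]).
#' @param edition_id edition label for the emitted references.
#' @return list of parsed references.
#' @export
synthesize_references <- function(records, edition_id = "1") {
  lapply(records, function(r) {
    raw <- sprintf("%s. %s. %s. 2000",
                   r$first_author_raw %||% r$first_author_surname,
                   r$title_raw %||% r$title, r$journal_raw %||% r$journal)
    parse_reference(raw, edition_id = edition_id)
  })
}

#' Generate a synthetic bibliographic record set
#'
#' Records with pronounceable surnames, distinct titles and a small journal
#' pool, each annotated with terms from `vocab`; used to exercise reference
#' matching end to end.
#'
#' @param vocab a `medsom_vocabulary`.
#' @param n number of records.
#' @param seed integer seed.
#' @return bibliographic record list (see [read_bib_records()]).
#' @export
make_bib_records <- function(vocab, n, seed = 1L) {
  with_seed(seed, {
    surnames <- c("Smith", "Jones", "Nguyen", "Garcia", "Okafor", "Ivanov",
                  "Tanaka", "Muller", "Rossi", "Chen")
    journals <- c("J Clin Invest", "Arch Gen Psychiatry", "Am J Psychiatry",
                  "Lancet", "Br J Psychiatry")
    adjectives <- c("randomized", "longitudinal", "retrospective", "blinded",
                    "population-based", "cross-sectional", "qualitative")
    subjects <- c("sleep architecture", "dopamine signalling", "grief reactions",
                  "memory consolidation", "treatment adherence", "social cognition",
                  "cortical thinning", "relapse prevention", "stigma", "comorbidity")
    groups <- c("adolescents", "older adults", "outpatients", "twins",
                "first-episode patients", "caregivers", "veterans")
    lapply(seq_len(n), function(i) {
      nterms <- max(1L, stats::rpois(1, 9))
      # word choices are a function of the index so records sharing a surname
      # (index step 10) differ in at least two content words, keeping
      # normalized-title similarity safely below the match threshold
      title <- sprintf("A %s study of %s in %s (%d)",
                       adjectives[i %% 7 + 1],
                       subjects[(i + i %/% 10) %% 10 + 1],
                       groups[(i * 2 + i %/% 10) %% 7 + 1], i)
      list(
        article_id = sprintf("P%06d", i),
        first_author_surname = tolower(surnames[(i - 1) %% length(surnames) + 1]),
        title = normalize_field(title),
        journal = normalize_field(journals[(i - 1) %% length(journals) + 1]),
        first_author_raw = paste(surnames[(i - 1) %% length(surnames) + 1], "J"),
        title_raw = title,
        journal_raw = journals[(i - 1) %% length(journals) + 1],
        term_ids = sample(vocab$terms$term_id, min(nterms, vocab$D))
      )
    })
  })
}
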