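PLANT_TARGETS <- c("abstract_only", "fulltext", "article", "intro_section",
                   "methods_section", "results_section", "review_pair",
                   "review_vs_research")

#' Specification of a set of planted duplicate pairs
#'
#' Each plant takes a source article B and a copier article A (assigned by
#' the generator from different topics) and copies a fraction `f` of B's
#' tokens into the corresponding unit(s) of A, token-prefix-wise, resampling
#' the remainder from A's own topic vocabulary — so the achieved overlap
#' equals `f` up to rounding and `f = 1` makes the copied units identical.
#' Targets:
#' \describe{
#'   \item{abstract_only}{abstract copied; body untouched.}
#'   \item{fulltext}{all body sections copied; abstract untouched (full-text
#'     similarity without abstract similarity).}
#'   \item{article}{abstract and body copied (a whole-article duplicate:
#'     both abstract and full-text similarity).}
#'   \item{intro_section, methods_section, results_section}{one section's
#'     paragraphs copied.}
#'   \item{review_pair}{body copied; both articles flagged review.}
#'   \item{review_vs_research}{results-section paragraphs of a research
#'     article copied into a review.}
#' }
#'
#' @param n_pairs Number of pairs to plant.
#' @param target One of the targets above.
#' @param copy_fraction Copy fraction `f` in `[0, 1]`.
#' @param author_overlap `"shared"` (exactly one common author) or
#'   `"disjoint"` (none).
#' @param same_journal,same_year Force the pair's journal/year equal (TRUE)
#'   or different (FALSE).
#' @return A list of class `"dc_plant"`.
#' @export
plant_spec <- function(n_pairs, target, copy_fraction = 1,
                       author_overlap = c("disjoint", "shared"),
                       same_journal = FALSE, same_year = FALSE) {
  target <- match.arg(target, PLANT_TARGETS)
  author_overlap <- match.arg(author_overlap)
  stopifnot(n_pairs >= 1, copy_fraction >= 0, copy_fraction <= 1)
  structure(list(n_pairs = as.integer(n_pairs), target = target,
                 copy_fraction = copy_fraction, author_overlap = author_overlap,
                 same_journal = isTRUE(same_journal),
                 same_year = isTRUE(same_year)),
            class = "dc_plant")
}

#' Synthetic corpus generator configuration
#'
#' Defaults describe a desk-scale corpus with the structural features the
#' census assumes: IMRaD-sectioned articles over topic-disjoint vocabularies
#' (so background cross-topic similarity is near zero), abstract-sized
#' paragraphs, author lists drawn from a pool, a handful of journals and
#' years, and a review share matching a large open-access full-text archive
#' (5,414 / 72,011). The per-topic vocabulary (20,000 terms, Zipf exponent
#' 0.6) is much larger than a document, as in natural language, so unrelated
#' same-topic articles overlap only through high-frequency terms and their
#' full-text similarity ratio stays well below the 0.5 operating point
#' (median near 0.12 at the defaults).
#'
#' @param n_articles Number of articles.
#' @param n_topics Number of disjoint topic vocabularies (>= 2 so planted
#'   pairs can span topics).
#' @param vocab_size Terms per topic vocabulary.
#' @param zipf_exponent Exponent of the within-topic Zipf term distribution.
#' @param paragraphs_per_section Mean paragraphs per section (Poisson,
#'   minimum 1).
#' @param words_per_paragraph Mean words per paragraph (normal, sd = mean/5,
#'   minimum 20) — abstract-sized, the scale the ratio is calibrated for.
#' @param abstract_words Mean abstract length in words.
#' @param review_fraction Fraction of articles flagged review.
#' @param n_journals Journal pool size.
#' @param years Candidate publication years.
#' @param authors_range Min/max authors per article.
#' @param author_pool_size Size of the synthetic author pool; default
#'   `3 * n_articles`.
#' @param plants List of [plant_spec()] objects (the duplication plan).
#' @param seed Integer RNG seed; identical config + seed gives a
#'   byte-identical corpus and ledger.
#' @return A list of class `"dc_generator_config"`.
#' @export
generator_config <- function(n_articles = 200, n_topics = 10,
                             vocab_size = 20000, zipf_exponent = 0.6,
                             paragraphs_per_section = 3,
                             words_per_paragraph = 120, abstract_words = 150,
                             review_fraction = 5414 / 72011, n_journals = 25,
                             years = 2000:2009, authors_range = c(2L, 6L),
                             author_pool_size = NULL, plants = list(),
                             seed = 1L) {
  stopifnot(n_articles >= 1, n_topics >= 2, vocab_size >= 10,
            paragraphs_per_section >= 1, words_per_paragraph >= 20,
            abstract_words >= 20, review_fraction >= 0, review_fraction <= 1,
            n_journals >= 2, length(years) >= 1,
            length(authors_range) == 2, authors_range[1] >= 1)
  for (p in plants) stopifnot(inherits(p, "dc_plant"))
  n_planted <- 2L * sum(vapply(plants, `[[`, integer(1), "n_pairs"))
  if (n_planted > n_articles)
    stop("infeasible duplication plan: ", n_planted,
         " planted articles exceed n_articles = ", n_articles)
  structure(list(
    n_articles = as.integer(n_articles), n_topics = as.integer(n_topics),
    vocab_size = as.integer(vocab_size), zipf_exponent = zipf_exponent,
    paragraphs_per_section = paragraphs_per_section,
    words_per_paragraph = words_per_paragraph, abstract_words = abstract_words,
    review_fraction = review_fraction, n_journals = as.integer(n_journals),
    years = as.integer(years), authors_range = as.integer(authors_range),
    author_pool_size = as.integer(author_pool_size %||% (3L * n_articles)),
    plants = plants, seed = as.integer(seed)
  ), class = "dc_generator_config")
}

#' Generate a synthetic corpus with planted duplicates
#'
#' Produces a corpus of structured articles plus a ground-truth ledger of
#' every planted pair. Background articles draw tokens from their topic's
#' Zipf-distributed vocabulary; distinct topics share no terms, so unplanted
#' cross-topic similarity is near zero. Plants are applied after background
#' generation by overwriting the copier's target units (see [plant_spec()]).
#' The ledger's achieved copy fraction is recounted from the emitted tokens
#' and validated against the requested fraction on write.
#'
#' @param config A [generator_config()].
#' @return A list of class `"dc_synthetic"`: `corpus` (list of [article()])
#'   and `ledger` (list with `plants` and `units` data frames, and the
#'   config).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "dc_generator_config"))
  set.seed(config$seed)
  V <- config$vocab_size
  vocab <- lapply(seq_len(config$n_topics), function(k)
    sprintf("t%02dw%04d", k, seq_len(V)))
  zipf <- (1 / seq_len(V)^config$zipf_exponent)
  zipf <- zipf / sum(zipf)

  n <- config$n_articles
  ids <- sprintf("SYN%05d", seq_len(n))
  topic <- sample.int(config$n_topics, n, replace = TRUE)
  is_review <- runif(n) < config$review_fraction
  journal <- sprintf("Journal%02d", sample.int(config$n_journals, n, replace = TRUE))
  year <- sample(config$years, n, replace = TRUE)

  pool_init <- sample(LETTERS, config$author_pool_size, replace = TRUE)
  pool <- sprintf("Author%04d, %s.", seq_len(config$author_pool_size), pool_init)
  n_auth <- sample(seq(config$authors_range[1], config$authors_range[2]),
                   n, replace = TRUE)
  authors <- lapply(seq_len(n), function(i)
    pool[sample.int(config$author_pool_size, n_auth[i])])

  zipf_cum <- cumsum(zipf)
  draw <- function(k, tp)
    vocab[[tp]][findInterval(runif(k), zipf_cum, rightmost.closed = TRUE) + 1L]
  n_words <- function(mean_w)
    max(20L, as.integer(round(rnorm(1, mean_w, mean_w / 5))))
  gen_paragraph <- function(tp, mean_w) paste(draw(n_words(mean_w), tp),
                                              collapse = " ")

  # assign plant slots up front so a copier's whole background is generated
  # from a topic disjoint from its source's
  total_pairs <- sum(vapply(config$plants, `[[`, integer(1), "n_pairs"))
  assign_rows <- list()
  if (total_pairs > 0) {
    slots <- sample.int(n, 2L * total_pairs)
    si <- 0L
    for (pi in seq_along(config$plants)) {
      p <- config$plants[[pi]]
      for (r in seq_len(p$n_pairs)) {
        ia <- slots[si + 1L]; ib <- slots[si + 2L]; si <- si + 2L
        if (topic[ia] == topic[ib])
          topic[ia] <- if (topic[ib] < config$n_topics) topic[ib] + 1L else 1L
        pt <- switch(p$target,
                     review_pair = c("review", "review"),
                     review_vs_research = c("review", "research"),
                     c("research", "research"))
        is_review[ia] <- pt[1L] == "review"
        is_review[ib] <- pt[2L] == "review"
        assign_rows[[length(assign_rows) + 1L]] <-
          list(plant = pi, ia = ia, ib = ib)
      }
    }
  }

  sec_titles <- c(INTRODUCTION = "Introduction", METHODS = "Methods",
                  RESULTS_DISCUSSION = "Results and Discussion")
  articles <- vector("list", n)
  for (i in seq_len(n)) {
    secs <- lapply(names(sec_titles), function(cl) {
      np <- max(1L, rpois(1, config$paragraphs_per_section))
      section(sec_titles[[cl]],
              vapply(seq_len(np), function(.)
                gen_paragraph(topic[i], config$words_per_paragraph),
                character(1)),
              section_class = cl)
    })
    articles[[i]] <- article(
      ids[i], title = paste(draw(8L, topic[i]), collapse = " "),
      abstract = gen_paragraph(topic[i], config$abstract_words),
      authors = authors[[i]], journal = journal[i], year = year[i],
      pub_type = if (is_review[i]) "review" else "research", sections = secs)
  }

  # ---- plant application -------------------------------------------------
  plant_rows <- list()
  if (total_pairs > 0) {
    copy_unit <- function(src_text, f, tp) {
      src <- strsplit(src_text, " ", fixed = TRUE)[[1L]]
      k <- as.integer(round(f * length(src)))
      kept <- head(src, k)
      fresh <- if (length(src) > k) draw(length(src) - k, tp) else character(0)
      paste(c(kept, fresh), collapse = " ")
    }
    for (asg in assign_rows) {
      p <- config$plants[[asg$plant]]
      ia <- asg$ia; ib <- asg$ib
      A <- articles[[ia]]; B <- articles[[ib]]
      f <- p$copy_fraction

      copy_section <- function(A, cls) {
        bi <- which(vapply(B$sections, `[[`, character(1), "section_class") == cls)
        ai <- which(vapply(A$sections, `[[`, character(1), "section_class") == cls)
        if (length(bi) == 0L || length(ai) == 0L) return(A)
        src <- B$sections[[bi[1L]]]$paragraphs
        A$sections[[ai[1L]]]$paragraphs <-
          vapply(src, copy_unit, character(1), f = f, tp = topic[ia],
                 USE.NAMES = FALSE)
        A
      }
      if (p$target %in% c("abstract_only", "article"))
        A$abstract <- copy_unit(B$abstract, f, topic[ia])
      if (p$target %in% c("fulltext", "article", "review_pair"))
        for (cls in names(sec_titles)) A <- copy_section(A, cls)
      if (p$target == "intro_section") A <- copy_section(A, "INTRODUCTION")
      if (p$target == "methods_section") A <- copy_section(A, "METHODS")
      if (p$target %in% c("results_section", "review_vs_research"))
        A <- copy_section(A, "RESULTS_DISCUSSION")

      # author overlap: rebuild A's list so the intersection is exact
      if (p$author_overlap == "shared") {
        others <- setdiff(pool, B$authors)
        A$authors <- c(B$authors[1L],
                       sample(others, max(0L, length(A$authors) - 1L)))
      } else {
        A$authors <- sample(setdiff(pool, B$authors), length(A$authors))
      }
      if (p$same_journal) A$journal <- B$journal
      else if (A$journal == B$journal)
        A$journal <- sprintf("Journal%02d",
                             (as.integer(sub("Journal", "", B$journal)) %%
                                config$n_journals) + 1L)
      if (p$same_year) A$year <- B$year
      else if (A$year == B$year)
        A$year <- if (B$year < max(config$years)) B$year + 1L else B$year - 1L

      articles[[ia]] <- A; articles[[ib]] <- B
      plant_rows[[length(plant_rows) + 1L]] <- data.frame(
        pair_id = sprintf("PLANT%04d", length(plant_rows) + 1L),
        article_id_a = ids[ia], article_id_b = ids[ib], target = p$target,
        copy_fraction = f, author_overlap = p$author_overlap,
        same_journal = p$same_journal, same_year = p$same_year,
        stringsAsFactors = FALSE)
    }
  }
  plants <- if (length(plant_rows)) do.call(rbind, plant_rows) else
    data.frame(pair_id = character(0), article_id_a = character(0),
               article_id_b = character(0), target = character(0),
               copy_fraction = numeric(0), author_overlap = character(0),
               same_journal = logical(0), same_year = logical(0),
               stringsAsFactors = FALSE)

  units <- data.frame(
    article_id = ids,
    n_sections = vapply(articles, function(a) length(a$sections), integer(1)),
    n_paragraphs = vapply(articles, function(a)
      sum(lengths(lapply(a$sections, `[[`, "paragraphs"))), integer(1)),
    abstract_words = vapply(articles, function(a)
      length(strsplit(a$abstract, " ", fixed = TRUE)[[1L]]), integer(1)),
    pub_type = vapply(articles, `[[`, character(1), "pub_type"),
    stringsAsFactors = FALSE)

  out <- structure(list(corpus = articles,
                        ledger = list(plants = plants, units = units,
                                      config = config)),
                   class = "dc_synthetic")
  out$ledger$plants$achieved_fraction <- validate_ledger(out)
  out
}

# recount achieved copy fractions from emitted tokens; error on mismatch
validate_ledger <- function(syn) {
  plants <- syn$ledger$plants
  if (nrow(plants) == 0L) return(numeric(0))
  ids <- corpus_ids(syn$corpus)
  achieved <- numeric(nrow(plants))
  for (r in seq_len(nrow(plants))) {
    A <- syn$corpus[[match(plants$article_id_a[r], ids)]]
    B <- syn$corpus[[match(plants$article_id_b[r], ids)]]
    target <- plants$target[r]
    get_texts <- function(art) switch(
      target,
      abstract_only = art$abstract,
      article = c(art$abstract, unlist(lapply(art$sections, `[[`, "paragraphs"))),
      fulltext = , review_pair =
        unlist(lapply(art$sections, `[[`, "paragraphs")),
      intro_section = section_paras(art, "INTRODUCTION"),
      methods_section = section_paras(art, "METHODS"),
      results_section = , review_vs_research =
        section_paras(art, "RESULTS_DISCUSSION"))
    ta <- strsplit(paste(get_texts(A), collapse = " "), " ", fixed = TRUE)[[1L]]
    tb <- strsplit(paste(get_texts(B), collapse = " "), " ", fixed = TRUE)[[1L]]
    ca <- token_counts(ta); cb <- token_counts(tb)
    shared <- intersect(names(ca), names(cb))
    achieved[r] <- sum(pmin(ca[shared], cb[shared])) / max(1L, length(tb))
  }
  bad <- abs(achieved - plants$copy_fraction) > 0.05
  if (any(bad))
    stop("ledger validation failed: achieved copy fraction ",
         format(achieved[bad][1L], digits = 3), " != planted ",
         plants$copy_fraction[bad][1L])
  achieved
}

section_paras <- function(art, cls) {
  unlist(lapply(art$sections, function(s)
    if (s$section_class == cls) s$paragraphs else character(0)))
}

#' Mean similarity ratio as a function of copy fraction
#'
#' Calibration of the detector's operating point: for each copy fraction `f`
#' in the grid, plants one full-text duplicate pair per replicate corpus and
#' measures the planted pair's full-text pair ratio (max over directions).
#' The mean is monotone non-decreasing in `f` in expectation, with `f = 1`
#' giving ratio 1 exactly and `f = 0` near 0 under disjoint topics.
#'
#' @param config Base [generator_config()] (its `plants` are replaced; keep
#'   it small — calibration regenerates a corpus per replicate).
#' @param f_grid Copy fractions in `[0, 1]`.
#' @param n_reps Replicates per fraction (>= 1).
#' @return `data.frame` with `f`, `mean_ratio`, `sd_ratio`, `n_reps`.
#' @export
calibration_curve <- function(config, f_grid = c(0, 0.25, 0.5, 0.75, 1),
                              n_reps = 10) {
  stopifnot(inherits(config, "dc_generator_config"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (any(f_grid < 0 | f_grid > 1)) stop("f_grid must lie in [0, 1]")
  rows <- list()
  for (fi in seq_along(f_grid)) {
    f <- f_grid[fi]
    ratios <- vapply(seq_len(n_reps), function(r) {
      cfg <- config
      cfg$plants <- list(plant_spec(1L, "fulltext", copy_fraction = f))
      cfg$seed <- (config$seed + 7919L * r + 104729L * fi) %% .Machine$integer.max
      syn <- generate_corpus(cfg)
      planted_fulltext_ratio(syn)
    }, numeric(1))
    rows[[fi]] <- data.frame(f = f, mean_ratio = mean(ratios),
                             sd_ratio = stats::sd(ratios), n_reps = n_reps)
  }
  do.call(rbind, rows)
}

planted_fulltext_ratio <- function(syn) {
  units <- extract_units(syn$corpus, "FULLTEXT")
  w <- build_weights(units)
  pl <- syn$ledger$plants[1L, ]
  ta <- units$tokens[[match(paste0(pl$article_id_a, ":fulltext"), units$unit_id)]]
  tb <- units$tokens[[match(paste0(pl$article_id_b, ":fulltext"), units$unit_id)]]
  max(similarity_ratio(ta, tb, w)$ratio, similarity_ratio(tb, ta, w)$ratio)
}

#' Build a labeled duplicate-pair fixture with target section frequencies
#'
#' Emulates a curated set of known duplicate article pairs carrying
#' manually-estimated per-section similarity ratios: emits `n` labeled pairs
#' whose per-section exceedance fractions (ratio > 0.5) equal the targets at
#' the nearest achievable count `round(target * n)`. With `exact = TRUE` a
#' target not representable as `k/n` is rejected, naming the nearest
#' achievable value.
#'
#' @param n Number of pairs; default 193.
#' @param targets Named fractions in `[0, 1]` for `INTRODUCTION`, `METHODS`,
#'   `RESULTS_DISCUSSION`.
#' @param seed RNG seed for ratio values and exceedance assignment.
#' @param exact Reject targets not exactly representable at `n`.
#' @return `data.frame` with `pair_id`, `intro_ratio`, `methods_ratio`,
#'   `results_ratio`, `shared_author`; attribute `achieved` holds the exact
#'   emitted fractions.
#' @export
make_duplicate_fixture <- function(n = 193,
                                   targets = c(INTRODUCTION = 0.82,
                                               METHODS = 0.89,
                                               RESULTS_DISCUSSION = 0.94),
                                   seed = 1L, exact = FALSE) {
  stopifnot(n >= 1, all(targets >= 0), all(targets <= 1),
            all(c("INTRODUCTION", "METHODS", "RESULTS_DISCUSSION") %in%
                  names(targets)))
  k <- round(targets * n)
  if (exact && any(abs(k / n - targets) > 1e-12))
    stop("targets not achievable at n = ", n, "; nearest achievable: ",
         paste(sprintf("%s=%s", names(targets), format(k / n, digits = 6)),
               collapse = ", "))
  set.seed(seed)
  gen <- function(k_cl) {
    hi <- sample.int(n, k_cl)
    r <- runif(n, 0.02, 0.45)
    r[hi] <- runif(k_cl, 0.55, 0.99)
    r
  }
  out <- data.frame(
    pair_id = sprintf("DUP%03d", seq_len(n)),
    intro_ratio = gen(k[["INTRODUCTION"]]),
    methods_ratio = gen(k[["METHODS"]]),
    results_ratio = gen(k[["RESULTS_DISCUSSION"]]),
    shared_author = runif(n) < 0.5,
    stringsAsFactors = FALSE)
  attr(out, "achieved") <- k / n
  out
}

#' Write the ground-truth ledger as TSV
#'
#' @param syn A [generate_corpus()] result.
#' @param path Output path for the plants table.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(syn, path) {
  write.table(syn$ledger$plants, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
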