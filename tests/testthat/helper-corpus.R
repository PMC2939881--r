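# Shared fixtures and the brute-force scan oracle.

# tiny deterministic corpus: 2 articles x 3 sections x 2 paragraphs
toy_corpus <- function() {
  mk <- function(id, seedword, authors, pub_type = "research") {
    para <- function(s, i) paste(rep(paste0(seedword, s, i), 40), collapse = " ")
    article(
      id, title = paste("study of", seedword),
      abstract = paste(rep(paste0(seedword, "abs"), 50), collapse = " "),
      authors = authors, journal = "J Test", year = 2005, pub_type = pub_type,
      sections = list(
        section("Introduction", c(para("i", 1), para("i", 2))),
        section("Methods", c(para("m", 1), para("m", 2))),
        section("Results and Discussion", c(para("r", 1), para("r", 2)))
      ))
  }
  list(mk("A1", "alpha", c("Smith, John A.", "Jones, Mary")),
       mk("A2", "beta", c("Garcia, Maria", "Jones, Mary")))
}

# units built from word lists through the public constructor path
make_units <- function(texts, article_ids = NULL, min_words = 0) {
  if (is.null(article_ids)) article_ids <- sprintf("ART%03d", seq_along(texts))
  corpus <- mapply(function(txt, id)
    article(id, sections = list(section("Methods", txt))),
    texts, unique_ids(article_ids), SIMPLIFY = FALSE)
  extract_units(corpus, "PARAGRAPH", min_words = min_words)
}
unique_ids <- function(ids) make.unique(ids, sep = "_")

# random unit texts over a shared small vocabulary (non-stopword tokens)
random_texts <- function(n, n_words = 40, vocab_size = 120, seed = 1) {
  set.seed(seed)
  vocab <- sprintf("term%03d", seq_len(vocab_size))
  vapply(seq_len(n), function(i)
    paste(sample(vocab, n_words, replace = TRUE), collapse = " "),
    character(1))
}

# independent double-loop oracle: scores every ordered pair directly
brute_force_pairs <- function(units, weights, threshold = 0.5,
                              pairing = "either") {
  keep <- which(!units$excluded)
  out <- NULL
  for (ii in seq_along(keep)) for (jj in seq_along(keep)) {
    if (jj <= ii) next
    i <- keep[ii]; j <- keep[jj]
    if (units$article_id[i] == units$article_id[j]) next
    s <- similarity_score(units$tokens[[i]], units$tokens[[j]], weights)
    idi <- identity_score(units$tokens[[i]], weights)
    idj <- identity_score(units$tokens[[j]], weights)
    if (idi <= 0 || idj <= 0) next
    rf <- s / idj; rr <- s / idi
    pr <- if (pairing == "either") max(rf, rr) else min(rf, rr)
    if (pr >= threshold) {
      a <- units$unit_id[i]; b <- units$unit_id[j]
      row <- if (a <= b)
        data.frame(unit_id_a = a, unit_id_b = b, pair_ratio = pr)
      else data.frame(unit_id_a = b, unit_id_b = a, pair_ratio = pr)
      out <- rbind(out, row)
    }
  }
  if (is.null(out))
    return(data.frame(unit_id_a = character(0), unit_id_b = character(0),
                      pair_ratio = numeric(0)))
  out <- out[order(out$unit_id_a, out$unit_id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# synthetic pair table with given SA/DA/unknown counts
mk_pairs <- function(n_sa, n_da, n_unknown = 0) {
  n <- n_sa + n_da + n_unknown
  data.frame(
    article_id_a = sprintf("X%04d", seq_len(n)),
    article_id_b = sprintf("Y%04d", seq_len(n)),
    pair_ratio = rep(0.8, n),
    shared_author = c(rep(TRUE, n_sa), rep(FALSE, n_da), rep(NA, n_unknown)),
    stringsAsFactors = FALSE)
}

planted_keys <- function(syn) {
  with(syn$ledger$plants,
       paste(pmin(article_id_a, article_id_b),
             pmax(article_id_a, article_id_b), sep = "\r"))
}
pair_article_keys <- function(pairs) {
  paste(pmin(pairs$article_id_a, pairs$article_id_b),
        pmax(pairs$article_id_a, pairs$article_id_b), sep = "\r")
}
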