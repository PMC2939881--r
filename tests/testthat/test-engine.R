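test_that("term weights follow the smoothed idf closed form", {
  # single unit: every term has df = N = 1 -> w = ln(2/2) + 1 = 1
  u1 <- make_units(list("apple banana apple"))
  w1 <- build_weights(u1)
  expect_true(all(w1$w == 1))

  # 10 units: ubiquitous term w = 1; singleton w = ln(11/2) + 1
  texts <- lapply(1:10, function(i)
    if (i == 1) "common rare" else "common filler")
  w10 <- build_weights(make_units(texts))
  expect_equal(unname(w10$w["common"]), 1)
  expect_equal(unname(w10$w["rare"]), log(11 / 2) + 1, tolerance = 1e-12)
  expect_equal(unname(w10$w["rare"]), 2.7047, tolerance = 1e-4)

  expect_error(build_weights(make_units(list("a the of"), min_words = 5)),
               "empty")
})

test_that("similarity score is the weighted min-count overlap", {
  wts <- structure(list(w = c(a = 2, b = 1, c = 1), N = 3),
                   class = "dc_weights")
  expect_identical(similarity_score(c("x", "y"), c("z"), wts), 0)
  expect_equal(similarity_score(c("a", "b"), c("a", "a", "c"), wts), 2)
  # query = subject -> identity score
  s <- c("a", "a", "b", "c")
  expect_equal(similarity_score(s, s, wts), identity_score(s, wts))
  expect_equal(identity_score(c("a", "a", "c"), wts), 5)
})

test_that("similarity ratio normalises by the subject identity score", {
  wts <- structure(list(w = c(a = 2, b = 1, c = 1), N = 3),
                   class = "dc_weights")
  r <- similarity_ratio(c("a", "b"), c("a", "a", "c"), wts)
  expect_equal(r$ratio, 0.4)
  expect_equal(similarity_ratio(c("a", "b"), c("a", "b"), wts)$ratio, 1)
  expect_equal(similarity_ratio(c("x"), c("a"), wts)$ratio, 0)
  # subject with no weighted tokens has no defined ratio
  expect_error(similarity_ratio(c("a"), character(0), wts), "identity score 0")
})

test_that("ratio is normalised over random pairs and exact on self", {
  texts <- random_texts(60, seed = 101)
  units <- make_units(as.list(texts))
  w <- build_weights(units)
  set.seed(202)
  for (rep in 1:300) {
    ij <- sample(nrow(units), 2)
    r <- similarity_ratio(units$tokens[[ij[1]]], units$tokens[[ij[2]]], w)
    expect_gte(r$ratio, 0)
    expect_lte(r$ratio, 1)
  }
  for (i in sample(nrow(units), 10))
    expect_identical(
      similarity_ratio(units$tokens[[i]], units$tokens[[i]], w)$ratio, 1)
})

test_that("appending a non-exhausted subject token never lowers the score", {
  texts <- random_texts(30, n_words = 25, seed = 77)
  units <- make_units(as.list(texts))
  w <- build_weights(units)
  set.seed(88)
  for (rep in 1:100) {
    ij <- sample(nrow(units), 2)
    q <- units$tokens[[ij[1]]]; s <- units$tokens[[ij[2]]]
    base <- similarity_score(q, s, w)
    # pick a subject token not yet exhausted by the min with the query
    cs <- table(s); cq <- table(q)
    open <- names(cs)[cs > ifelse(is.na(cq[names(cs)]), 0, cq[names(cs)])]
    if (length(open) == 0) next
    tok <- sample(open, 1)
    expect_gte(similarity_score(c(q, tok), s, w), base)
  }
})

test_that("indexed scan equals the brute-force double loop", {
  for (seed in c(1, 2, 3)) {
    texts <- random_texts(80, n_words = 30, vocab_size = 100, seed = seed)
    units <- make_units(as.list(texts))
    w <- build_weights(units)
    for (thr in c(0.2, 0.5)) {
      got <- all_vs_all(units, config = scan_config(threshold = thr,
                                                    top_k = 1e6), weights = w)
      want <- brute_force_pairs(units, w, threshold = thr)
      expect_identical(got$unit_id_a, want$unit_id_a)
      expect_identical(got$unit_id_b, want$unit_id_b)
      expect_equal(got$pair_ratio, want$pair_ratio, tolerance = 1e-12)
    }
  }
})

test_that("capped and exact scan paths agree when top_k covers the dataset", {
  texts <- random_texts(50, seed = 9)
  units <- make_units(as.list(texts))
  w <- build_weights(units)
  exact <- all_vs_all(units, config = scan_config(threshold = 0.2, top_k = 1e6),
                      weights = w)
  capped <- all_vs_all(units, config = scan_config(threshold = 0.2, top_k = 50),
                       weights = w)
  expect_identical(exact, capped)
})

test_that("scan excludes same-article pairs and orders output canonically", {
  texts <- list(c("alpha beta gamma delta epsilon zeta eta theta"),
                c("alpha beta gamma delta epsilon zeta eta theta"))
  # same text twice within one article: must not self-pair
  one_article <- list(
    article("A1", sections = list(section("Methods", unlist(texts)))))
  u1 <- extract_units(one_article, "PARAGRAPH", min_words = 0)
  w1 <- build_weights(u1)
  expect_identical(nrow(all_vs_all(u1, config = scan_config(top_k = 10),
                                   weights = w1)), 0L)

  # across articles the identical pair is found once, ids ordered
  two <- list(article("B2", sections = list(section("Methods", texts[[1]]))),
              article("B1", sections = list(section("Methods", texts[[2]]))))
  u2 <- extract_units(two, "PARAGRAPH", min_words = 0)
  p <- all_vs_all(u2, config = scan_config(top_k = 10),
                  weights = build_weights(u2))
  expect_identical(nrow(p), 1L)
  expect_identical(p$article_id_a, "B1")
  expect_identical(p$pair_ratio, 1)
})

test_that("scan config validates the threshold and pairing rule", {
  expect_error(scan_config(threshold = 1.5), "threshold")
  expect_error(scan_config(threshold = 0), "threshold")
  expect_error(scan_config(top_k = 0), "top_k")
  expect_identical(scan_config()$threshold, 0.5)
  expect_identical(scan_config()$pairing, "either")
})

test_that("pairing rule controls the pair ratio aggregation", {
  # asymmetric pair: query contains subject (ratio 1 one way, <1 the other)
  texts <- list("alpha beta gamma delta",
                "alpha beta gamma delta extra1 extra2 extra3 extra4")
  units <- make_units(texts)
  w <- build_weights(units)
  either <- all_vs_all(units, config = scan_config(threshold = 0.99,
                                                   top_k = 10), weights = w)
  both <- all_vs_all(units, config = scan_config(threshold = 0.99, top_k = 10,
                                                 pairing = "both"),
                     weights = w)
  expect_identical(nrow(either), 1L)
  expect_identical(nrow(both), 0L)
  expect_equal(either$pair_ratio, 1)
  expect_lt(min(either$ratio_forward, either$ratio_reverse), 1)
})
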