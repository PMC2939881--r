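test_that("census computes frequency and shared-author odds from counts", {
  # published introduction column: 318 pairs over 61,149 sections
  cs <- census(mk_pairs(222, 96), N = 61149)
  expect_equal(round(cs$frequency, 4), 0.0052)
  expect_equal(round(cs$odds, 2), 2.31)
  expect_identical(cs$n_sa + cs$n_da + cs$n_unknown, cs$n_pairs)

  empty <- census(mk_pairs(0, 0), N = 100)
  expect_identical(empty$frequency, 0)
  expect_false(empty$odds_defined)
  expect_error(census(mk_pairs(1, 1), N = 0), "positive")

  unk <- census(mk_pairs(2, 3, 4), N = 10)
  expect_identical(unk$n_unknown, 4L)
  expect_equal(unk$odds, 2 / 3)
})

test_that("article-level collapse keeps one row per article pair", {
  p <- data.frame(
    article_id_a = c("B", "A", "A"), article_id_b = c("A", "B", "C"),
    pair_ratio = c(0.6, 0.9, 0.7), shared_author = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  ap <- article_pairs(p)
  expect_identical(nrow(ap), 2L)
  expect_identical(ap$article_id_a, c("A", "A"))
  expect_equal(ap$pair_ratio[ap$article_id_b == "B"], 0.9)  # max over units
})

test_that("contingency table uses the ordered-pair-space convention", {
  none <- contingency(mk_pairs(0, 0), mk_pairs(0, 0), n_articles = 72011)
  expect_identical(none$a + none$b + none$c, 0L)
  expect_equal(none$d, 5185512110)
  expect_equal(none$pair_space, 72011 * 72010)

  one <- data.frame(article_id_a = "P1", article_id_b = "P2",
                    stringsAsFactors = FALSE)
  both <- contingency(one, one, n_articles = 10)
  expect_identical(c(both$a, both$b, both$c), c(1L, 0L, 0L))
  expect_equal(both$a + both$b + both$c + both$d, both$pair_space)
})

test_that("log10 odds ratio reproduces the published association strength", {
  tab <- contingency_from_counts(a = 150, b = 598, c = 282,
                                 n_articles = 72011)
  or <- log10_odds_ratio(tab, confidence = 0.99)
  expect_equal(round(or$log10_or, 2), 6.66)
  # the standard large-sample 0.99 interval half-width is ~0.12
  expect_equal(or$half_width, 0.122, tolerance = 0.005)

  flat <- contingency_from_counts(5, 5, 5, 5)
  expect_identical(log10_odds_ratio(flat)$log10_or, 0)
  direct <- contingency_from_counts(10, 5, 2, 1)
  expect_equal(log10_odds_ratio(direct)$log10_or, 0)

  # negating one condition (a<->b, c<->d) inverts the odds: sign flips
  tab2 <- contingency_from_counts(a = tab$b, b = tab$a, c = tab$d, d = tab$c)
  expect_equal(log10_odds_ratio(tab2)$log10_or, -or$log10_or,
               tolerance = 1e-12)

  zero <- contingency_from_counts(0, 5, 5, 5)
  expect_error(log10_odds_ratio(zero), "haldane")
  expect_true(log10_odds_ratio(zero, haldane = TRUE)$corrected)
})

test_that("prediction metrics match the published screening summary", {
  tab <- contingency_from_counts(a = 150, b = 598, c = 282,
                                 n_articles = 72011)
  pm <- prediction_metrics(tab)
  expect_equal(round(100 * pm$ppv, 1), 20.1)
  expect_equal(round(100 * unname(pm$ppv_ci), 1), c(17.3, 23.1),
               tolerance = 0.05)
  expect_equal(pm$sensitivity_like, 1 - pm$fnr)

  expect_equal(prediction_metrics(contingency_from_counts(0, 9, 1, 1))$ppv, 0)
  expect_equal(prediction_metrics(contingency_from_counts(7, 7, 1, 1))$ppv, 0.5)
  # PPV invariant to scaling all cells
  t1 <- contingency_from_counts(3, 9, 2, 6)
  t2 <- contingency_from_counts(30, 90, 20, 60)
  expect_equal(prediction_metrics(t1)$ppv, prediction_metrics(t2)$ppv)
  expect_error(prediction_metrics(contingency_from_counts(0, 0, 1, 1)), "PPV")
})

test_that("conditional probabilities and one-sided comparisons work", {
  # 40 methods-similar article pairs of which 10 also share abstracts -> 25%
  sec <- data.frame(
    article_id_a = sprintf("M%02da", 1:40), article_id_b = sprintf("M%02db", 1:40),
    pair_ratio = 0.8, shared_author = FALSE,
    section_class_a = "METHODS", section_class_b = "METHODS",
    stringsAsFactors = FALSE)
  abs_pairs <- sec[1:10, c("article_id_a", "article_id_b")]
  cp <- conditional_probability(sec, abs_pairs)
  est <- cp$estimates
  expect_identical(est$n[est$section_class == "METHODS"], 40L)
  expect_equal(est$p[est$section_class == "METHODS"], 0.25)

  none <- conditional_probability(sec[0, ], abs_pairs)
  expect_identical(nrow(none$estimates), 0L)

  all_in <- conditional_probability(sec, sec[, c("article_id_a", "article_id_b")])
  expect_equal(all_in$estimates$p, 1)

  # published section comparison: one-sided pooled z-tests on the printed
  # numerators/denominators give P = 0.01 and P = 0.03
  expect_equal(round(two_proportion_test(36, 380, 50, 846)$p_value, 2), 0.01)
  expect_equal(round(two_proportion_test(36, 380, 3, 87)$p_value, 2), 0.03)
})

test_that("ratio distributions flag empty classes and find crossings", {
  one_class <- ratio_distribution(runif(50), rep(TRUE, 50))
  expect_true(one_class$empty[["false"]])
  expect_false(one_class$empty[["true"]])
  expect_equal(sum(one_class$bins$freq_true), 1)

  # uniform ratios: both histograms flat within sampling error
  set.seed(42)
  r <- runif(4000); cond <- rep(c(TRUE, FALSE), 2000)
  d <- ratio_distribution(r, cond)
  counts_t <- d$bins$freq_true * 2000
  chi <- sum((counts_t - 100)^2 / 100)
  expect_lt(chi, qchisq(0.999, df = 19))

  # planted bimodal: duplicates near 0.87, background near 0.17
  set.seed(7)
  dup <- pmin(pmax(rnorm(500, 0.87, 0.03), 0), 1)
  bg <- pmin(pmax(rnorm(500, 0.17, 0.03), 0), 1)
  d2 <- ratio_distribution(c(dup, bg), c(rep(TRUE, 500), rep(FALSE, 500)))
  expect_equal(d2$bins$bin_lo[which.max(d2$bins$freq_true)], 0.85)
  expect_equal(d2$bins$bin_lo[which.max(d2$bins$freq_false)], 0.15)

  # overlapping low/high classes cross once near the middle
  set.seed(8)
  lo_class <- rbeta(4000, 2, 5); hi_class <- rbeta(4000, 5, 2)
  d3 <- ratio_distribution(c(hi_class, lo_class),
                           c(rep(TRUE, 4000), rep(FALSE, 4000)))
  expect_identical(nrow(d3$crossings), 1L)
  expect_gt(d3$crossings$lo, 0.3)
  expect_lt(d3$crossings$hi, 0.7)
})

test_that("similarity correlation handles exact lines and independence", {
  x <- seq(0.45, 0.95, length.out = 20)
  up <- similarity_correlation(x, x)
  expect_equal(up$pearson_r, 1)
  expect_equal(up$slope, 1)
  down <- similarity_correlation(x, 1 - x + 0.45)  # stay above the floor
  expect_equal(down$pearson_r, -1)

  set.seed(11)
  a <- runif(2000, 0.41, 1); b <- runif(2000, 0.41, 1)
  ind <- similarity_correlation(a, b)
  expect_lt(abs(ind$pearson_r), 2 / sqrt(ind$n))
  expect_error(similarity_correlation(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)),
               "floor")
})

test_that("review census stratifies by publication type", {
  mk_art <- function(id, pt, journal, year, author)
    article(id, authors = author, journal = journal, year = year,
            pub_type = pt)
  corpus <- list(
    mk_art("R1", "review", "JA", 2005, "Smith, J."),
    mk_art("R2", "review", "JA", 2005, "Smith, J."),
    mk_art("R3", "review", "JB", 2006, "Brown, K."),
    mk_art("O1", "research", "JC", 2005, "Lee, H."),
    mk_art("O2", "research", "JD", 2007, "Park, S."))
  pairs <- data.frame(
    article_id_a = c("R1", "R1", "O1"), article_id_b = c("R2", "O1", "O2"),
    pair_ratio = 0.8, shared_author = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rc <- review_census(corpus, pairs)
  expect_false(rc$empty)
  st <- rc$strata
  expect_identical(st$n_pairs[st$stratum == "review_review"], 1L)
  expect_identical(st$n_pairs[st$stratum == "review_research"], 1L)
  expect_equal(st$frequency[st$stratum == "review_review"], 1 / 3)
  # the single SA review pair shares journal and year
  expect_equal(rc$same_journal_fraction, 1)
  expect_equal(rc$same_year_fraction, 1)

  none <- review_census(list(mk_art("O9", "research", "J", 2000, "A, B.")),
                        pairs[0, ])
  expect_true(none$empty)
})

test_that("duplicate-set section frequencies count strict exceedances", {
  fx <- data.frame(pair_id = c("p1", "p2"), intro_ratio = c(1, 1),
                   methods_ratio = c(0.4, NA), results_ratio = c(1, 1))
  fr <- duplicate_set_section_frequencies(fx)
  expect_equal(fr$frequency[fr$section_class == "RESULTS_DISCUSSION"], 1)
  expect_equal(fr$frequency[fr$section_class == "METHODS"], 0)
  expect_identical(fr$n_skipped[fr$section_class == "METHODS"], 1L)
  expect_error(duplicate_set_section_frequencies(fx[0, ]), "empty")
})
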