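test_that("identical config and seed give identical corpora and ledgers", {
  cfg <- generator_config(n_articles = 40, seed = 123,
                          plants = list(plant_spec(2, "fulltext", 0.8)))
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_identical(s1$corpus, s2$corpus)
  expect_identical(s1$ledger$plants, s2$ledger$plants)

  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_corpus(s1$corpus, p1); write_corpus(s2$corpus, p2)
  expect_identical(readLines(p1), readLines(p2))

  s3 <- generate_corpus(generator_config(n_articles = 40, seed = 124,
                                         plants = cfg$plants))
  expect_false(identical(s1$corpus, s3$corpus))
})

test_that("config validation rejects infeasible duplication plans", {
  expect_error(generator_config(n_articles = 10,
                                plants = list(plant_spec(6, "fulltext"))),
               "infeasible")
  expect_error(plant_spec(1, "fulltext", copy_fraction = 1.2))
  expect_error(plant_spec(1, "whole_journal"))
})

test_that("ledger matches the emitted corpus token for token", {
  cfg <- generator_config(n_articles = 50, seed = 9, plants = list(
    plant_spec(3, "methods_section", 0.7, author_overlap = "shared"),
    plant_spec(2, "abstract_only", 1.0)))
  syn <- generate_corpus(cfg)
  pl <- syn$ledger$plants
  expect_identical(nrow(pl), 5L)
  expect_equal(pl$achieved_fraction, pl$copy_fraction, tolerance = 0.03)

  # independent recount of one methods plant: shared token mass / source length
  ids <- vapply(syn$corpus, `[[`, character(1), "article_id")
  r <- which(pl$target == "methods_section")[1]
  grab <- function(id) {
    a <- syn$corpus[[match(id, ids)]]
    cls <- vapply(a$sections, `[[`, character(1), "section_class")
    unlist(strsplit(a$sections[[which(cls == "METHODS")[1]]]$paragraphs, " "))
  }
  ta <- grab(pl$article_id_a[r]); tb <- grab(pl$article_id_b[r])
  shared <- intersect(unique(ta), unique(tb))
  overlap <- sum(pmin(table(ta)[shared], table(tb)[shared])) / length(tb)
  expect_equal(overlap, 0.7, tolerance = 0.03)

  # author overlap is exactly as planted
  for (r in seq_len(nrow(pl))) {
    ka <- author_keys(syn$corpus[[match(pl$article_id_a[r], ids)]])
    kb <- author_keys(syn$corpus[[match(pl$article_id_b[r], ids)]])
    expect_identical(length(intersect(ka, kb)) > 0,
                     pl$author_overlap[r] == "shared")
  }
})

test_that("full-copy plants are recovered exactly at the 0.5 threshold", {
  cfg <- generator_config(n_articles = 80, seed = 21,
                          plants = list(plant_spec(10, "fulltext", 1.0)))
  syn <- generate_corpus(cfg)
  units <- extract_units(syn$corpus, "FULLTEXT")
  w <- build_weights(units)
  pairs <- all_vs_all(units, config = scan_config(top_k = 1e6), weights = w)
  expect_identical(sort(pair_article_keys(pairs)), sort(planted_keys(syn)))
  expect_equal(pairs$pair_ratio, rep(1, 10))
})

test_that("zero-copy plants stay indistinguishable from background", {
  for (seed in 1:5) {
    cfg <- generator_config(n_articles = 40, seed = seed,
                            plants = list(plant_spec(3, "fulltext", 0)))
    syn <- generate_corpus(cfg)
    units <- extract_units(syn$corpus, "FULLTEXT")
    w <- build_weights(units)
    pairs <- all_vs_all(units, config = scan_config(top_k = 1e6), weights = w)
    expect_identical(nrow(pairs), 0L)
  }
})

test_that("mean pair ratio rises with the copy fraction", {
  cfg <- generator_config(n_articles = 24, seed = 300)
  cal <- calibration_curve(cfg, f_grid = c(0, 0.5, 1), n_reps = 4)
  expect_true(all(diff(cal$mean_ratio) >= 0))
  expect_equal(cal$mean_ratio[cal$f == 1], 1)
  expect_lt(cal$mean_ratio[cal$f == 0], 0.05)
  expect_error(calibration_curve(cfg, n_reps = 0), "n_reps")
})

test_that("duplicate fixture hits its exceedance targets by construction", {
  fx <- make_duplicate_fixture()
  expect_identical(nrow(fx), 193L)
  fr <- duplicate_set_section_frequencies(fx)
  expect_identical(fr$n_exceed[fr$section_class == "RESULTS_DISCUSSION"], 181L)
  expect_identical(fr$n_exceed[fr$section_class == "METHODS"], 172L)
  expect_identical(fr$n_exceed[fr$section_class == "INTRODUCTION"], 158L)
  expect_equal(round(fr$frequency, 2), c(0.82, 0.89, 0.94))

  all_hi <- make_duplicate_fixture(n = 20, targets = c(
    INTRODUCTION = 1, METHODS = 1, RESULTS_DISCUSSION = 1))
  expect_true(all(duplicate_set_section_frequencies(all_hi)$frequency == 1))
  none <- make_duplicate_fixture(n = 20, targets = c(
    INTRODUCTION = 0, METHODS = 0, RESULTS_DISCUSSION = 0))
  expect_true(all(duplicate_set_section_frequencies(none)$frequency == 0))

  expect_error(make_duplicate_fixture(n = 10, targets = c(
    INTRODUCTION = 0.82, METHODS = 0.89, RESULTS_DISCUSSION = 0.94),
    exact = TRUE), "nearest achievable")
})

test_that("review plants stratify and flag journals/years as requested", {
  cfg <- generator_config(n_articles = 60, seed = 77, plants = list(
    plant_spec(3, "review_pair", 0.9, author_overlap = "shared",
               same_journal = TRUE, same_year = TRUE),
    plant_spec(2, "review_vs_research", 0.9)))
  syn <- generate_corpus(cfg)
  ids <- vapply(syn$corpus, `[[`, character(1), "article_id")
  pt <- vapply(syn$corpus, `[[`, character(1), "pub_type")
  pl <- syn$ledger$plants
  rr <- pl[pl$target == "review_pair", ]
  expect_true(all(pt[match(rr$article_id_a, ids)] == "review"))
  expect_true(all(pt[match(rr$article_id_b, ids)] == "review"))
  jr <- vapply(syn$corpus, `[[`, character(1), "journal")
  expect_true(all(jr[match(rr$article_id_a, ids)] ==
                    jr[match(rr$article_id_b, ids)]))

  units <- extract_units(syn$corpus, "FULLTEXT")
  pairs <- all_vs_all(units, config = scan_config(top_k = 1e6),
                      weights = build_weights(units), authors = syn$corpus)
  rc <- review_census(syn$corpus, pairs)
  st <- rc$strata
  expect_gte(st$n_pairs[st$stratum == "review_review"], 3L)
  expect_equal(rc$same_journal_fraction, 1)
  expect_equal(rc$same_year_fraction, 1)
})
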