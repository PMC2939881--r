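#' Census of similar pairs
#'
#' Summarises a set of similar pairs against the size of the query dataset:
#' the frequency of similar pairs (count normalised by `N`) and the
#' shared-author odds, i.e. the number of pairs with at least one shared
#' author (SA) over the number with none (DA). Pairs whose authorship is
#' unknown are excluded from the odds and reported separately.
#'
#' @param pairs A `data.frame` of similar pairs (from [all_vs_all()] or with
#'   at least a `shared_author` column).
#' @param N Size of the query dataset (the normalisation denominator); must
#'   be positive.
#' @return A list of class `"dc_census"`: `N`, `n_pairs`, `n_sa`, `n_da`,
#'   `n_unknown`, `frequency`, `odds` (`NA` with `odds_defined = FALSE` when
#'   DA = 0).
#' @export
census <- function(pairs, N) {
  if (!is.numeric(N) || length(N) != 1L || N <= 0)
    stop("N must be a positive dataset size")
  sa <- pairs$shared_author
  if (is.null(sa)) sa <- rep(NA, nrow(pairs))
  n_sa <- sum(sa %in% TRUE)
  n_da <- sum(sa %in% FALSE)
  n_unknown <- sum(is.na(sa))
  structure(list(
    N = N, n_pairs = nrow(pairs), n_sa = n_sa, n_da = n_da,
    n_unknown = n_unknown, frequency = nrow(pairs) / N,
    odds = if (n_da > 0) n_sa / n_da else NA_real_,
    odds_defined = n_da > 0
  ), class = "dc_census")
}

#' Collapse unit-level similar pairs to article-level pairs
#'
#' Multiple similar unit pairs between the same two articles collapse to one
#' article pair; the pair ratio kept is the maximum over unit pairs and
#' `shared_author` is carried through. Used by the contingency and
#' conditional-probability analyses, which live at article level, while
#' section and paragraph censuses count unit pairs.
#'
#' @param pairs Output of [all_vs_all()].
#' @return A `data.frame` with `article_id_a` < `article_id_b`,
#'   `pair_ratio` (max) and `shared_author`.
#' @export
article_pairs <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(article_id_a = character(0), article_id_b = character(0),
                      pair_ratio = numeric(0), shared_author = logical(0),
                      stringsAsFactors = FALSE))
  a <- pmin(pairs$article_id_a, pairs$article_id_b)
  b <- pmax(pairs$article_id_a, pairs$article_id_b)
  key <- paste(a, b, sep = "\r")
  agg_ratio <- tapply(pairs$pair_ratio, key, max)
  first <- !duplicated(key)
  out <- data.frame(article_id_a = a[first], article_id_b = b[first],
                    stringsAsFactors = FALSE)
  k <- key[first]
  out$pair_ratio <- as.numeric(agg_ratio[k])
  out$shared_author <- pairs$shared_author[first]
  out <- out[order(out$article_id_a, out$article_id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_keys <- function(pairs) {
  if (nrow(pairs) == 0L) return(character(0))
  unique(paste(pmin(pairs$article_id_a, pairs$article_id_b),
               pmax(pairs$article_id_a, pairs$article_id_b), sep = "\r"))
}

#' 2x2 contingency table of two pair-level similarity conditions
#'
#' Cross-classifies article pairs by two binary similarity conditions (e.g.
#' high abstract similarity and high full-text similarity). Cells:
#' `a` = pairs satisfying both, `b` = condition 1 only, `c` = condition 2
#' only, `d` = remainder of the pair space. The pair-space denominator uses
#' the ordered-pair convention `n_articles * (n_articles - 1)`, matching how
#' corpus-scale scans count each unordered pair from both directions;
#' detected pairs themselves are stored unordered.
#'
#' @param pairs_cond1,pairs_cond2 Article-level pair sets (`data.frame`s with
#'   `article_id_a`/`article_id_b`, e.g. from [article_pairs()]).
#' @param n_articles Number of articles in the shared universe.
#' @param labels Character vector of length 2 naming the conditions.
#' @return A list of class `"dc_contingency"` with `a`, `b`, `c`, `d`,
#'   `n_articles`, `pair_space` and `labels`.
#' @export
contingency <- function(pairs_cond1, pairs_cond2, n_articles,
                        labels = c("condition1", "condition2")) {
  k1 <- pair_keys(pairs_cond1)
  k2 <- pair_keys(pairs_cond2)
  a <- length(intersect(k1, k2))
  b <- length(setdiff(k1, k2))
  cc <- length(setdiff(k2, k1))
  space <- as.numeric(n_articles) * (n_articles - 1)
  d <- space - a - b - cc
  if (d < 0)
    stop("pair sets exceed the declared pair space; universes mismatch")
  structure(list(a = a, b = b, c = cc, d = d, n_articles = n_articles,
                 pair_space = space, labels = labels),
            class = "dc_contingency")
}

#' Build a contingency table directly from cell counts
#'
#' For recomputing published statistics from printed counts.
#'
#' @param a,b,c,d Cell counts (both / condition-1 only / condition-2 only /
#'   neither). `d` may be given implicitly via `n_articles`.
#' @param n_articles If supplied, `d` is derived as
#'   `n_articles*(n_articles-1) - a - b - c`.
#' @param labels Condition labels.
#' @return A `"dc_contingency"` object.
#' @export
contingency_from_counts <- function(a, b, c, d = NULL, n_articles = NULL,
                                    labels = c("condition1", "condition2")) {
  if (is.null(d)) {
    if (is.null(n_articles)) stop("supply either d or n_articles")
    d <- as.numeric(n_articles) * (n_articles - 1) - a - b - c
  }
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  structure(list(a = a, b = b, c = c, d = d,
                 n_articles = n_articles %||% NA,
                 pair_space = a + b + c + d, labels = labels),
            class = "dc_contingency")
}

#' Log10 odds ratio of a 2x2 table with a large-sample interval
#'
#' `log10((a*d)/(b*c))` with half-width
#' `z * sqrt(1/a + 1/b + 1/c + 1/d) / ln(10)` at the given two-sided
#' confidence level — the standard large-sample interval for the log odds
#' ratio, expressed on the base-10 scale. With any zero cell the Haldane
#' 0.5 correction can be applied (and is flagged); otherwise a zero cell is
#' an error.
#'
#' @param table A `"dc_contingency"` object.
#' @param confidence Two-sided confidence level in `(0, 1)`; default 0.99.
#' @param haldane Add 0.5 to every cell when any cell is zero.
#' @return A list of class `"dc_or"`: `log10_or`, `half_width`, `confidence`,
#'   `corrected`.
#' @export
log10_odds_ratio <- function(table, confidence = 0.99, haldane = FALSE) {
  stopifnot(inherits(table, "dc_contingency"),
            confidence > 0, confidence < 1)
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!haldane)
      stop("zero cell in contingency table; enable haldane = TRUE for the 0.5 correction")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  l10 <- log10((cells[1] * cells[4]) / (cells[2] * cells[3]))
  hw <- z * sqrt(sum(1 / cells)) / log(10)
  structure(list(log10_or = l10, half_width = hw, confidence = confidence,
                 corrected = corrected), class = "dc_or")
}

#' Predictive performance of condition 1 for condition 2
#'
#' The positive-predictive fraction `a / (a + b)`: among pairs flagged by
#' condition 1 (e.g. high abstract similarity), the fraction also satisfying
#' condition 2 (high full-text similarity). Reported with a Wilson score
#' interval. Also reports the miss rate among unflagged pairs,
#' `fnr = c / (c + d)` (the complement of the negative predictive value),
#' and its complement `sensitivity_like = d / (c + d)`; this convention is
#' stated explicitly because several incompatible "false negative rate"
#' definitions exist for screening problems.
#'
#' @param table A `"dc_contingency"` object.
#' @param conf_level Confidence level for the Wilson interval; default 0.95.
#' @return A list of class `"dc_prediction"`: `ppv`, `ppv_ci` (length 2),
#'   `fnr`, `sensitivity_like`, `n_predicted`, `conf_level`.
#' @export
prediction_metrics <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "dc_contingency"))
  n1 <- table$a + table$b
  if (n1 <= 0) stop("no pairs flagged by condition 1; PPV undefined")
  ppv <- table$a / n1
  ci <- wilson_interval(table$a, n1, conf_level)
  n0 <- table$c + table$d
  fnr <- if (n0 > 0) table$c / n0 else NA_real_
  structure(list(ppv = ppv, ppv_ci = ci, fnr = fnr,
                 sensitivity_like = if (is.na(fnr)) NA_real_ else 1 - fnr,
                 n_predicted = n1, conf_level = conf_level),
            class = "dc_prediction")
}

wilson_interval <- function(k, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Conditional probability of abstract similarity given section similarity
#'
#' Among article pairs with a similar section of each class, the fraction
#' that also have similar abstracts. Section pairs are collapsed to article
#' level first. Classes are compared with a pooled two-proportion z-test;
#' one-sided by default, in the direction given by the comparison order.
#'
#' @param section_pairs Similar pairs at section (or paragraph) granularity
#'   ([all_vs_all()] output); class is taken from `section_class_a` for pairs
#'   within one class.
#' @param abstract_pairs Article-level pair set with similar abstracts.
#' @param comparisons Optional list of 2-vectors of class names to test
#'   (first vs second, alternative "greater"); default: all ordered pairs by
#'   decreasing estimate.
#' @return A list of class `"dc_conditional"`: `estimates` (`data.frame` of
#'   `section_class`, `k`, `n`, `p`) and `comparisons` (`data.frame` of
#'   `class_hi`, `class_lo`, `z`, `p_value`).
#' @export
conditional_probability <- function(section_pairs, abstract_pairs,
                                    comparisons = NULL) {
  abs_keys <- pair_keys(abstract_pairs)
  within <- section_pairs[section_pairs$section_class_a ==
                            section_pairs$section_class_b, , drop = FALSE]
  classes <- sort(unique(within$section_class_a))
  est <- do.call(rbind, lapply(classes, function(cl) {
    ap <- article_pairs(within[within$section_class_a == cl, , drop = FALSE])
    n <- nrow(ap)
    k <- length(intersect(pair_keys(ap), abs_keys))
    data.frame(section_class = cl, k = k, n = n,
               p = if (n > 0) k / n else NA_real_, stringsAsFactors = FALSE)
  }))
  if (is.null(est))
    est <- data.frame(section_class = character(0), k = integer(0),
                      n = integer(0), p = numeric(0), stringsAsFactors = FALSE)
  if (is.null(comparisons) && nrow(est) >= 2L) {
    ord <- est$section_class[order(-est$p)]
    comparisons <- list()
    for (i in seq_along(ord)) for (j in seq_along(ord))
      if (i < j) comparisons[[length(comparisons) + 1L]] <- c(ord[i], ord[j])
  }
  comp <- NULL
  for (cmp in comparisons) {
    e1 <- est[est$section_class == cmp[1L], ]
    e2 <- est[est$section_class == cmp[2L], ]
    if (nrow(e1) == 0L || nrow(e2) == 0L || e1$n == 0 || e2$n == 0) next
    tst <- two_proportion_test(e1$k, e1$n, e2$k, e2$n, alternative = "greater")
    comp <- rbind(comp, data.frame(class_hi = cmp[1L], class_lo = cmp[2L],
                                   z = tst$z, p_value = tst$p_value,
                                   stringsAsFactors = FALSE))
  }
  structure(list(estimates = est, comparisons = comp),
            class = "dc_conditional")
}

#' Pooled two-proportion z-test
#'
#' @param k1,n1,k2,n2 Successes and trials of the two groups.
#' @param alternative `"greater"` (p1 > p2), `"less"`, or `"two.sided"`.
#' @return List with `z` and `p_value`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2,
                                alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  p <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  pv <- switch(alternative,
               greater = pnorm(z, lower.tail = FALSE),
               less = pnorm(z),
               two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  list(z = z, p_value = pv)
}

#' Conditional similarity-ratio distributions
#'
#' Normalised histograms of a similarity ratio for two classes of pairs
#' (condition true / false), with the crossing interval(s) where the two
#' frequency curves intersect — used to read off an operating threshold.
#'
#' @param ratio Numeric vector of similarity ratios in `[0, 1]`.
#' @param condition Logical vector classifying each pair.
#' @param bin_width Histogram bin width over `[0, 1]`; default 0.05.
#' @return A list of class `"dc_distribution"`: `bins` (`data.frame` with
#'   `bin_lo`, `bin_hi`, `freq_true`, `freq_false`), `empty` (named logical:
#'   a condition class with no pairs is flagged), and `crossings`
#'   (`data.frame` of intervals where `freq_true - freq_false` changes sign).
#' @export
ratio_distribution <- function(ratio, condition, bin_width = 0.05) {
  stopifnot(length(ratio) == length(condition))
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  cut_idx <- findInterval(pmin(pmax(ratio, 0), 1), breaks,
                          rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(breaks) - 1L
  h <- function(keep) {
    n <- sum(keep)
    if (n == 0L) return(rep(NA_real_, nb))
    tabulate(cut_idx[keep], nbins = nb) / n
  }
  ft <- h(condition %in% TRUE)
  ff <- h(condition %in% FALSE)
  bins <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                     freq_true = ft, freq_false = ff)
  empty <- c(true = all(is.na(ft)), false = all(is.na(ff)))
  crossings <- NULL
  if (!any(empty)) {
    diffs <- ft - ff
    sgn <- sign(diffs)
    for (i in seq_len(nb - 1L)) {
      if (sgn[i] != 0 && sgn[i + 1L] != 0 && sgn[i] != sgn[i + 1L])
        crossings <- rbind(crossings,
                           data.frame(lo = bins$bin_lo[i + 1L],
                                      hi = bins$bin_hi[i + 1L]))
    }
  }
  if (is.null(crossings)) crossings <- data.frame(lo = numeric(0), hi = numeric(0))
  structure(list(bins = bins, empty = empty, crossings = crossings),
            class = "dc_distribution")
}

#' Correlation between two similarity ratios above a floor
#'
#' Pearson correlation and least-squares line between two similarity ratios
#' (e.g. abstract vs full text), restricted to pairs where both ratios exceed
#' the floor — the regime where both signals are informative.
#'
#' @param ratio_x,ratio_y Numeric vectors of equal length.
#' @param floor Inclusion floor; both ratios must be strictly greater.
#'   Default 0.4.
#' @return A list of class `"dc_correlation"`: `pearson_r`, `slope`,
#'   `intercept`, `n`, `floor`.
#' @export
similarity_correlation <- function(ratio_x, ratio_y, floor = 0.4) {
  stopifnot(length(ratio_x) == length(ratio_y))
  keep <- ratio_x > floor & ratio_y > floor
  if (sum(keep) < 3L)
    stop("fewer than 3 pairs pass the floor; correlation undefined")
  x <- ratio_x[keep]; y <- ratio_y[keep]
  fit <- lm(y ~ x)
  structure(list(pearson_r = cor(x, y), slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]), n = sum(keep),
                 floor = floor), class = "dc_correlation")
}

#' Review-article similarity census
#'
#' Stratifies article-level similar pairs by publication type: review-review,
#' review-research and research-research. Reports per-stratum pair counts,
#' frequencies (normalised by the number of articles of the stratum's query
#' type: reviews for review-involving strata, research articles otherwise),
#' shared-author odds, and — among review-review pairs with a shared author —
#' the fractions published in the same journal and in the same year.
#' Optionally, review-vs-research pair counts by the research unit's section
#' class are normalised by supplied per-class paragraph counts.
#'
#' @param corpus List of [article()] objects (source of `pub_type`, journal
#'   and year).
#' @param pairs Similar pairs ([all_vs_all()] output; unit- or article-level).
#' @param paragraph_counts Optional named vector of paragraph counts per
#'   section class for the review-vs-section frequencies.
#' @return A list of class `"dc_review"`; `empty = TRUE` (with zero counts)
#'   when the corpus has no review articles.
#' @export
review_census <- function(corpus, pairs, paragraph_counts = NULL) {
  ptype <- corpus_pub_types(corpus)
  n_review <- sum(ptype == "review")
  n_research <- sum(ptype == "research")
  if (n_review == 0L)
    return(structure(list(empty = TRUE, n_review = 0L,
                          n_research = n_research),
                     class = "dc_review"))
  journal <- setNames(vapply(corpus, `[[`, character(1), "journal"),
                      names(ptype))
  year <- setNames(vapply(corpus, `[[`, integer(1), "year"), names(ptype))

  ap <- article_pairs(pairs)
  ta <- ptype[ap$article_id_a]; tb <- ptype[ap$article_id_b]
  stratum <- ifelse(ta == "review" & tb == "review", "review_review",
                    ifelse(ta == "research" & tb == "research",
                           "research_research", "review_research"))
  denom <- c(review_review = n_review, review_research = n_review,
             research_research = n_research)
  strata <- do.call(rbind, lapply(names(denom), function(st) {
    sp <- ap[stratum == st, , drop = FALSE]
    cs <- census(sp, denom[[st]])
    data.frame(stratum = st, n_articles = denom[[st]], n_pairs = cs$n_pairs,
               n_sa = cs$n_sa, n_da = cs$n_da, frequency = cs$frequency,
               odds = cs$odds, stringsAsFactors = FALSE)
  }))

  rr_sa <- ap[stratum == "review_review" & ap$shared_author %in% TRUE, ,
              drop = FALSE]
  same_journal <- same_year <- NA_real_
  if (nrow(rr_sa) > 0) {
    same_journal <- mean(journal[rr_sa$article_id_a] ==
                           journal[rr_sa$article_id_b])
    same_year <- mean(year[rr_sa$article_id_a] == year[rr_sa$article_id_b])
  }

  by_section <- NULL
  if (!is.null(paragraph_counts) && "section_class_a" %in% names(pairs)) {
    rv <- pairs[ptype[pairs$article_id_a] != ptype[pairs$article_id_b], ,
                drop = FALSE]
    # section class of the research-side unit
    cls <- ifelse(ptype[rv$article_id_a] == "research",
                  rv$section_class_a, rv$section_class_b)
    by_section <- do.call(rbind, lapply(names(paragraph_counts), function(cl) {
      data.frame(section_class = cl, n_pairs = sum(cls == cl),
                 n_units = paragraph_counts[[cl]],
                 frequency = sum(cls == cl) / paragraph_counts[[cl]],
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(
    empty = FALSE, n_review = n_review, n_research = n_research,
    strata = strata, n_sa_review_review = nrow(rr_sa),
    same_journal_fraction = same_journal, same_year_fraction = same_year,
    by_section = by_section
  ), class = "dc_review")
}

#' Per-section similarity frequencies in a labeled duplicate-pair set
#'
#' For a labeled set of known duplicate article pairs carrying per-section
#' similarity ratios, the fraction of pairs whose ratio for each section
#' class strictly exceeds 0.5. Pairs with a missing ratio for a section are
#' skipped for that section and counted.
#'
#' @param fixture `data.frame` with columns `pair_id`, `intro_ratio`,
#'   `methods_ratio`, `results_ratio` (e.g. from [make_duplicate_fixture()]).
#' @param threshold Exceedance threshold (strict); default 0.5.
#' @return `data.frame` with `section_class`, `n_used`, `n_exceed`,
#'   `frequency`, `n_skipped`.
#' @export
duplicate_set_section_frequencies <- function(fixture, threshold = 0.5) {
  if (nrow(fixture) == 0L) stop("empty duplicate-pair fixture")
  cols <- c(INTRODUCTION = "intro_ratio", METHODS = "methods_ratio",
            RESULTS_DISCUSSION = "results_ratio")
  do.call(rbind, lapply(names(cols), function(cl) {
    r <- fixture[[cols[[cl]]]]
    used <- !is.na(r)
    data.frame(section_class = cl, n_used = sum(used),
               n_exceed = sum(r[used] > threshold),
               frequency = sum(r[used] > threshold) / sum(used),
               n_skipped = sum(!used), stringsAsFactors = FALSE)
  }))
}

#' Write a census table as TSV
#'
#' @param censuses Named list of `"dc_census"` objects (name = stratum).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(censuses, path) {
  df <- do.call(rbind, lapply(names(censuses), function(nm) {
    cs <- censuses[[nm]]
    data.frame(stratum = nm, N = cs$N, pairs_total = cs$n_pairs,
               pairs_SA = cs$n_sa, pairs_DA = cs$n_da,
               pairs_unknown = cs$n_unknown, frequency = cs$frequency,
               odds = cs$odds, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
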