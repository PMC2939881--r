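#' Corpus-derived term weights
#'
#' Inverse-document-frequency style weights over the vocabulary of a unit
#' dataset: `w(t) = ln((N + 1) / (df(t) + 1)) + 1`, where `N` is the number of
#' included units and `df(t)` the number of included units containing `t`.
#' Weights are strictly positive and deterministic given the dataset. A term
#' present in every unit gets weight 1; rarer terms weigh more, so shared rare
#' vocabulary dominates the similarity score.
#'
#' @param units A dataset from [extract_units()] (excluded units are ignored).
#' @return An object of class `"dc_weights"`: list with `w` (named numeric
#'   vector) and `N`.
#' @export
build_weights <- function(units) {
  tokens <- units$tokens[!units$excluded]
  if (length(tokens) == 0L) stop("cannot build weights from an empty dataset")
  N <- length(tokens)
  df <- table(unlist(lapply(tokens, unique), use.names = FALSE))
  w <- log((N + 1) / (as.numeric(df) + 1)) + 1
  names(w) <- names(df)
  structure(list(w = w, N = N), class = "dc_weights")
}

term_weight <- function(weights, terms) {
  w <- weights$w[terms]
  w[is.na(w)] <- 0
  unname(w)
}

#' Weighted term-overlap similarity score
#'
#' The engine's order-free score of a query text against a subject text:
#' `sum over distinct terms t of w(t) * min(count_query(t), count_subject(t))`.
#' Query terms outside the weight vocabulary contribute weight 0. Comparing a
#' text against itself yields its identity score
#' `sum over t of w(t) * count(t)`, the normalisation constant of the
#' similarity ratio.
#'
#' @param query,subject Token vectors (from [tokenize()]).
#' @param weights A [build_weights()] object.
#' @return Non-negative numeric score.
#' @export
similarity_score <- function(query, subject, weights) {
  qc <- token_counts(query)
  sc <- token_counts(subject)
  shared <- intersect(names(qc), names(sc))
  if (length(shared) == 0L) return(0)
  sum(term_weight(weights, shared) * pmin(qc[shared], sc[shared]))
}

#' Identity score of a text
#'
#' @inheritParams similarity_score
#' @return The subject's score against itself.
#' @export
identity_score <- function(subject, weights) {
  sc <- token_counts(subject)
  if (length(sc) == 0L) return(0)
  sum(term_weight(weights, names(sc)) * sc)
}

#' Directed similarity ratio between two texts
#'
#' The pair statistic of the census: similarity score of query vs subject
#' divided by the subject's identity score. Lies in `[0, 1]` by the min-count
#' construction and equals 1 exactly when the query's token multiset contains
#' the subject's.
#'
#' @inheritParams similarity_score
#' @param query_id,subject_id Optional unit identifiers carried into the
#'   report.
#' @return A list (score report) with `query_id`, `subject_id`,
#'   `similarity_score`, `identity_score` and `ratio`.
#' @export
similarity_ratio <- function(query, subject, weights,
                             query_id = NA_character_,
                             subject_id = NA_character_) {
  id <- identity_score(subject, weights)
  if (id <= 0)
    stop("undefined similarity ratio: subject ", subject_id,
         " has identity score 0 (no weighted tokens)")
  s <- similarity_score(query, subject, weights)
  list(query_id = query_id, subject_id = subject_id,
       similarity_score = s, identity_score = id, ratio = s / id)
}

#' Scan configuration
#'
#' @param threshold Similarity-ratio cut-off in `(0, 1]`; a pair is similar
#'   when its pair ratio is `>= threshold` (closed threshold). Default 0.5,
#'   the calibrated operating point for abstract-sized texts.
#' @param top_k Candidate cap per query before exact scoring, ranked by
#'   number of shared index terms. The index scan is exact whenever `top_k`
#'   is at least the dataset size.
#' @param pairing `"either"` flags a pair when either directed ratio clears
#'   the threshold (pair ratio = max of the two directions); `"both"`
#'   requires both (min).
#' @param seed Optional integer recorded for provenance of any sampling
#'   diagnostics.
#' @return An object of class `"dc_scan_config"`.
#' @export
scan_config <- function(threshold = 0.5, top_k = 400L,
                        pairing = c("either", "both"), seed = NULL) {
  pairing <- match.arg(pairing)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) stop("top_k must be a positive integer")
  structure(list(threshold = threshold, top_k = top_k, pairing = pairing,
                 seed = seed), class = "dc_scan_config")
}

#' Build an inverted index over a unit dataset
#'
#' Maps every weighted term to its postings (unit, term count), backed by a
#' sparse term-by-unit count matrix. The index is a pure accelerator for
#' [all_vs_all()]: candidate retrieval by shared terms followed by exact
#' scoring, so results equal brute-force pairwise scoring (when `top_k`
#' covers the dataset).
#'
#' @param units A dataset from [extract_units()].
#' @param weights A [build_weights()] object; terms outside its vocabulary
#'   are not indexed (they carry weight 0).
#' @return An object of class `"dc_index"`.
#' @export
build_index <- function(units, weights) {
  keep <- !units$excluded
  tokens <- units$tokens[keep]
  vocab <- names(weights$w)
  n <- length(tokens)
  # vectorised (term, unit) count aggregation over the whole dataset
  all_tok <- unlist(tokens, use.names = FALSE)
  uidx <- rep.int(seq_len(n), lengths(tokens))
  tid <- match(all_tok, vocab)
  ok <- !is.na(tid)
  tid <- tid[ok]; uidx <- uidx[ok]
  if (length(tid)) {
    ord <- order(uidx, tid, method = "radix")
    tid <- tid[ord]; uidx <- uidx[ord]
    new_run <- c(TRUE, tid[-1L] != tid[-length(tid)] |
                   uidx[-1L] != uidx[-length(uidx)])
    starts <- which(new_run)
    ii <- tid[starts]; jj <- uidx[starts]
    xx <- diff(c(starts, length(tid) + 1L))
  } else { ii <- integer(0); jj <- integer(0); xx <- numeric(0) }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                            dims = c(length(vocab), max(n, 1L)))
  w <- unname(weights$w)
  identity <- as.numeric(Matrix::colSums(M * w))
  postings <- lapply(seq_along(vocab), function(t) integer(0))
  nz <- data.frame(t = ii, j = jj)
  if (nrow(nz)) postings <- split(nz$j, factor(nz$t, levels = seq_along(vocab)))
  structure(list(
    M = M, postings = postings, w = w, vocab = vocab,
    unit_id = units$unit_id[keep], article_id = units$article_id[keep],
    section_class = units$section_class[keep],
    granularity = if (nrow(units)) units$granularity[which(keep)[1L]] else NA,
    identity = identity, n = n
  ), class = "dc_index")
}

index_column <- function(index, j) {
  M <- index$M
  idx <- (M@p[j] + 1L):(M@p[j + 1L])
  if (M@p[j] == M@p[j + 1L]) return(list(terms = integer(0), x = numeric(0)))
  list(terms = M@i[idx] + 1L, x = M@x[idx])
}

#' Thresholded all-vs-all similarity scan
#'
#' Compares every unit of the query dataset against every unit of the target
#' dataset (or the dataset against itself when `target_units` is `NULL`),
#' retrieving candidates through the inverted index and scoring them exactly.
#' Pairs whose pair ratio clears `config$threshold` are returned once,
#' unordered, in deterministic unit-id order. Pairs of units from the same
#' article are excluded: self-reuse within one article is outside the census.
#'
#' @param query_units Dataset from [extract_units()].
#' @param target_units Optional second dataset; `NULL` scans `query_units`
#'   against itself.
#' @param config A [scan_config()].
#' @param weights A [build_weights()] object, normally built on the target
#'   dataset (or the union for cross-dataset scans).
#' @param authors Optional corpus (list of [article()]) or named list of
#'   author-key sets per article id, used to set the `shared_author` flag
#'   (`NA` when either article has no known authors).
#' @return A `data.frame` of similar pairs with columns `unit_id_a`,
#'   `unit_id_b`, `article_id_a`, `article_id_b`, `ratio_forward`
#'   (a as query), `ratio_reverse`, `pair_ratio`, `shared_author`,
#'   `granularity`, `section_class_a`, `section_class_b`.
#' @export
all_vs_all <- function(query_units, target_units = NULL, config = scan_config(),
                       weights, authors = NULL) {
  stopifnot(inherits(config, "dc_scan_config"), inherits(weights, "dc_weights"))
  self_scan <- is.null(target_units)
  target <- if (self_scan) query_units else target_units
  tindex <- build_index(target, weights)
  qindex <- if (self_scan) tindex else build_index(query_units, weights)

  key_sets <- author_key_sets(authors)
  if (config$top_k >= tindex$n) {
    hits <- scan_exact(qindex, tindex, config, self_scan)
  } else {
    hits <- scan_capped(qindex, tindex, config, self_scan)
  }
  if (is.null(hits) || nrow(hits) == 0L) return(empty_pairs())
  assemble_pairs(hits, qindex, tindex, key_sets)
}

# Exact whole-matrix scan. The min-count overlap decomposes over count
# levels: min(a, b) = sum_k 1[a >= k] 1[b >= k], and token counts are small
# integers, so the full score matrix is a short sum of sparse cross-products
# S_k = t(1[Q >= k] * w) %*% 1[T >= k].
scan_exact <- function(qindex, tindex, config, self_scan) {
  K <- min(suppressWarnings(max(qindex$M@x, 0)),
           suppressWarnings(max(tindex$M@x, 0)))
  if (K < 1) return(NULL)
  S <- NULL
  for (k in seq_len(K)) {
    Qk <- level_indicator(qindex$M, k)
    Tk <- if (self_scan) Qk else level_indicator(tindex$M, k)
    Sk <- Matrix::crossprod(Qk * qindex$w, Tk)
    S <- if (is.null(S)) Sk else S + Sk
  }
  trip <- methods::as(S, "TsparseMatrix")
  i <- trip@i + 1L; j <- trip@j + 1L; s <- trip@x
  if (self_scan) {
    keep <- j > i
    i <- i[keep]; j <- j[keep]; s <- s[keep]
  }
  ok <- tindex$identity[j] > 0 & qindex$identity[i] > 0
  i <- i[ok]; j <- j[ok]; s <- s[ok]
  rf <- s / tindex$identity[j]
  rr <- s / qindex$identity[i]
  pr <- if (config$pairing == "either") pmax(rf, rr) else pmin(rf, rr)
  keep <- pr >= config$threshold
  data.frame(q = i[keep], t = j[keep], ratio_forward = rf[keep],
             ratio_reverse = rr[keep], pair_ratio = pr[keep])
}

level_indicator <- function(M, k) {
  A <- M
  A@x <- as.numeric(M@x >= k)
  Matrix::drop0(A)
}

# Candidate-capped scan: per query, retrieve candidates from the postings,
# keep the top_k by shared-term hits, then score exactly.
scan_capped <- function(qindex, tindex, config, self_scan) {
  acc <- vector("list", qindex$n)
  for (i in seq_len(qindex$n)) {
    qcol <- index_column(qindex, i)
    if (length(qcol$terms) == 0L || qindex$identity[i] <= 0) next
    cand <- unlist(tindex$postings[qcol$terms], use.names = FALSE)
    if (length(cand) == 0L) next
    if (length(cand) > config$top_k) {
      hits <- tabulate(cand, nbins = tindex$n)
      cand <- unique(cand)
      cand <- cand[order(-hits[cand], cand)][seq_len(min(config$top_k, length(cand)))]
    } else cand <- unique(cand)
    if (self_scan) cand <- cand[cand > i]
    cand <- cand[tindex$article_id[cand] != qindex$article_id[i] &
                   tindex$unit_id[cand] != qindex$unit_id[i]]
    if (length(cand) == 0L) next

    sub <- as.matrix(tindex$M[qcol$terms, cand, drop = FALSE])
    s <- colSums(qindex$w[qcol$terms] * pmin(sub, qcol$x))
    rf <- s / tindex$identity[cand]   # query i as query, candidate as subject
    rr <- s / qindex$identity[i]
    pr <- if (config$pairing == "either") pmax(rf, rr) else pmin(rf, rr)
    keep <- pr >= config$threshold
    if (!any(keep)) next
    cand <- cand[keep]
    acc[[i]] <- data.frame(
      q = i, t = cand, ratio_forward = rf[keep], ratio_reverse = rr[keep],
      pair_ratio = pr[keep], stringsAsFactors = FALSE)
  }

  do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
}

assemble_pairs <- function(hits, qindex, tindex, key_sets) {
  # same-article pairs (and self pairs in cross-scans) are out of scope
  keep <- qindex$article_id[hits$q] != tindex$article_id[hits$t]
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_pairs())
  out <- data.frame(
    unit_id_a = qindex$unit_id[hits$q], unit_id_b = tindex$unit_id[hits$t],
    article_id_a = qindex$article_id[hits$q],
    article_id_b = tindex$article_id[hits$t],
    ratio_forward = hits$ratio_forward, ratio_reverse = hits$ratio_reverse,
    pair_ratio = hits$pair_ratio,
    granularity = qindex$granularity,
    section_class_a = qindex$section_class[hits$q],
    section_class_b = tindex$section_class[hits$t],
    stringsAsFactors = FALSE
  )
  # canonical unordered form: smaller unit id first
  flip <- out$unit_id_b < out$unit_id_a
  if (any(flip)) {
    sw <- function(a, b) { tmp <- out[[a]][flip]; out[[a]][flip] <<- out[[b]][flip]; out[[b]][flip] <<- tmp }
    sw("unit_id_a", "unit_id_b"); sw("article_id_a", "article_id_b")
    sw("section_class_a", "section_class_b")
    tmp <- out$ratio_forward[flip]
    out$ratio_forward[flip] <- out$ratio_reverse[flip]
    out$ratio_reverse[flip] <- tmp
  }
  # cross-dataset scans can discover the same unordered pair twice
  key <- paste(out$unit_id_a, out$unit_id_b, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$unit_id_a, out$unit_id_b), , drop = FALSE]
  rownames(out) <- NULL
  out$shared_author <- shared_author_flag(out$article_id_a, out$article_id_b,
                                          key_sets)
  out[, PAIR_COLUMNS]
}

PAIR_COLUMNS <- c("unit_id_a", "unit_id_b", "article_id_a", "article_id_b",
                  "ratio_forward", "ratio_reverse", "pair_ratio",
                  "shared_author", "granularity", "section_class_a",
                  "section_class_b")

empty_pairs <- function() {
  out <- data.frame(
    unit_id_a = character(0), unit_id_b = character(0),
    article_id_a = character(0), article_id_b = character(0),
    ratio_forward = numeric(0), ratio_reverse = numeric(0),
    pair_ratio = numeric(0), shared_author = logical(0),
    granularity = character(0), section_class_a = character(0),
    section_class_b = character(0), stringsAsFactors = FALSE)
  out
}

author_key_sets <- function(authors) {
  if (is.null(authors)) return(NULL)
  if (is.list(authors) && length(authors) && inherits(authors[[1L]], "dc_article"))
    return(corpus_author_keys(authors))
  authors
}

shared_author_flag <- function(id_a, id_b, key_sets) {
  if (is.null(key_sets)) return(rep(NA, length(id_a)))
  mapply(function(a, b) {
    ka <- key_sets[[a]]; kb <- key_sets[[b]]
    if (is.null(ka) || is.null(kb) || length(ka) == 0L || length(kb) == 0L)
      return(NA)
    any(ka %in% kb)
  }, id_a, id_b, USE.NAMES = FALSE)
}

#' Write a similar-pairs table as TSV
#'
#' @param pairs Output of [all_vs_all()].
#' @param path Output path.
#' @param config Optional [scan_config()] serialised into header comments.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("# %s=%s", names(unclass(config)),
                       vapply(unclass(config), format_scalar, character(1))),
               con)
  writeLines(paste(PAIR_COLUMNS, collapse = "\t"), con)
  if (nrow(pairs))
    utils::write.table(pairs[, PAIR_COLUMNS], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_scalar <- function(x) {
  if (is.null(x)) "NULL" else paste(format(x, digits = 15), collapse = ",")
}
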