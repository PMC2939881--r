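#' Extract comparable text units from a corpus
#'
#' Builds the comparison dataset at one of four granularities:
#' \describe{
#'   \item{FULLTEXT}{one unit per article: all body-section paragraphs
#'     concatenated in document order (citation-only articles yield none).}
#'   \item{ABSTRACT}{one unit per article with a non-empty abstract.}
#'   \item{SECTION}{one unit per body section (paragraphs concatenated).}
#'   \item{PARAGRAPH}{one unit per paragraph.}
#' }
#' Units shorter than `min_words` tokens are flagged `excluded` but retained
#' for audit; the dataset size used to normalise census frequencies counts
#' only included units. The default minimum is 30 words for paragraphs and 0
#' otherwise: the similarity ratio is calibrated for abstract-sized texts and
#' very short paragraphs produce unstable ratios.
#'
#' @param corpus List of [article()] objects.
#' @param granularity One of `"FULLTEXT"`, `"ABSTRACT"`, `"SECTION"`,
#'   `"PARAGRAPH"` (case-insensitive).
#' @param section_filter Optional section class to restrict SECTION or
#'   PARAGRAPH units to.
#' @param min_words Minimum token count for inclusion; `NULL` uses the
#'   granularity default.
#' @return A `data.frame` of class `"dc_units"` with columns `unit_id`,
#'   `article_id`, `granularity`, `section_class`, `word_count`, `excluded`
#'   and a list-column `tokens`; attribute `N` holds the number of included
#'   units (the census normalisation denominator).
#' @export
extract_units <- function(corpus, granularity, section_filter = NULL,
                          min_words = NULL) {
  granularity <- toupper(granularity)
  if (!granularity %in% GRANULARITIES)
    stop("unknown granularity: ", granularity)
  if (!is.null(section_filter)) {
    section_filter <- match.arg(toupper(section_filter), SECTION_CLASSES)
    if (granularity %in% c("FULLTEXT", "ABSTRACT"))
      stop("section_filter applies only to SECTION and PARAGRAPH granularities")
  }
  if (is.null(min_words))
    min_words <- if (granularity == "PARAGRAPH") 30L else 0L
  stopifnot(min_words >= 0L)

  rows <- list()
  for (a in corpus) {
    id <- a$article_id
    if (granularity == "FULLTEXT") {
      text <- paste(unlist(lapply(a$sections, `[[`, "paragraphs")), collapse = " ")
      if (nzchar(text))
        rows[[length(rows) + 1L]] <- list(
          unit_id = paste0(id, ":fulltext"), article_id = id,
          section_class = "NONE", text = text)
    } else if (granularity == "ABSTRACT") {
      if (nzchar(a$abstract))
        rows[[length(rows) + 1L]] <- list(
          unit_id = paste0(id, ":abstract"), article_id = id,
          section_class = "NONE", text = a$abstract)
    } else {
      for (si in seq_along(a$sections)) {
        s <- a$sections[[si]]
        if (!is.null(section_filter) && s$section_class != section_filter) next
        if (granularity == "SECTION") {
          text <- paste(s$paragraphs, collapse = " ")
          if (nzchar(text))
            rows[[length(rows) + 1L]] <- list(
              unit_id = paste0(id, ":sec", si), article_id = id,
              section_class = s$section_class, text = text)
        } else {
          for (pi in seq_along(s$paragraphs)) {
            rows[[length(rows) + 1L]] <- list(
              unit_id = paste0(id, ":sec", si, ":p", pi), article_id = id,
              section_class = s$section_class, text = s$paragraphs[[pi]])
          }
        }
      }
    }
  }

  if (length(rows) == 0L) {
    units <- data.frame(unit_id = character(0), article_id = character(0),
                        granularity = character(0), section_class = character(0),
                        word_count = integer(0), excluded = logical(0),
                        stringsAsFactors = FALSE)
    units$tokens <- list()
  } else {
    tokens <- lapply(rows, function(r) tokenize_one(r$text))
    units <- data.frame(
      unit_id = vapply(rows, `[[`, character(1), "unit_id"),
      article_id = vapply(rows, `[[`, character(1), "article_id"),
      granularity = granularity,
      section_class = vapply(rows, `[[`, character(1), "section_class"),
      word_count = lengths(tokens),
      stringsAsFactors = FALSE
    )
    units$excluded <- units$word_count < min_words
    units$tokens <- tokens
  }
  if (anyDuplicated(units$unit_id))
    stop("internal error: duplicate unit_id")
  attr(units, "N") <- sum(!units$excluded)
  attr(units, "min_words") <- min_words
  class(units) <- c("dc_units", "data.frame")
  units
}

#' Number of included units in a dataset
#'
#' The normalisation denominator for census frequencies: units not flagged
#' excluded by the minimum-length rule.
#'
#' @param units A dataset from [extract_units()].
#' @return Integer count.
#' @export
dataset_size <- function(units) {
  n <- attr(units, "N")
  if (is.null(n)) sum(!units$excluded) else n
}

#' Write a unit manifest as TSV
#'
#' Columns: unit_id, article_id, granularity, section_class, word_count,
#' excluded. Token sequences are not serialised.
#'
#' @param units A dataset from [extract_units()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unit_manifest <- function(units, path) {
  df <- units[, c("unit_id", "article_id", "granularity", "section_class",
                  "word_count", "excluded")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
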