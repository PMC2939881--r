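#' @importFrom stats rnorm rpois runif setNames quantile qnorm pnorm cor lm
#'   coef qbinom
#' @importFrom utils head write.table read.delim
NULL

SECTION_CLASSES <- c("INTRODUCTION", "METHODS", "RESULTS_DISCUSSION", "OTHER")
GRANULARITIES <- c("FULLTEXT", "ABSTRACT", "SECTION", "PARAGRAPH")

# Default keyword table for IMRaD section classification. Titles are
# case-folded and matched by substring; precedence is row order (an
# "Introduction to methods" header classifies as INTRODUCTION).
DEFAULT_SECTION_KEYWORDS <- list(
  INTRODUCTION       = c("introduction", "background"),
  METHODS            = c("method", "materials", "experimental procedure"),
  RESULTS_DISCUSSION = c("result", "discussion", "conclusion")
)

#' Construct an article record
#'
#' The unit of the census: one structured publication with metadata, an
#' abstract and an ordered list of classified body sections. Articles with no
#' body sections are retained as citation-only records: they count toward the
#' corpus size but contribute no full-text, section or paragraph units.
#'
#' @param article_id Unique opaque identifier within a corpus.
#' @param title Article title.
#' @param abstract Abstract text; may be empty.
#' @param authors Character vector of author names ("Surname, Given" or
#'   "Given Surname"); may be empty, in which case the article is excluded
#'   from shared-author statistics.
#' @param journal Journal name.
#' @param year Publication year (integer >= 0).
#' @param pub_type Either "research" or "review".
#' @param sections List of sections from [section()].
#' @return An object of class `"dc_article"`.
#' @export
article <- function(article_id, title = "", abstract = "", authors = character(0),
                    journal = "", year = 0L, pub_type = c("research", "review"),
                    sections = list()) {
  pub_type <- match.arg(pub_type)
  stopifnot(is.character(article_id), length(article_id) == 1L, nzchar(article_id))
  year <- as.integer(year)
  if (is.na(year) || year < 0L) stop("year must be a non-negative integer")
  structure(
    list(article_id = article_id, title = title, abstract = abstract,
         authors = as.character(authors), journal = journal, year = year,
         pub_type = pub_type, sections = sections),
    class = "dc_article"
  )
}

#' Construct a body section
#'
#' @param title Section heading as printed.
#' @param paragraphs Character vector of paragraph texts.
#' @param section_class Optional explicit class; defaults to
#'   [classify_section()] applied to the title.
#' @return A list with `section_class`, `title` and `paragraphs`.
#' @export
section <- function(title, paragraphs, section_class = classify_section(title)) {
  section_class <- match.arg(section_class, SECTION_CLASSES)
  list(section_class = section_class, title = as.character(title),
       paragraphs = as.character(paragraphs))
}

#' Classify a section heading into an IMRaD class
#'
#' Matches keywords in the case-folded heading: INTRODUCTION for
#' introduction/background, METHODS for method(s)/materials/experimental
#' procedure, RESULTS_DISCUSSION for result(s)/discussion/conclusion(s),
#' OTHER otherwise. On multiple matches, precedence is
#' INTRODUCTION > METHODS > RESULTS_DISCUSSION. Total and deterministic.
#'
#' @param title Character vector of section headings (possibly empty strings).
#' @param keywords Keyword table; a named list of character vectors, in
#'   precedence order. Defaults to the package table.
#' @return Character vector of section classes.
#' @export
#' @examples
#' classify_section(c("Materials and Methods", "Results and Discussion", ""))
classify_section <- function(title, keywords = DEFAULT_SECTION_KEYWORDS) {
  title <- tolower(ifelse(is.na(title), "", title))
  out <- rep("OTHER", length(title))
  for (cls in rev(names(keywords))) {
    pat <- paste(keywords[[cls]], collapse = "|")
    out[grepl(pat, title, fixed = FALSE)] <- cls
  }
  out
}

#' Parse a JATS/NLM full-text article XML document
#'
#' Extracts the metadata, abstract and body sections of one article from
#' JATS (journal article tag suite) XML as distributed by PubMed Central.
#' Text content is concatenated with whitespace normalisation. Articles
#' lacking a `<body>` yield an empty section list (the citation-only case);
#' nested `<sec>` elements are flattened in document order with paragraphs
#' attached to the classified top-level section. `pub_type` is read from the
#' `article-type` attribute (review types map to "review"); when absent it
#' defaults to "research".
#'
#' @param x Path to an XML file, a string of XML, or an `xml2` document.
#' @return A [article()] object.
#' @export
parse_jats <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  ns <- xml2::xml_ns_strip(doc)

  text1 <- function(xpath, node = doc) {
    n <- xml2::xml_find_first(node, xpath)
    if (inherits(n, "xml_missing")) "" else squish(xml2::xml_text(n))
  }

  id <- text1(".//front//article-meta/article-id")
  if (!nzchar(id)) stop("JATS record rejected: missing <article-id>")

  atype <- xml2::xml_attr(xml2::xml_find_first(doc, "/article"), "article-type")
  pub_type <- if (!is.na(atype) && grepl("review", atype, ignore.case = TRUE))
    "review" else "research"

  contribs <- xml2::xml_find_all(
    doc, ".//front//contrib-group/contrib[not(@contrib-type) or @contrib-type='author']")
  authors <- vapply(contribs, function(cn) {
    sn <- text1(".//surname", cn)
    gn <- text1(".//given-names", cn)
    if (nzchar(gn)) paste0(sn, ", ", gn) else sn
  }, character(1))
  authors <- authors[nzchar(authors)]

  yr <- suppressWarnings(as.integer(text1(".//front//article-meta/pub-date/year")))
  if (is.na(yr)) yr <- 0L

  secs <- xml2::xml_find_all(doc, "./body/sec")
  sections <- lapply(secs, function(sn) {
    stitle <- text1("./title", sn)
    paras <- vapply(xml2::xml_find_all(sn, ".//p"), function(p)
      squish(xml2::xml_text(p)), character(1))
    section(stitle, paras[nzchar(paras)])
  })

  article(
    article_id = id,
    title = text1(".//front//article-meta//article-title"),
    abstract = text1(".//front//article-meta/abstract"),
    authors = authors,
    journal = text1(".//front//journal-meta//journal-title"),
    year = yr,
    pub_type = pub_type,
    sections = sections
  )
}

squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Write a corpus to the package's JSONL format
#'
#' One JSON record per line per article, schema: `id`, `title`, `abstract`,
#' `authors` (array), `journal`, `year`, `pub_type`, `sections` (array of
#' `{class, title, paragraphs[]}`). Round-trips exactly through
#' [read_corpus()].
#'
#' @param corpus List of [article()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(a) {
    jsonlite::toJSON(list(
      id = a$article_id, title = a$title, abstract = a$abstract,
      authors = a$authors, journal = a$journal, year = a$year,
      pub_type = a$pub_type,
      sections = lapply(a$sections, function(s)
        list(class = s$section_class, title = s$title, paragraphs = s$paragraphs))
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a corpus from the package's JSONL format
#'
#' @param path Path to a JSONL corpus written by [write_corpus()].
#' @return List of [article()] objects.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  corpus <- lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    secs <- lapply(r$sections, function(s)
      section(s$title, unlist(s$paragraphs, use.names = FALSE),
              section_class = s$class))
    article(r$id, title = r$title, abstract = r$abstract,
            authors = unlist(r$authors, use.names = FALSE) %||% character(0),
            journal = r$journal, year = r$year, pub_type = r$pub_type,
            sections = secs)
  })
  ids <- vapply(corpus, `[[`, character(1), "article_id")
  if (anyDuplicated(ids)) stop("duplicate article_id in corpus: ",
                               ids[duplicated(ids)][1L])
  corpus
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalised author keys for shared-author matching
#'
#' Each author name is reduced to a deterministic key: case-folded,
#' diacritic-stripped surname plus first initial of the given name. Two
#' articles "share an author" when their key sets intersect. Names are parsed
#' as "Surname, Given ..." when a comma is present, otherwise as
#' "Given ... Surname".
#'
#' @param x An [article()] object or a character vector of author names.
#' @return Character vector of unique keys of the form `"surname|g"`.
#' @export
#' @examples
#' author_keys(c("Smith, John A.", "GARCIA, Maria"))
author_keys <- function(x) {
  names_ <- if (inherits(x, "dc_article")) x$authors else as.character(x)
  if (length(names_) == 0L) return(character(0))
  keys <- vapply(names_, function(nm) {
    nm <- squish(nm)
    if (!nzchar(nm)) return(NA_character_)
    nm <- tolower(iconv(nm, from = "UTF-8", to = "ASCII//TRANSLIT"))
    nm <- gsub("[^a-z0-9, ]", "", nm)
    if (grepl(",", nm)) {
      parts <- strsplit(nm, ",")[[1L]]
      surname <- squish(parts[1L])
      given <- if (length(parts) > 1L) squish(parts[2L]) else ""
    } else {
      words <- strsplit(nm, " +")[[1L]]
      surname <- words[length(words)]
      given <- if (length(words) > 1L) words[1L] else ""
    }
    surname <- gsub(" ", "", surname)
    init <- if (nzchar(given)) substr(given, 1L, 1L) else ""
    if (!nzchar(surname)) return(NA_character_)
    paste0(surname, "|", init)
  }, character(1), USE.NAMES = FALSE)
  unique(keys[!is.na(keys)])
}

# named list article_id -> author key set, for scan/census plumbing
corpus_author_keys <- function(corpus) {
  setNames(lapply(corpus, author_keys),
           vapply(corpus, `[[`, character(1), "article_id"))
}

# small corpus accessors
corpus_ids <- function(corpus) vapply(corpus, `[[`, character(1), "article_id")
corpus_pub_types <- function(corpus)
  setNames(vapply(corpus, `[[`, character(1), "pub_type"), corpus_ids(corpus))
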