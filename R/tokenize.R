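#' Fixed English stopword list used by the tokenizer
#'
#' A fixed list of 127 high-frequency English function words removed during
#' tokenization. The list is frozen inside the package so that token streams,
#' term weights and similarity ratios are bit-reproducible across runs and
#' machines; it is deliberately small (function words only) so that domain
#' terms, including numbers and gene-like symbols, are always retained.
#'
#' @return Character vector of 127 lower-case stopwords.
#' @export
#' @examples
#' length(census_stopwords())
census_stopwords <- function() .STOPWORDS

.STOPWORDS <- c(
  "a", "about", "above", "after", "again", "against", "all", "also", "am",
  "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "cannot", "could",
  "did", "do", "does", "doing", "down", "during", "each", "few", "for",
  "from", "further", "had", "has", "have", "having", "he", "her", "here",
  "hers", "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "itself", "just", "may", "might", "more", "most", "must", "my", "no",
  "nor", "not", "now", "of",
  "off", "on", "once", "only", "or", "other", "our", "ours", "out", "over",
  "own", "same", "she", "should", "so", "some", "such", "than", "that",
  "the", "their", "theirs", "them", "then", "there", "these", "they",
  "this", "those", "through", "to", "too", "under", "until", "up", "upon",
  "very", "was", "we", "were", "what", "when", "where", "whether", "which",
  "while", "who", "whom", "why", "will", "with", "within", "without",
  "would", "you", "your", "yours"
)

#' Tokenize text for similarity comparison
#'
#' Case-folds, strips punctuation, splits on whitespace and removes the
#' package's fixed stopword list ([census_stopwords()]). Numbers are retained:
#' in methods text, numeric values (concentrations, cycle counts) carry reuse
#' signal. The tokenizer is order-preserving; the downstream score is
#' order-free but the generator's prefix-copy plants rely on token order.
#'
#' @param text Character vector; elements are tokenized independently.
#' @return For a single string, a character vector of tokens; for a vector,
#'   a list of token vectors.
#' @export
#' @examples
#' tokenize("The PCR was performed twice.")
tokenize <- function(text) {
  out <- lapply(text, tokenize_one)
  if (length(out) == 1L) out[[1L]] else out
}

tokenize_one <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  x <- tolower(x)
  # punctuation (incl. unicode) to space; keep letters and digits
  x <- gsub("[^[:alnum:]]+", " ", x)
  toks <- strsplit(trimws(x), " +", fixed = FALSE)[[1L]]
  toks[!(toks %in% .STOPWORDS) & nzchar(toks)]
}

# token count table as a named integer vector (term -> count)
token_counts <- function(tokens) {
  if (length(tokens) == 0L) return(integer(0))
  tab <- table(tokens)
  structure(as.integer(tab), names = names(tab))
}
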