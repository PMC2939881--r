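#' Pipeline run configuration
#'
#' Bundles every knob of a parse/simulate -> index -> scan -> census run.
#' The configuration is serialised into the header of every output file so
#' each artifact self-describes its provenance; defaults reproduce the
#' census's standard regime (similarity-ratio threshold 0.5, either-direction
#' pairing).
#'
#' @param input Either a path to a JSONL corpus ([write_corpus()] format) or
#'   a [generator_config()] to simulate from.
#' @param granularity Unit granularity for the main scan.
#' @param section_filter Optional section class restriction.
#' @param threshold,pairing,top_k Passed to [scan_config()].
#' @param min_words Minimum unit length; `NULL` = granularity default.
#' @param out_dir Output directory (created if missing).
#' @param contingency_granularity Second granularity scanned to build the
#'   abstract-vs-full-text style contingency table; `"ABSTRACT"` by default;
#'   `NA` disables it.
#' @return A list of class `"dc_run_config"`.
#' @export
run_config <- function(input, granularity = "SECTION", section_filter = NULL,
                       threshold = 0.5, pairing = "either", top_k = 1e6,
                       min_words = NULL, out_dir = tempfile("census_run_"),
                       contingency_granularity = "ABSTRACT") {
  if (is.character(input) && !file.exists(input))
    stop("input corpus not found: ", input)
  if (!is.character(input) && !inherits(input, "dc_generator_config"))
    stop("input must be a corpus path or a generator_config()")
  sc <- scan_config(threshold = threshold, top_k = top_k, pairing = pairing)
  structure(list(input = input, granularity = toupper(granularity),
                 section_filter = section_filter, scan = sc,
                 min_words = min_words, out_dir = out_dir,
                 contingency_granularity = contingency_granularity),
            class = "dc_run_config")
}

#' Run the full census pipeline
#'
#' Stages: obtain the corpus (read or simulate), extract units, build term
#' weights, run the thresholded all-vs-all scan, and compute census
#' statistics; additionally scans a second granularity (abstracts by
#' default) and cross-classifies article pairs into a 2x2 contingency table
#' with its log odds ratio and predictive metrics. Writes `corpus.jsonl`
#' (when simulated), `ledger.tsv` (when simulated), `units.tsv`,
#' `pairs.tsv`, `census.tsv` and `contingency.json` under `out_dir`.
#' Identical configuration and inputs give identical outputs. On failure the
#' partially written outputs are removed and the error names the stage.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage count messages.
#' @return Invisibly, a list with the output `paths`, stage `counts`, the
#'   `pairs` table, per-stratum `census` objects and the `contingency`
#'   summary.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "dc_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(...) if (!quiet) message(sprintf(...))
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  out <- function(name) file.path(config$out_dir, name)

  # --- corpus -------------------------------------------------------------
  syn <- NULL
  corpus <- tryCatch({
    if (is.character(config$input)) read_corpus(config$input)
    else {
      syn <- generate_corpus(config$input)
      syn$corpus
    }
  }, error = function(e) fail("corpus", e))
  if (!is.null(syn)) {
    write_corpus(corpus, out("corpus.jsonl"))
    write_ledger(syn, out("ledger.tsv"))
    written <- c(written, out("corpus.jsonl"), out("ledger.tsv"))
  }
  note("corpus: %d articles (%d review)", length(corpus),
       sum(corpus_pub_types(corpus) == "review"))

  # --- units --------------------------------------------------------------
  units <- tryCatch(
    extract_units(corpus, config$granularity,
                  section_filter = config$section_filter,
                  min_words = config$min_words),
    error = function(e) fail("units", e))
  write_unit_manifest(units, out("units.tsv"))
  written <- c(written, out("units.tsv"))
  note("units: %d %s units (%d excluded)", nrow(units), config$granularity,
       sum(units$excluded))

  # --- scan ---------------------------------------------------------------
  pairs <- tryCatch({
    weights <- build_weights(units)
    all_vs_all(units, config = config$scan, weights = weights,
               authors = corpus)
  }, error = function(e) fail("scan", e))
  write_pairs(pairs, out("pairs.tsv"), config = config$scan)
  written <- c(written, out("pairs.tsv"))
  note("scan: %d similar pairs at threshold %.2f", nrow(pairs),
       config$scan$threshold)

  # --- census -------------------------------------------------------------
  censuses <- tryCatch({
    N <- dataset_size(units)
    cls <- list(overall = census(pairs, N))
    for (sc in intersect(unique(pairs$section_class_a), SECTION_CLASSES)) {
      sp <- pairs[pairs$section_class_a == sc & pairs$section_class_b == sc, ]
      cls[[sc]] <- census(sp, N)
    }
    cls
  }, error = function(e) fail("census", e))
  write_census(censuses, out("census.tsv"))
  written <- c(written, out("census.tsv"))

  # --- contingency --------------------------------------------------------
  cont <- NULL
  cg <- config$contingency_granularity
  if (!is.na(cg) && toupper(cg) != config$granularity) {
    cont <- tryCatch({
      u2 <- extract_units(corpus, cg)
      w2 <- build_weights(u2)
      p2 <- all_vs_all(u2, config = config$scan, weights = w2,
                       authors = corpus)
      tab <- contingency(article_pairs(p2), article_pairs(pairs),
                         n_articles = length(corpus),
                         labels = c(cg, config$granularity))
      or <- log10_odds_ratio(tab, confidence = 0.99, haldane = TRUE)
      pm <- if (tab$a + tab$b > 0) prediction_metrics(tab) else NULL
      list(a = tab$a, b = tab$b, c = tab$c, d = tab$d,
           labels = tab$labels, log10_or = or$log10_or,
           half_width = or$half_width, corrected = or$corrected,
           ppv = if (is.null(pm)) NA else pm$ppv,
           ppv_ci = if (is.null(pm)) c(NA, NA) else unname(pm$ppv_ci),
           fnr = if (is.null(pm)) NA else pm$fnr)
    }, error = function(e) fail("contingency", e))
    jsonlite::write_json(cont, out("contingency.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    written <- c(written, out("contingency.json"))
  }

  invisible(list(
    paths = written,
    counts = list(articles = length(corpus), units = nrow(units),
                  excluded = sum(units$excluded), pairs = nrow(pairs)),
    pairs = pairs, census = censuses, contingency = cont, ledger = syn$ledger
  ))
}
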