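---
title: "A full-text similarity census: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A full-text similarity census: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupcensus)
```

## The problem

Duplicate publication in the biomedical literature ranges from legitimate
(updates, multi-part studies, republications) to unethical (co-submission,
plagiarism). At corpus scale it can only be surveyed computationally: every
article is compared against every other, pairs above a similarity threshold
are flagged, and the flagged set is summarised statistically — how often
reuse occurs at each level of a structured article, whether the authors
overlap, and how well similarity of one part (the abstract) predicts
similarity of another (the full text). `dupcensus` implements that survey
as a pipeline over four granularities of text unit: full texts, abstracts,
IMRaD-classified sections, and paragraphs.

## The similarity model

Each unit is tokenized: case-folded, punctuation stripped, split on
whitespace, and filtered against a fixed 127-word English stopword list
shipped with the package (`census_stopwords()`). Numbers are retained —
in methods text, numeric values carry reuse signal. The list is frozen so
token streams and every downstream statistic are reproducible bit for bit.

The score of a query $q$ against a subject $s$ is an order-free weighted
term overlap,

$$\mathrm{score}(q,s) \;=\; \sum_t w(t)\,\min\{c_q(t),\,c_s(t)\},
\qquad w(t) \;=\; \ln\!\frac{N+1}{\mathrm{df}(t)+1} + 1,$$

with $c_x(t)$ the count of term $t$ in $x$, $N$ the number of units in the
indexed dataset and $\mathrm{df}(t)$ the number of units containing $t$.
The smoothed inverse-document-frequency weight is strictly positive,
equals 1 for a term present in every unit, and grows for rarer terms, so
shared rare vocabulary dominates. The **similarity ratio**

$$R(q,s) \;=\; \frac{\mathrm{score}(q,s)}{\mathrm{score}(s,s)} \in [0,1]$$

normalises by the subject's self-score (its *identity score*). The ratio
is 1 exactly when the query's token multiset contains the subject's, and 0
when the vocabularies are disjoint. It is directional; a pair is flagged
when *either* direction reaches the threshold (the `either` pairing rule,
configurable to `both`), because a corpus-scale scan visits each pair from
both sides and retains any significant match.

Assumptions worth stating: the score is order-free (a bag-of-words
engine), so paraphrase and re-ordering are invisible to it — it measures
verbatim lexical reuse, the signal the census targets; and the ratio is
calibrated for units of roughly abstract size, which is why full texts are
also cut into sections and paragraphs before comparison.

### Why this scorer

The census methodology requires only that the engine produce an
identity-normalised ratio in $[0,1]$; keyword engines of this family are
proprietary or service-bound and their internals vary. The min-count
overlap was chosen because (a) it yields the required normalisation
exactly, (b) it is order-free like the retrieval engines it stands in for,
and (c) it admits an exact brute-force oracle, so the indexed scan can be
*proven* equal to a double-loop reference on any corpus. The scorer sits
behind a small interface (`similarity_score()`, `similarity_ratio()`) and
can be swapped.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `threshold` | 0.5 | ratio | calibrated operating point balancing sensitivity and specificity for abstract-sized text; ties count as similar (closed threshold) |
| `pairing` | `either` | — | a pair is significant if either scan direction clears the threshold |
| `top_k` | 400 | candidates | per-query candidate cap, ranked by shared index terms; the scan is exact whenever `top_k` ≥ dataset size, and every correctness test runs in that regime |
| `min_words` | 30 (paragraphs), 0 otherwise | tokens | tiny paragraphs yield unstable ratios; excluded units are kept in the manifest for audit but leave the normalisation denominator |
| `bin_width` | 0.05 | ratio | histogram granularity for the conditional ratio distributions |
| `confidence` | 0.99 (odds ratio), 0.95 (PPV) | — | matches the reporting conventions of the census statistics |

The threshold is closed ($R \ge \tau$): at corpus scale exact ties are
measure-zero, but the choice must be fixed for determinism, and closing it
errs toward review rather than omission.

## Census statistics and their conventions

* **Frequency of similar pairs** — detected pairs divided by the size of
  the query dataset (included units only). The denominator is always an
  explicit argument and is recorded in every output: published section
  datasets are known to carry off-by-a-few count ambiguities, so nothing
  downstream ever assumes a dataset size it was not handed.
* **SA/DA odds** — pairs sharing at least one author over pairs sharing
  none. Author identity is a normalised key: diacritic-stripped, case-folded
  surname plus first initial — the loosest rule that avoids trivial
  string-mismatch misses; articles with no author list are excluded from
  the odds and reported separately.
* **Contingency table** — article pairs cross-classified by two similarity
  conditions. The pair-space denominator uses the *ordered* convention
  $n(n-1)$, matching how an all-vs-all scan visits pairs from both
  directions; detected pairs themselves are stored unordered. Both
  conventions are exposed (`pair_space`, cell sums).
* **Log odds ratio** — $\log_{10}(ad/bc)$ with the standard large-sample
  interval, $z\sqrt{1/a+1/b+1/c+1/d}/\ln 10$, two-sided at the stated
  confidence. Zero cells are an error unless the Haldane 0.5 correction is
  enabled, in which case the result is flagged `corrected`.
* **Predictive metrics** — the fraction of condition-1 pairs that also
  satisfy condition 2 is a positive predictive value, $a/(a+b)$, reported
  with a Wilson score interval. (In parts of the screening literature the
  same fraction is called "specificity"; this package labels it PPV to be
  unambiguous.) The miss-rate among unflagged pairs is reported as
  $\mathrm{fnr} = c/(c+d)$ — the complement of the negative predictive
  value — because several incompatible "false negative rate" definitions
  exist; the convention is stated in the output.
* **Conditional probabilities** — among article pairs with a similar
  section of a class, the fraction that also have similar abstracts.
  Classes are compared with a pooled two-proportion z-test, one-sided by
  default: the scientific question is directional (are results sections a
  *stronger* abstract-similarity indicator?), and the one-sided test is
  also the convention under which the published comparison P-values
  reproduce. No multiplicity correction is applied by default, matching
  how such comparisons are conventionally presented; the test helper is
  exposed for corrected analyses.
* **Article-level collapse** — several similar paragraph pairs between the
  same two articles are one article pair for contingency and conditional
  statistics; section and paragraph censuses count unit pairs. Every
  output states its level.

## The synthetic corpus generator

The generator emulates the *statistical structure* the census assumes, not
natural language. Articles have a title, abstract, author list, journal,
year, publication type and Introduction/Methods/Results-Discussion
sections of abstract-sized paragraphs. Tokens are drawn from per-topic
Zipf-distributed vocabularies; distinct topics share no terms. Defaults
(chosen once, as study conditions):

* 20,000 terms per topic, Zipf exponent 0.6 — the vocabulary is much
  larger than a document, as in natural text, so unrelated same-topic
  articles overlap only through common terms: their full-text ratio sits
  near 0.12 (99th percentile ≈ 0.2), well below the 0.5 threshold, while
  cross-topic pairs sit at 0.
* 3 paragraphs per section (Poisson, min 1) of ~120 words (normal,
  sd = mean/5, min 20); abstracts ~150 words — the size regime the ratio
  is calibrated for.
* Review fraction 5,414/72,011 ≈ 7.5%, the review share of a large
  open-access full-text archive. Reviews share the IMRaD body structure of
  research articles and differ only in `pub_type`: the review census needs
  only the flag, and giving reviews a distinct structure would conflate
  structural and type effects.
* Authors drawn from a pool of 3× the corpus size; "shared" plants share
  exactly one author, "disjoint" plants none, by construction.

Planted duplicates copy a token *prefix* of fraction $f$ of each target
unit and resample the rest from the copier's own (disjoint) topic, so the
achieved overlap equals $f$ up to per-paragraph rounding — making the
calibration analytic: the planted pair's ratio responds linearly in $f$,
with $f=1$ giving exactly 1 and $f=0$ indistinguishable from background.
The ledger records every plant and is validated against the emitted corpus
by recounting token overlap at generation time. Two plant targets cover
the full-text/abstract dissociation: `article` copies abstract + body
(both conditions), `fulltext` copies the body only (full-text similarity
without abstract similarity), `abstract_only` the converse.

What passing tests on this generator do **not** show about real data: real
reuse is paraphrased, translated, partially rewritten; real "background"
similarity includes shared boilerplate, journal templates and common
methods phrasing, which an order-free scorer partially absorbs into its
document-frequency weights but does not eliminate; and real author
matching confronts homonyms and name variants that the surname+initial key
deliberately merges. Recovery rates of 100% at $f = 0.9$ are a property of
verbatim planting, not a claim about curated duplicate sets.

## Numerical choices

* The inverted index is a sparse term-by-unit count matrix. The exact scan
  uses the decomposition $\min(a,b) = \sum_{k\ge1} [a\ge k][b\ge k]$ —
  token counts are small integers — so the full score matrix is a short sum
  of sparse cross-products; the capped scan (`top_k` below the dataset
  size) retrieves candidates per query from the postings and scores them
  exactly. Both paths are compared against a brute-force double loop in
  the tests.
* Identity scores and overlap scores are accumulated in the same
  column-order summation, so $R(s,s) = 1$ holds exactly in floating point,
  and planted $f=1$ pairs score exactly 1.
* A unit whose tokens are all stopwords has identity score 0 and no
  defined ratio; `similarity_ratio()` refuses it by name, and scans skip
  such units.
* Degenerate inputs are rejected early with stage-named errors: empty
  datasets for weight building, $N = 0$ censuses, empty fixtures,
  infeasible duplication plans (more planted articles than the corpus
  holds).
* All randomness flows through R's RNG from a single integer seed;
  identical configuration and seed give byte-identical corpora, ledgers
  and pipeline outputs (asserted against committed golden files).

## Problem sizes used in validation

The test suite validates oracle equivalence on 30 random corpora of up to
500 units; ratio normalisation on 10⁴ random pairs; planted-rate recovery
on twenty 1,000-article corpora with per-section plants (frequencies must
fall within binomial 95% bounds of the planted rates in at least 19 of 20
seeds); calibration monotonicity over $f \in \{0, 0.25, 0.5, 0.75, 1\}$
with 30 replicates per point; and end-to-end determinism of a 40-article
simulate→scan→census run against golden files. These sizes exercise every
code path at desk scale; corpus-scale statistics (tens of thousands of
articles) are recomputed from published counts rather than re-simulated.

## Known limitations

* The scorer measures verbatim lexical overlap; paraphrase, translation
  and idea-level duplication are out of scope, as are sentence-level
  alignment and reuse highlighting.
* Section classification is keyword-based on headings
  (introduction/background; method/materials/experimental procedure;
  result/discussion/conclusion, with precedence in that order). Articles
  without IMRaD-style headings fall to `OTHER` and leave the section
  census, exactly as unclassifiable sections leave corpus-scale section
  datasets.
* JATS parsing flattens nested sections to their top-level heading's
  class and concatenates text with whitespace normalisation; tables,
  figures and references are taken as the XML's text content, not
  structurally modelled.
* Statistics on pairs are treated as independent counts; articles
  participating in many pairs induce dependence the binomial and
  large-sample intervals ignore. At census scale this is the standard
  approximation.
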