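---
title: "Dictionary and rule-based enzyme NER: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary and rule-based enzyme NER: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzner)
```

## The problem

Enzymes are named with an unusually regular vocabulary: most names end
in an "-ase" word (dehydrogenase, kinase, phosphatase, ...) that
encodes the catalysed reaction class, and the Enzyme Commission (EC)
numbering attaches a four-field identifier to each activity.  No
manually annotated enzyme corpus exists at the scale deep NER models
need, so `enzner` implements an automatic annotation pipeline that
exploits this nomenclature: a dictionary of known names organised as a
tree keyed by the root term, combined with rule-based fuzzy matching
around "-ase" words the dictionary does not cover.  The output is
stand-off annotations in BioC-JSON and, downstream, a token-labelled
training corpus.

## The hierarchical dictionary

`load_enzyme_list()` parses an EC-to-names nomenclature (a KEGG-style
flat file or a two-column TSV).  Names vary in separator usage
(hyphens vs spaces) and in Greek letters written as symbols or spelled
out; `expand_variants()` closes every name under both transformations,
so "beta-galactosidase" indexes four surface forms.  The closure is a
fixed point: expanding an output adds nothing.  A safety cap
(`max_variants = 512`) guards against pathological names; no real
nomenclature entry comes close.

`build_hierarchy()` buckets every expanded form into a branch keyed by
its lowercased final token — the *root term*.  Forms whose final token
does not end in "-ase" (lysozyme, trypsin, pepsin, ...) live in a
parallel set of branches.  Within a branch, forms sort by descending
token count, then descending character length, then lexicographically;
this total order is what makes greedy matching longest-first.  Each
branch also records its *vocabulary*: every non-final token seen in
that branch, which the fuzzy matcher reuses as evidence that a
preceding word belongs to an enzyme name.

Matching is case-insensitive (dictionary keys are lowercase;
annotations keep the article's casing).  The nomenclature itself does
not state a case convention, and biomedical mentions capitalise
freely, so insensitivity is the safer default.  Duplicate surface
forms with conflicting EC numbers keep the first EC and log the
conflict.

## The two-step search

Paragraphs are split into sentences with ICU sentence-boundary
analysis (stringi); offsets are 0-based character positions into the
whole article, per BioC convention.  The ICU rules do not break before
a lowercase continuation ("E. coli cultures ..." stays together),
which is the contract the rest of the pipeline relies on.

**Step 1, direct matching** (`direct_match()`): every token whose
lowercase form is a branch key anchors a lookup; branch forms are
tried longest-first against the token window ending at the anchor.
Overlap resolution is greedy — the longest span wins, ties go to the
leftmost — so "aliphatic alcohol dehydrogenase" suppresses the nested
"alcohol dehydrogenase".  The identifier is the form's EC number (root
word if the form has none).

**Step 2, keyword matching** (`keyword_match()`): tokens ending in
"-ase" that are not stoplisted and not inside a direct match seed a
fuzzy span.  The published description leaves the acceptance rule for
preceding words open; the reconstruction used here accepts a
preceding token iff it occurs in the root's branch vocabulary, or it
matches a chemical-modifier shape (letters/digits/hyphens/slashes,
e.g. "deoxycytidine", "Ser/Thr") *and* is not in a closed
function-word list (determiners, prepositions, common verbs) nor a
descriptive modifier ("human", "serum", "bacterial" — those only
enter via exact dictionary matches).  Extension takes the longest
acceptable contiguous run up to four tokens — over 99% of dictionary
"-ase" names have five words or fewer — and never crosses the
sentence start, a direct match, or non-hyphen punctuation.  Forward
extension appends at most one unit: a round-bracketed group
immediately after the root word, a bare integer ("carboxylesterase
2"), or a single Greek letter.  The default stoplist extends the two
published examples ("phase", "database") with the obvious English
"-ase" words (case, increase, disease, ...); it is a plain text file
(`inst/extdata/stoplist.txt`) and a `rule_config()` argument.

**Abbreviations** are consumed, not detected: a per-article JSON maps
short forms to definitions.  `find_enzyme_abbreviations()` runs the
two-step matcher over each definition and keeps short forms whose
definition contains an enzyme match covering the head word; their
occurrences are then annotated (word-bounded, case-sensitive — "ADH"
should not match inside "ADHESION") with the definition's identifier.
For training corpora, `replace_abbreviations()` substitutes the
definitions back into the text, recomputing all offsets.

Annotations carry exactly four elements — text, infons (identifier,
type, annotator, timestamp, matching method), id, locations — and
every location is validated to slice the article to the annotated
surface.

## Corpus building

`extract_tagged_sentences()` keeps only sentences overlapping an
annotation, tokenises them neutrally (whitespace split, punctuation
split off, hyphens kept inside words — model-specific subword
tokenisers are deliberately out of scope), and labels tokens in SOBIE
(`S` singleton, `B`/`I`/`E` multi-word, `O` outside) or BIO.  A token
overlapping an annotation by at least one character is inside the
entity.  Conversions between schemes go through entity spans, so
SOBIE→BIO→SOBIE is the identity on valid sequences.

`split_corpus()` stratifies by domain with ratios 75:10:15 and the
rounding rule `validation = floor(0.10 n)`, `test = floor(0.15 n)`,
`train = n − validation − test`.  This rule was chosen because it
reproduces the published per-domain counts exactly (e.g. a
1006-article domain gives 756/100/150).  Counts depend only on `n`;
membership is randomised by the seed.

## Scoring

`classify_matches()` pairs predictions with gold annotations greedily
in document order, one-to-one.  Exact span-and-text agreement is a TP.
An overlapping pair where one surface is the other's root-term suffix
("kinase" vs "Ser/Thr kinase") or differs only by a trailing isoform
marker (number, single letter, roman numeral, Greek letter) is a
*partial positive* (PP).  `scores()` gives PPs half credit:
`tp' = tp + pp/2`, `fn' = fn + pp/2`, and by default also
`fp' = fp + pp/2`.  The published description mentions splitting PPs
"between TP and FN" in one place and "between TP and FP/FN (as
appropriate)" in another; the default follows the latter (and
MUC-style half credit), and `pp_in_fp = FALSE` selects the former.
True negatives are never counted — scoring operates on annotation
sets, not token grids, so the O-majority cannot inflate the scores.

Inter-annotator agreement is a Jaccard index at two levels: *entity*
(exact offset+length+text matches over the union of annotations) and
*character* (Jaccard of the annotated character-position sets, the
overlap-tolerant measure).  Cohen's kappa is intentionally absent: it
needs true negatives, which are ill-defined and overwhelming in NER.

## The synthetic corpus generator

`generate_corpus()` emulates the *shape* of a full-text enzyme corpus:
IAO-labelled sections, a domain mix matching the observed proportions
of GWAS/proteomics/metabolomics/microbiome articles (0.251/0.127/
0.285/0.337), 20–40 sentences per article, and per-sentence planting
of enzymes (default rate 0.4), stoplist confounders (0.3), and
abbreviation introductions (0.2 of verbatim plants).  Plants come in
three kinds: verbatim dictionary forms, expanded spelling variants,
and root-word-plus-unseen-modifier constructions
("phosphoribosyl kinase") that only the keyword step can find.
Carrier sentences use realistic prose whose words precede plants with
function words, so the backward-extension blocker is exercised.  The
generator self-checks that every gold span slices the document text
to its surface, and it is deterministic given the seed.

What the generator does *not* emulate: real PMC prose statistics,
tables, OCR noise, nested or discontinuous mentions, sentence-initial
lowercase enzymes, and the long tail of ad-hoc naming in real
articles.  Perfect precision/recall on planted verbatim forms
therefore validates the machinery (offsets, greediness, stoplist,
abbreviation plumbing), not real-world recall, which on a manually
annotated test set is bounded by dictionary coverage.

## Numerical and degenerate-input choices

* Offsets are 0-based character counts; all slicing is
  character-based, so Greek symbols count as one position.
* Empty paragraphs split into zero sentences; empty annotation sets
  score 0 across the board rather than NaN.
* `split_corpus()` floors both held-out sets, so tiny strata
  (n < 10) degenerate gracefully to all-train.
* Branch sorting breaks ties by character length then
  lexicographically, making dictionary construction independent of
  input order.
* The per-call annotation timestamp can be pinned
  (`rule_config(timestamp = ...)`) to make outputs byte-reproducible.

## Problem sizes used in the test suite

The property suites run on generated corpora of 10–40 articles
(roughly 1,200 sentences for the matcher-equivalence check against a
brute-force flat scan, and 200 random set pairs for the metric
oracle).  These sizes give every code path multiple hits while keeping
the default test run fast; all thresholds asserted by the suite
(precision/recall 1.0 on verbatim plants, exact split counts, exact
table sums) are invariant to making the corpora larger.

## Known limitations

* Keyword acceptance is a reconstruction; genuinely ambiguous
  premodifiers ("total kinase activity") can over- or under-extend.
* Entities split across sentence-boundary errors are unfindable by
  construction.
* EC identifiers are carried, not validated against the EC ontology;
  conflicting duplicate forms resolve first-wins.
* Table text is not annotated; only passages are processed.
* A metabolite-NER post-filter is a documented hook, not implemented.
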