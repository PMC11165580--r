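# enzner — dictionary and rule-based enzyme named entity recognition

`enzner` annotates enzyme mentions in full-text biomedical articles.
It is aimed at text-mining practitioners who need an enzyme-specific
training corpus or a fast, high-precision tagger without a GPU: no
annotated enzyme corpus exists at scale, but enzyme nomenclature is
regular enough (most names end in an "-ase" root term; EC numbers
identify activities) that a dictionary-plus-rules pipeline annotates a
full-text article in well under a second.

The core is a two-step search over a **hierarchical dictionary**:
every surface form (expanded over hyphen/space and Greek-letter
spelling variants) is bucketed into a branch keyed by its final token
(its *root term*, e.g. `dehydrogenase`), with branch entries sorted
longest-first.

1. **Direct matching** — greedy longest exact match of dictionary
   forms, so a term nested in a longer matched term is never selected
   ("aliphatic alcohol dehydrogenase", not the inner "alcohol
   dehydrogenase"); the identifier is the form's EC number.
2. **Keyword matching** — any remaining non-stoplisted "-ase" token
   seeds a fuzzy span, extended backward over up to four
   branch-vocabulary or chemical-modifier tokens and forward over one
   bracketed group, bare integer, or Greek letter; the identifier is
   the root word.

Enzyme **abbreviations** are resolved from each article's short-form →
definition map and annotated wherever they occur.  Downstream, the
package exports SOBIE/BIO-tagged sentences (CoNLL style), stratified
75:10:15 corpus splits, and evaluation: precision/recall/F1 with
MUC-style half credit for *partial positives* (root-only or
isoform-truncated matches),

    P = (TP + PP/2) / (TP + PP/2 + FP + PP/2),
    R = (TP + PP/2) / (TP + PP/2 + FN + PP/2),
    F1 = 2PR / (P + R),

and Jaccard inter-annotator agreement at entity (exact) and character
(overlap) level.  A seeded synthetic-corpus generator with planted
gold mentions makes everything testable offline.

## Worked example

```r
library(enzner)
dict <- mini_dictionary()   # bundled ~230-record nomenclature fixture
dict
#> <enzyme_dictionary> 1112 forms in 510 '-ase' branches + 81 other branches

doc <- bioc_document("PMC0012345", list(bioc_passage(
  paste("Serum gamma-glutamyl transpeptidase (γGT) and deoxycytidine kinase",
        "were elevated, while the database phase was unchanged.",
        "γGT activity doubled by week six."),
  0L, section_label = "results")))

doc <- annotate_document(doc, dict,
                         abbrevs = c("γGT" = "gamma-glutamyl transpeptidase"))
doc_annotations(doc)[, c("id", "text", "identifier", "method", "offset", "length")]
#>   id                          text identifier       method offset length
#> 1  1 gamma-glutamyl transpeptidase    2.3.2.2       direct      6     29
#> 2  2                           γGT    2.3.2.2 abbreviation     37      3
#> 3  3          deoxycytidine kinase     kinase      keyword     46     20
#> 4  4                           γGT    2.3.2.2 abbreviation    122      3
```

The dictionary form is found directly and carries its EC number;
"deoxycytidine kinase" is not in the dictionary, so the keyword step
builds the span around the root word `kinase`; the abbreviation is
resolved from its definition and annotated at both occurrences; the
stoplisted words "database" and "phase" are ignored.  Offsets are
0-based character positions into the article, and each annotation's
text always equals the article slice at its location.

Scoring with partial-positive half credit:

```r
print(scores(match_counts(tp = 7, fp = 1, fn = 1, pp = 2)))
#> precision = 0.800  recall = 0.800  F1 = 0.800

sp <- split_corpus(sprintf("PMC%07d", 1:1006), seed = 42)
sp$counts
#>   domain    n train validation test
#> 1    all 1006   756        100  150
```

## Command line

```sh
enzner build-dict --input enzymes.tsv --dialect tsv --output dict.json
enzner annotate --input docs/ --dict dict.json --abbrev abbrevs/ --output annotated/
enzner corpus --input annotated/ --scheme sobie --output corpus.conll
enzner eval --pred annotated/ --gold gold/ --report report.json
enzner synth --n-docs 50 --seed 7 --out synth/
```

(`exec/enzner` is an Rscript; call it via its installed path,
`system.file("exec", "enzner", package = "enzner")`.)

See `vignettes/enzyme-ner.Rmd` for the model, the rule reconstruction
and its assumptions, parameter defaults, and known limitations.
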