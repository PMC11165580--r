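test_that("enzyme abbreviations are replaced by definitions with consistent offsets", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  doc <- one_passage_doc("ADH rose quickly.")
  doc <- annotate_document(doc, d, abbrevs = c(ADH = "alcohol dehydrogenase"),
                           cfg = cfg)
  out <- replace_abbreviations(doc, c(ADH = "alcohol dehydrogenase"))
  expect_equal(out$passages[[1]]$text, "alcohol dehydrogenase rose quickly.")
  ann <- doc_annotations(out)
  expect_equal(ann$text, "alcohol dehydrogenase")
  expect_equal(ann$offset, 0L)

  # text without abbreviations is untouched
  plain <- one_passage_doc("Nothing here.")
  expect_equal(replace_abbreviations(plain, c(ADH = "alcohol dehydrogenase")),
               plain)
})

test_that("two abbreviations in one sentence are both replaced and re-verifiable", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  txt <- paste("Alcohol dehydrogenase (ADH) and alkaline phosphatase (ALP)",
               "were assayed; ADH and ALP both rose.")
  doc <- one_passage_doc(txt)
  ab <- c(ADH = "alcohol dehydrogenase", ALP = "alkaline phosphatase")
  doc <- annotate_document(doc, d, abbrevs = ab, cfg = cfg)
  out <- replace_abbreviations(doc, ab)
  # independent substitution oracle on the raw string
  expected <- gsub("\\bADH\\b", "alcohol dehydrogenase", txt)
  expected <- gsub("\\bALP\\b", "alkaline phosphatase", expected)
  expect_equal(out$passages[[1]]$text, expected)
  expect_silent(validate_bioc(out)) # every annotation re-slices correctly
  # re-annotating the replaced text finds entities at the same places
  re_ann <- doc_annotations(annotate_document(
    one_passage_doc(expected), d, cfg = cfg))
  ann <- doc_annotations(out)
  expect_setequal(sprintf("%d:%d", ann$offset, ann$length),
                  sprintf("%d:%d", re_ann$offset, re_ann$length))
})

test_that("tag induction follows the SOBIE and BIO definitions", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  doc <- annotate_document(
    one_passage_doc("Alcohol dehydrogenase activity. Catalase only."),
    d, cfg = cfg)
  sob <- extract_tagged_sentences(doc, "sobie")
  expect_length(sob, 2L)
  expect_equal(sob[[1]]$tags, c("B", "E", "O", "O"))
  expect_equal(sob[[2]]$tags, c("S", "O", "O")) # one-word entity -> singleton
  bio <- extract_tagged_sentences(doc, "bio")
  expect_equal(bio[[1]]$tags, c("B", "I", "O", "O"))
  expect_equal(bio[[2]]$tags, c("B", "O", "O"))

  # sentences without entities are excluded
  doc2 <- annotate_document(
    one_passage_doc("Catalase rose. Nothing here. Lysozyme fell."),
    d, cfg = cfg)
  ids <- vapply(extract_tagged_sentences(doc2, "sobie"),
                function(s) s$sentence_id, "")
  expect_length(ids, 2L)
  expect_equal(sub(".*:", "", ids), c("1", "3"))
})

test_that("sentence ids carry PMCID, section, paragraph and index", {
  d <- tiny_dict()
  doc <- annotate_document(one_passage_doc("Hexokinase was assayed."),
                           d, cfg = fixed_cfg())
  s <- extract_tagged_sentences(doc, "sobie")
  expect_equal(s[[1]]$sentence_id, "PMC0000001:results:1:1")
})

test_that("tag sequences convert between schemes through entity spans", {
  expect_equal(sobie_to_bio(c("B", "I", "E", "O", "S")),
               c("B", "I", "I", "O", "B"))
  expect_equal(bio_to_sobie(c("B", "I", "I", "O", "B")),
               c("B", "I", "E", "O", "S"))
  expect_error(tags_to_spans(c("B", "O"), "sobie"), "invalid")
  expect_error(tags_to_spans(c("I", "O"), "bio"), "invalid")

  # property: SOBIE -> BIO -> spans -> SOBIE is the identity
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    spans <- list()
    pos <- 1L
    while (pos <= n) {
      if (stats::runif(1) < 0.5) {
        len <- sample(1:min(3, n - pos + 1L), 1)
        spans[[length(spans) + 1L]] <- c(pos, pos + len - 1L)
        pos <- pos + len + 1L
      } else {
        pos <- pos + 1L
      }
    }
    sob <- spans_to_tags(n, spans, "sobie")
    expect_equal(bio_to_sobie(sobie_to_bio(sob)), sob)
    expect_equal(tags_to_spans(sob, "sobie"), spans)
  }
})

test_that("tagged sentences decode back to the spans they encode", {
  d <- cached_mini_dict()
  cfg <- fixed_cfg()
  corpus <- generate_corpus(synth_spec(n_docs = 3L, seed = 5L), d)
  for (pmcid in names(corpus$docs)) {
    doc <- annotate_document(corpus$docs[[pmcid]], d,
                             corpus$abbrevs[[pmcid]], cfg)
    for (s in extract_tagged_sentences(doc, "sobie")) {
      spans <- tags_to_spans(s$tags, "sobie")
      expect_gt(length(spans), 0L)
      expect_equal(spans_to_tags(length(s$tokens), spans, "sobie"), s$tags)
    }
  }
})

test_that("75:10:15 split reproduces the published per-domain counts", {
  # metabolomics: 1006 -> 756/100/150
  sp <- split_corpus(sprintf("doc%04d", 1:1006), seed = 3L)
  expect_equal(sp$counts$train, 756L)
  expect_equal(sp$counts$validation, 100L)
  expect_equal(sp$counts$test, 150L)
  # GWAS: 884 -> 664/88/132
  sp <- split_corpus(sprintf("doc%04d", 1:884), seed = 3L)
  expect_equal(unlist(sp$counts[c("train", "validation", "test")],
                      use.names = FALSE), c(664L, 88L, 132L))
  # tiny corpus by the same rounding rule: 20 -> 15/2/3
  sp <- split_corpus(sprintf("d%02d", 1:20), seed = 3L)
  expect_equal(unlist(sp$counts[c("train", "validation", "test")],
                      use.names = FALSE), c(15L, 2L, 3L))
})

test_that("the split is a partition and its counts are seed independent", {
  ids <- sprintf("doc%03d", 1:137)
  domains <- rep(c("GWAS", "proteomics", "metabolomics"), length.out = 137)
  for (seed in c(1L, 99L)) {
    sp <- split_corpus(ids, domains, seed = seed)
    expect_setequal(c(sp$train, sp$validation, sp$test), ids)
    expect_equal(length(sp$train) + length(sp$validation) + length(sp$test),
                 137L)
    expect_equal(anyDuplicated(c(sp$train, sp$validation, sp$test)), 0L)
  }
  c1 <- split_corpus(ids, domains, seed = 1L)$counts
  c2 <- split_corpus(ids, domains, seed = 99L)$counts
  expect_equal(c1, c2)
  # membership does change with the seed
  expect_false(identical(split_corpus(ids, domains, seed = 1L)$train,
                         split_corpus(ids, domains, seed = 99L)$train))
})

test_that("corpus statistics recover planted totals and stay additive", {
  d <- cached_mini_dict()
  cfg <- fixed_cfg()
  corpus <- generate_corpus(synth_spec(n_docs = 6L, seed = 21L), d)
  docs <- lapply(names(corpus$docs), function(id) {
    annotate_document(corpus$docs[[id]], d, corpus$abbrevs[[id]], cfg)
  })
  st <- corpus_stats(docs)
  planted <- vapply(docs, function(dd) nrow(doc_annotations(dd)), 1L)
  tot <- st$per_domain[st$per_domain$domain == "total", ]
  expect_equal(tot$entities, sum(planted))
  expect_equal(tot$articles, length(docs))
  expect_equal(sum(st$per_domain$entities[st$per_domain$domain != "total"]),
               tot$entities)
  # each root-term row sums to its own total; the word-count buckets
  if (nrow(st$root_terms)) {
    expect_equal(st$root_terms$`1` + st$root_terms$`2` +
                   st$root_terms$`3` + st$root_terms$`>3`,
                 st$root_terms$total)
  }
  # empty corpus gives zeros
  st0 <- corpus_stats(list())
  expect_equal(st0$per_domain$entities, 0L)
  expect_equal(nrow(st0$root_terms), 0L)
})

test_that("CoNLL export round trips and handles the empty corpus", {
  d <- tiny_dict()
  doc <- annotate_document(
    one_passage_doc("Hexokinase rose. Catalase fell in serum."),
    d, cfg = fixed_cfg())
  sents <- extract_tagged_sentences(doc, "sobie")
  f <- withr::local_tempfile(fileext = ".conll")
  write_conll(sents, f)
  expect_equal(read_conll(f), sents)

  write_conll(list(), f)
  expect_equal(file.size(f), 0)
  expect_equal(read_conll(f), list())
})
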