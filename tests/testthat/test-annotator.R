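test_that("sentence splitting yields global 0-based offsets", {
  s <- split_sentences("Kinases act. Phosphatases too.", 100L)
  expect_length(s, 2L)
  # "Kinases act." is 12 chars at 100..111, space at 112, next at 113
  expect_equal(vapply(s, function(x) x$start_offset, 1L), c(100L, 113L))
  expect_equal(s[[2]]$text, "Phosphatases too.")

  expect_equal(split_sentences("", 0L), list())

  one <- split_sentences("no terminal period here", 7L)
  expect_length(one, 1L)
  expect_equal(one[[1]]$text, "no terminal period here")
  expect_equal(one[[1]]$start_offset, 7L)
})

test_that("sentence tokens are non-overlapping, ascending, and in range", {
  for (txt in c("Alkaline phosphatase (ALP) rose.",
                "A 3-fold rise; then, a fall.",
                "E. coli cultures grew overnight.")) {
    for (sent in split_sentences(txt, 50L)) {
      tk <- sent$tokens
      if (nrow(tk) < 2L) next
      expect_true(all(diff(tk$start0) > 0))
      expect_true(all(tk$end0[-nrow(tk)] <= tk$start0[-1]))
      expect_true(all(tk$start0 >= sent$start_offset))
      expect_true(all(tk$end0 <= sent$start_offset + nchar(sent$text)))
    }
  }
})

test_that("direct matching is greedy: nested terms never co-selected", {
  d <- tiny_dict()
  sent <- split_sentences(
    "aliphatic alcohol dehydrogenase activity was measured", 0L)[[1]]
  m <- direct_match(sent, d)
  expect_equal(nrow(m), 1L)
  expect_equal(m$surface, "aliphatic alcohol dehydrogenase")
  expect_equal(m$identifier, "1.1.1.1")

  sent2 <- split_sentences("no enzymes mentioned here at all", 0L)[[1]]
  expect_equal(nrow(direct_match(sent2, d)), 0L)
})

test_that("repeated mentions produce one match per occurrence", {
  d <- tiny_dict()
  txt <- "alcohol dehydrogenase and alcohol dehydrogenase"
  sent <- split_sentences(txt, 0L)[[1]]
  m <- direct_match(sent, d)
  # independent brute-force scan for all occurrences
  locs <- stringi::stri_locate_all_fixed(txt, "alcohol dehydrogenase")[[1]]
  expect_equal(nrow(m), nrow(locs))
  expect_equal(m$start, locs[, 1] - 1L)
})

test_that("direct matching is case-insensitive but keeps article casing", {
  d <- tiny_dict()
  sent <- split_sentences("Alkaline Phosphatase was raised.", 0L)[[1]]
  m <- direct_match(sent, d)
  expect_equal(m$surface, "Alkaline Phosphatase")
  expect_equal(m$identifier, "3.1.3.1")
})

test_that("keyword matching grows spans around unmatched root words", {
  d <- tiny_dict()
  cfg <- fixed_cfg()

  sent <- split_sentences("deoxycytidine kinase was upregulated", 0L)[[1]]
  dm <- direct_match(sent, d)
  expect_equal(nrow(dm), 0L) # not a dictionary form
  km <- keyword_match(sent, d, cfg, dm)
  expect_equal(km$surface, "deoxycytidine kinase")
  expect_equal(km$identifier, "kinase")
  expect_equal(km$method, "keyword")

  sent <- split_sentences("the database was queried", 0L)[[1]]
  expect_equal(nrow(keyword_match(sent, d, cfg, direct_match(sent, d))), 0L)

  # single-number forward rule
  sent <- split_sentences("carboxylesterase 2 is expressed", 0L)[[1]]
  km <- keyword_match(sent, d, cfg, direct_match(sent, d))
  expect_equal(km$surface, "carboxylesterase 2")
})

test_that("backward extension stops at function words, punctuation and caps at 4", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  sent <- split_sentences("we measured the dehydrogenase there", 0L)[[1]]
  km <- keyword_match(sent, d, cfg, direct_match(sent, d))
  expect_equal(km$surface, "dehydrogenase")

  sent <- split_sentences("citrate, synthase", 0L)[[1]]
  km <- keyword_match(sent, d, cfg, direct_match(sent, d))
  expect_equal(km$surface, "synthase") # comma blocks the extension

  sent <- split_sentences(
    "one two three four five six deoxyguanosine kinase", 0L)[[1]]
  km <- keyword_match(sent, d, cfg, direct_match(sent, d))
  # at most 4 preceding tokens absorbed
  expect_lte(stringi::stri_count_regex(km$surface, "\\S+"), 5L)
})

test_that("forward extension accepts one bracketed group or Greek letter", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  sent <- split_sentences("phospholipase (acidic) was assayed", 0L)[[1]]
  km <- keyword_match(sent, d, cfg, direct_match(sent, d))
  expect_equal(km$surface, "phospholipase (acidic)")

  sent <- split_sentences("amylase α was assayed", 0L)[[1]]
  km <- keyword_match(sent, d, cfg, direct_match(sent, d))
  expect_equal(km$surface[1], "amylase α")

  # a plain word after the root is never absorbed
  sent <- split_sentences("protease activity was assayed", 0L)[[1]]
  km <- keyword_match(sent, d, cfg, direct_match(sent, d))
  expect_equal(km$surface, "protease")
})

test_that("keyword matches never overlap direct matches", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  sent <- split_sentences(
    "serum alkaline phosphatase and deoxycytidine kinase rose", 0L)[[1]]
  dm <- direct_match(sent, d)
  km <- keyword_match(sent, d, cfg, dm)
  expect_equal(dm$surface, "alkaline phosphatase")
  expect_equal(km$surface, "deoxycytidine kinase")
  a <- rbind(dm[c("start", "length")], km[c("start", "length")])
  a <- a[order(a$start), ]
  expect_true(all(a$start[-1] >= (a$start + a$length)[-nrow(a)]))
})

test_that("enzyme abbreviations are recognized from their definitions", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  found <- find_enzyme_abbreviations(
    c("γGT" = "gamma-glutamyl transpeptidase",
      CSF = "cerebrospinal fluid",
      ADH = "alcohol dehydrogenase"), d, cfg)
  expect_setequal(names(found), c("γGT", "ADH"))
  expect_equal(found$ADH$identifier, "1.1.1.1")
  expect_equal(found$`γGT`$identifier, "2.3.2.2")
  expect_equal(find_enzyme_abbreviations(character(0), d, cfg), list())
})

test_that("document annotation plants ids, offsets and slices consistently", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  doc <- bioc_document("PMC1", list(
    bioc_passage("Catalase and lysozyme were assayed. Hexokinase too.",
                 0L, "results"),
    bioc_passage("Nothing enzymatic in this paragraph.", 53L, "discussion")))
  out <- annotate_document(doc, d, cfg = cfg)
  ann <- doc_annotations(out)
  expect_equal(ann$text, c("Catalase", "lysozyme", "Hexokinase"))
  expect_equal(ann$id, as.character(1:3))
  # verify every annotation by slicing the passage text
  full <- doc_text(out)
  for (i in seq_len(nrow(ann))) {
    expect_equal(stringi::stri_sub(full, ann$offset[i] + 1L,
                                   ann$offset[i] + ann$length[i]),
                 ann$text[i])
  }
})

test_that("a document with no enzymes round trips unchanged", {
  d <- tiny_dict()
  doc <- one_passage_doc("Plain text with no mentions at all.")
  out <- annotate_document(doc, d, cfg = fixed_cfg())
  expect_equal(nrow(doc_annotations(out)), 0L)
  f <- withr::local_tempfile(fileext = ".json")
  write_bioc(out, f)
  expect_equal(read_bioc(f), out)
})

test_that("abbreviation occurrences are annotated wherever they appear", {
  d <- tiny_dict()
  cfg <- fixed_cfg()
  txt <- paste("Alcohol dehydrogenase (ADH) was assayed.",
               "ADH rose. Then ADH fell. Finally ADH stabilised.")
  doc <- one_passage_doc(txt)
  out <- annotate_document(doc, d, abbrevs = c(ADH = "alcohol dehydrogenase"),
                           cfg = cfg)
  ann <- doc_annotations(out)
  # independent substring count of the short form
  n_occ <- nrow(stringi::stri_locate_all_fixed(txt, "ADH")[[1]])
  expect_equal(sum(ann$method == "abbreviation"), n_occ)
  expect_equal(sum(ann$method == "direct"), 1L)
  expect_true(all(ann$identifier == "1.1.1.1"))
})

test_that("only configured sections are annotated", {
  d <- tiny_dict()
  doc <- bioc_document("PMC2", list(
    bioc_passage("Catalase here.", 0L, "results"),
    bioc_passage("Catalase there.", 15L, "acknowledgements")))
  ann <- doc_annotations(annotate_document(doc, d, cfg = fixed_cfg()))
  expect_equal(ann$section_label, "results")
})

test_that("annotation is deterministic and annotations never overlap", {
  d <- cached_mini_dict()
  cfg <- fixed_cfg()
  corpus <- generate_corpus(synth_spec(n_docs = 4L, seed = 11L), d)
  for (pmcid in names(corpus$docs)) {
    a1 <- annotate_document(corpus$docs[[pmcid]], d,
                            corpus$abbrevs[[pmcid]], cfg)
    a2 <- annotate_document(corpus$docs[[pmcid]], d,
                            corpus$abbrevs[[pmcid]], cfg)
    expect_equal(a1, a2)
    ann <- doc_annotations(a1)
    if (nrow(ann) > 1L) {
      ann <- ann[order(ann$offset), ]
      expect_true(all(ann$offset[-1] >=
                        (ann$offset + ann$length)[-nrow(ann)]))
    }
    expect_silent(validate_bioc(a1))
  }
})
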