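# Seeded synthetic-corpus generator: BioC documents with planted gold
# enzyme mentions, stoplist confounders and abbreviation pairs, so the
# whole pipeline is testable without any download.

#' Synthetic corpus specification
#'
#' The defaults emulate the shape of the published enzyme corpus: the
#' domain weights are the observed proportions of GWAS, proteomics,
#' metabolomics and microbiome articles; entity and confounder rates
#' approximate a-few-mentions-per-paragraph full-text density.
#'
#' @param n_docs Number of articles to generate.
#' @param domains Named weights over the four biomedical domains
#'   (must sum to 1).
#' @param sentences_per_doc Integer range `c(min, max)` of sentences
#'   per article.
#' @param entity_rate Probability that a sentence carries a planted
#'   enzyme mention.
#' @param confounder_rate Probability that a non-entity sentence carries
#'   a stoplisted "-ase" word (phase, database, ...).
#' @param abbreviation_rate Probability that a planted verbatim enzyme
#'   is introduced with an abbreviation (and re-mentioned by it).
#' @param plant_weights Mix of plant kinds: `verbatim` dictionary forms,
#'   spelling `variant` forms, and `keyword` (root word + unseen
#'   modifier) constructions that only fuzzy matching can find.
#' @param seed Integer RNG seed; generation is deterministic given the
#'   spec.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_docs = 20L,
                       domains = c(GWAS = 0.251, proteomics = 0.127,
                                   metabolomics = 0.285,
                                   microbiome = 0.337),
                       sentences_per_doc = c(20L, 40L),
                       entity_rate = 0.4,
                       confounder_rate = 0.3,
                       abbreviation_rate = 0.2,
                       plant_weights = c(verbatim = 0.6, variant = 0.2,
                                         keyword = 0.2),
                       seed = 1L) {
  stopifnot(n_docs >= 1L,
            abs(sum(domains) - 1) < 1e-6,
            length(sentences_per_doc) == 2L,
            sentences_per_doc[1] >= 1L,
            sentences_per_doc[1] <= sentences_per_doc[2],
            entity_rate >= 0, confounder_rate >= 0,
            abbreviation_rate >= 0, abbreviation_rate <= 1,
            abs(sum(plant_weights) - 1) < 1e-6,
            all(plant_weights >= 0))
  structure(
    list(n_docs = as.integer(n_docs), domains = domains,
         sentences_per_doc = as.integer(sentences_per_doc),
         entity_rate = entity_rate, confounder_rate = confounder_rate,
         abbreviation_rate = abbreviation_rate,
         plant_weights = plant_weights, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

entity_templates <- function() {
  c("The activity of %s was quantified in all samples.",
    "We observed that %s was significantly higher in patients.",
    "Levels of %s correlated strongly with the clinical outcome.",
    "Treatment lowered the abundance of %s in the intervention arm.",
    "Analysis suggested that %s plays a central role in this pathway.",
    "Serum samples were assayed for %s at baseline and follow-up.",
    "In contrast, %s did not differ between the two groups.",
    "Notably, %s remained detectable throughout the experiment.")
}

confounder_templates <- function() {
  c("This phase of the study relied on the public reference database.",
    "In any case, the observed increase did not reach significance.",
    "The release of the metabolite coincided with disease onset.",
    "We queried the database again during the validation phase.",
    "A further decrease was noted at the final visit in this case.")
}

plain_templates <- function() {
  c("Participants were recruited from two independent centres.",
    "Statistical analysis followed a prespecified protocol.",
    "Samples were frozen immediately and thawed once before analysis.",
    "The cohort comprised adults of both sexes without comorbidity.",
    "Raw intensities were normalised prior to further modelling.",
    "Ethical approval was obtained from the institutional board.")
}

unseen_modifiers <- function() {
  c("deoxycytidine", "phosphoribosyl", "methylmalonyl", "hydroxyacyl",
    "acetylneuraminate", "carboxyvinyl", "glucuronosyl",
    "imidazoleglycerol", "aminolevulinate", "hydroxymethylglutaryl")
}

# forms the tokenizer can rediscover in running text: every
# space-separated token starts and ends with an alphanumeric character
# and contains no brackets
plantable_forms <- function(dict) {
  forms <- all_forms(dict)
  if (!length(forms)) return(character(0))
  ok <- vapply(strsplit(forms, " ", fixed = TRUE), function(toks) {
    all(stringi::stri_detect_regex(
      toks, "^[\\p{L}\\p{N}]([\\p{L}\\p{N}'+/:,.-]*[\\p{L}\\p{N}])?$")) &&
      !any(stringi::stri_detect_regex(toks, "[()]"))
  }, TRUE)
  forms[ok]
}

abbreviate_form <- function(form) {
  toks <- unlist(strsplit(form, "[ -]+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) >= 2L) {
    toupper(paste(substr(toks, 1L, 1L), collapse = ""))
  } else {
    toupper(substr(form, 1L, 3L))
  }
}

#' Generate a synthetic BioC corpus with planted gold annotations
#'
#' Each article has IAO-labelled sections (abstract, introduction,
#' methods, results, discussion).  Planted entities are verbatim
#' dictionary forms, expanded spelling variants, or root-word plus
#' unseen-modifier constructions that exercise keyword matching;
#' confounder sentences carry stoplisted "-ase" words; abbreviations
#' introduce a planted enzyme as "name (SHORT)" and re-mention the
#' short form later.  The gold set records every planted span, and the
#' generator verifies that each gold span slices the document text to
#' its surface string.  Generation is deterministic given the spec.
#'
#' @param spec A [synth_spec()].
#' @param dict A non-empty `enzyme_dictionary` to draw plants from.
#' @return List with elements `docs` (list of [bioc_document()]),
#'   `gold` (per-document data.frames: offset, length, text, kind),
#'   `abbrevs` (per-document named character vectors), all named by
#'   PMCID, plus the `spec`.
#' @export
generate_corpus <- function(spec, dict) {
  stopifnot(inherits(spec, "synth_spec"),
            inherits(dict, "enzyme_dictionary"))
  forms <- plantable_forms(dict)
  if (!length(forms)) stop("cannot generate a corpus from an empty dictionary")
  multi <- forms[stringi::stri_count_fixed(forms, " ") >= 1L]
  roots <- names(dict$branches)
  roots <- roots[stringi::stri_detect_regex(
    roots, "^[\\p{L}\\p{N}][\\p{L}\\p{N}'+/.-]*$")]
  mods <- unseen_modifiers()

  with_seed(spec$seed, {
    docs <- list()
    gold <- list()
    abbrevs <- list()
    for (d in seq_len(spec$n_docs)) {
      pmcid <- sprintf("PMC%07d", 9000000L + d)
      domain <- sample(names(spec$domains), 1L, prob = spec$domains)
      n_sent <- sample(seq(spec$sentences_per_doc[1],
                           spec$sentences_per_doc[2]), 1L)
      sections <- c("abstract", "introduction", "methods", "results",
                    "discussion")
      sec_of <- sort(sample(seq_along(sections), n_sent, replace = TRUE))
      doc_abbr <- character(0)
      doc_gold <- list()
      passages <- list()
      offset <- 0L
      for (si in seq_along(sections)) {
        idx <- which(sec_of == si)
        if (!length(idx)) next
        sent_texts <- character(0)
        spans <- list() # local (0-based) spans within the passage
        pos <- 0L # current passage length
        for (k in idx) {
          extra <- NULL
          if (stats::runif(1) < spec$entity_rate) {
            kind <- sample(names(spec$plant_weights), 1L,
                           prob = spec$plant_weights)
            plant <- switch(kind,
              verbatim = sample(forms, 1L),
              variant = {
                f <- if (length(multi)) sample(multi, 1L) else sample(forms, 1L)
                sample(expand_variants(f), 1L)
              },
              keyword = paste(sample(mods, 1L), sample(roots, 1L)))
            short <- NULL
            surface <- plant
            if (kind == "verbatim" &&
                stats::runif(1) < spec$abbreviation_rate) {
              short <- abbreviate_form(plant)
              if (nchar(short) >= 2L && !(short %in% names(doc_abbr))) {
                surface <- paste0(plant, " (", short, ")")
                doc_abbr[short] <- plant
              } else {
                short <- NULL
              }
            }
            tmpl <- sample(entity_templates(), 1L)
            at <- stringi::stri_locate_first_fixed(tmpl, "%s")[1, 1]
            sent <- sub("%s", surface, tmpl, fixed = TRUE)
            plant0 <- pos + at - 1L # 0-based within passage
            spans[[length(spans) + 1L]] <-
              list(offset = plant0, length = nchar(plant),
                   text = plant, kind = kind)
            if (!is.null(short)) {
              s0 <- plant0 + nchar(plant) + 2L
              spans[[length(spans) + 1L]] <-
                list(offset = s0, length = nchar(short),
                     text = short, kind = "abbrev_short")
              extra <- sprintf(
                "Subsequent assays confirmed that %s remained stable.",
                short)
            }
          } else if (stats::runif(1) < spec$confounder_rate) {
            sent <- sample(confounder_templates(), 1L)
          } else {
            sent <- sample(plain_templates(), 1L)
          }
          sent_texts <- c(sent_texts, sent)
          pos <- pos + nchar(sent) + 1L # sentences joined by one space
          if (!is.null(extra)) {
            eat <- stringi::stri_locate_first_fixed(
              extra, names(doc_abbr)[length(doc_abbr)])[1, 1]
            spans[[length(spans) + 1L]] <-
              list(offset = pos + eat - 1L,
                   length = nchar(names(doc_abbr)[length(doc_abbr)]),
                   text = names(doc_abbr)[length(doc_abbr)],
                   kind = "abbrev_short")
            sent_texts <- c(sent_texts, extra)
            pos <- pos + nchar(extra) + 1L
          }
        }
        text <- paste(sent_texts, collapse = " ")
        for (sp in spans) {
          slice <- stringi::stri_sub(text, sp$offset + 1L,
                                     sp$offset + sp$length)
          stopifnot(slice == sp$text) # generator self-check
          doc_gold[[length(doc_gold) + 1L]] <- data.frame(
            offset = offset + sp$offset, length = sp$length,
            text = sp$text, kind = sp$kind, stringsAsFactors = FALSE)
        }
        passages[[length(passages) + 1L]] <-
          bioc_passage(text, offset, section_label = sections[si])
        offset <- offset + nchar(text) + 1L
      }
      docs[[pmcid]] <- bioc_document(pmcid, passages, domain)
      gold[[pmcid]] <- if (length(doc_gold)) {
        g <- do.call(rbind, doc_gold)
        g[order(g$offset), ]
      } else {
        data.frame(offset = integer(0), length = integer(0),
                   text = character(0), kind = character(0),
                   stringsAsFactors = FALSE)
      }
      abbrevs[[pmcid]] <- doc_abbr
    }
    list(docs = docs, gold = gold, abbrevs = abbrevs, spec = spec)
  })
}
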