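# The two-step search engine: sentence splitting, greedy direct
# dictionary matching, rule-based keyword (fuzzy) matching with
# backward/forward span extension, and abbreviation resolution.

#' Annotation rule configuration
#'
#' @param sections Section labels (lowercase) whose passages are
#'   annotated.  The default includes introduction and references in
#'   addition to the core abstract/methods/results/discussion set.
#' @param stoplist Common "-ase" words that never seed a keyword match.
#' @param greek Greek letter table.
#' @param max_back Maximum number of preceding tokens absorbed by the
#'   keyword matcher's backward extension (default 4: over 99% of
#'   dictionary "-ase" names have five words or fewer).
#' @param function_words Closed list of determiners, prepositions and
#'   common verbs that terminate backward extension.
#' @param descriptive_modifiers Adjectives like "human"/"serum"/
#'   "bacterial" that are excluded from keyword spans (they only enter an
#'   annotation via an exact dictionary match).
#' @param annotator Annotator tag written into annotation infons.
#' @param timestamp Fixed ISO-8601 timestamp for annotation infons;
#'   `NULL` (default) stamps each [annotate_document()] call with the
#'   current UTC time.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(sections = c("abstract", "introduction", "methods",
                                     "results", "discussion", "references"),
                        stoplist = default_stoplist(),
                        greek = default_greek_table(),
                        max_back = 4L,
                        function_words = default_function_words(),
                        descriptive_modifiers = c("human", "serum",
                                                  "bacterial"),
                        annotator = paste0("enzner ", enzner_version()),
                        timestamp = NULL) {
  structure(
    list(sections = stringi::stri_trans_tolower(sections),
         stoplist = stringi::stri_trans_tolower(stoplist),
         greek = greek,
         max_back = as.integer(max_back),
         function_words = stringi::stri_trans_tolower(function_words),
         descriptive_modifiers =
           stringi::stri_trans_tolower(descriptive_modifiers),
         annotator = annotator,
         timestamp = timestamp),
    class = "rule_config"
  )
}

#' @rdname rule_config
#' @export
default_function_words <- function() {
  c("the", "a", "an", "of", "in", "on", "at", "by", "for", "to", "with",
    "from", "and", "or", "but", "as", "is", "are", "was", "were", "be",
    "been", "being", "this", "that", "these", "those", "its", "their",
    "our", "such", "other", "which", "each", "all", "both", "any", "some",
    "no", "not", "than", "then", "more", "most", "several", "various",
    "respectively", "including", "between", "during", "after", "before",
    "where", "when", "also", "only", "via", "using", "used", "show",
    "shows", "shown", "showed", "found", "observed", "measured",
    "detected", "identified", "revealed", "confirmed", "purified",
    "incubated", "expressed", "elevated", "increased", "decreased",
    "reduced", "has", "have", "had", "we", "it", "they")
}

empty_matches <- function() {
  data.frame(surface = character(0), start = integer(0),
             length = integer(0), identifier = character(0),
             method = character(0), stringsAsFactors = FALSE)
}

match_row <- function(surface, start, length, identifier, method) {
  data.frame(surface = surface, start = as.integer(start),
             length = as.integer(length), identifier = identifier,
             method = method, stringsAsFactors = FALSE)
}

# tokens with 0-based global offsets; leading/trailing non-alphanumeric
# characters are stripped (hyphens/slashes inside tokens are kept)
tokenize_words <- function(text, base0 = 0L) {
  empty <- data.frame(token = character(0), start0 = integer(0),
                      end0 = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  locs <- stringi::stri_locate_all_regex(text, "\\S+")[[1]]
  if (is.na(locs[1, 1])) return(empty)
  rows <- vector("list", nrow(locs))
  for (r in seq_len(nrow(locs))) {
    raw <- stringi::stri_sub(text, locs[r, 1], locs[r, 2])
    lead <- stringi::stri_locate_first_regex(raw, "[\\p{L}\\p{N}]")[1, 1]
    if (is.na(lead)) next
    last <- stringi::stri_locate_last_regex(raw, "[\\p{L}\\p{N}]")[1, 1]
    tok <- stringi::stri_sub(raw, lead, last)
    s0 <- base0 + (locs[r, 1] - 1L) + (lead - 1L)
    rows[[r]] <- data.frame(token = tok, start0 = as.integer(s0),
                            end0 = as.integer(s0 + nchar(tok)),
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

new_sentence <- function(text, start_offset) {
  structure(
    list(text = text, start_offset = as.integer(start_offset),
         tokens = tokenize_words(text, start_offset)),
    class = "enz_sentence"
  )
}

#' Split a paragraph into sentences with global offsets
#'
#' Uses ICU sentence-boundary analysis (via stringi).  Offsets are
#' 0-based character positions into the whole article text, obtained by
#' adding `paragraph_offset` to each sentence's position within the
#' paragraph.  Each sentence carries its tokens (with offsets).
#'
#' @param paragraph_text Paragraph string.
#' @param paragraph_offset 0-based global offset of the paragraph.
#' @return List of sentence objects (`text`, `start_offset`, `tokens`);
#'   empty list for an empty paragraph.
#' @export
split_sentences <- function(paragraph_text, paragraph_offset = 0L) {
  stopifnot(paragraph_offset >= 0L)
  if (is.null(paragraph_text) || !nzchar(paragraph_text)) return(list())
  pieces <- stringi::stri_split_boundaries(paragraph_text,
                                           type = "sentence")[[1]]
  starts0 <- cumsum(c(0L, nchar(pieces)[-length(pieces)]))
  out <- list()
  for (i in seq_along(pieces)) {
    piece <- pieces[[i]]
    lead <- nchar(piece) - nchar(stringi::stri_trim_left(piece))
    txt <- stringi::stri_trim_both(piece)
    if (!nzchar(txt)) next
    out[[length(out) + 1L]] <-
      new_sentence(txt, paragraph_offset + starts0[i] + lead)
  }
  out
}

# greedy resolution: longest span wins, ties leftmost; `fixed` spans are
# pre-selected and never displaced
resolve_overlaps <- function(cands, fixed = NULL) {
  if (!nrow(cands)) return(cands)
  cands <- cands[order(-cands$length, cands$start), , drop = FALSE]
  sel_start <- if (!is.null(fixed) && nrow(fixed)) fixed$start else integer(0)
  sel_end <- if (!is.null(fixed) && nrow(fixed)) {
    fixed$start + fixed$length
  } else {
    integer(0)
  }
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    s <- cands$start[i]
    e <- s + cands$length[i]
    if (!any(s < sel_end & sel_start < e)) {
      keep[i] <- TRUE
      sel_start <- c(sel_start, s)
      sel_end <- c(sel_end, e)
    }
  }
  out <- cands[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Direct (exact) greedy dictionary matching in one sentence
#'
#' Every token whose lowercase form is a branch key of the hierarchical
#' dictionary anchors a lookup: the branch's forms are tried
#' longest-first against the token window ending at the anchor, and the
#' first (longest) exact, case-insensitive match wins.  Overlapping
#' candidates are resolved greedily (longest span wins, ties leftmost),
#' so a term contained in a longer matched term is never selected.  The
#' identifier is the form's EC number, or its root word when the form
#' has no EC.
#'
#' @param sentence A sentence from [split_sentences()].
#' @param dict An `enzyme_dictionary`.
#' @return data.frame of matches (`surface`, `start`, `length`,
#'   `identifier`, `method = "direct"`).
#' @export
direct_match <- function(sentence, dict) {
  toks <- sentence$tokens
  if (!nrow(toks)) return(empty_matches())
  text <- sentence$text
  s0 <- sentence$start_offset
  cands <- list()
  for (i in seq_len(nrow(toks))) {
    key <- stringi::stri_trans_tolower(toks$token[i])
    forms <- c(dict$branches[[key]], dict$non_ase[[key]])
    if (is.null(forms)) next
    for (form in forms) {
      k <- stringi::stri_count_fixed(form, " ") + 1L
      j <- i - k + 1L
      if (j < 1L) next
      a0 <- toks$start0[j]
      b0 <- toks$end0[i]
      surface <- stringi::stri_sub(text, a0 - s0 + 1L, b0 - s0)
      if (stringi::stri_trans_tolower(surface) == form) {
        ec <- dict$ec_index[form]
        ident <- if (!is.na(ec)) unname(ec) else final_token(form)
        cands[[length(cands) + 1L]] <-
          match_row(surface, a0, b0 - a0, ident, "direct")
        break # longest form at this anchor; shorter ones are contained
      }
    }
  }
  if (!length(cands)) return(empty_matches())
  resolve_overlaps(unique(do.call(rbind, cands)))
}

greek_symbols <- function(greek) greek$symbol

#' Rule-based keyword (fuzzy) matching in one sentence
#'
#' For every token that is an accepted root term (ends in "ase", not
#' stoplisted) and is not already inside a direct match, a span is grown
#' around it:
#' * backward: up to `cfg$max_back` preceding tokens are absorbed while
#'   each is either in the root's branch vocabulary or looks like a
#'   chemical modifier (letters/digits/hyphens, not a function word or a
#'   descriptive modifier such as "human"), never crossing the sentence
#'   start, a direct match, or non-hyphen punctuation;
#' * forward: at most one unit is appended — a round-bracketed group
#'   immediately after the root word, a bare integer token, or a single
#'   Greek letter token.
#'
#' The identifier of a keyword match is the root word itself.  Keyword
#' spans never overlap direct-match spans.
#'
#' @param sentence A sentence from [split_sentences()].
#' @param dict An `enzyme_dictionary`.
#' @param cfg A [rule_config()].
#' @param direct data.frame of direct matches already found in this
#'   sentence (spans to suppress and avoid).
#' @return data.frame of matches (`method = "keyword"`).
#' @export
keyword_match <- function(sentence, dict, cfg = rule_config(),
                          direct = NULL) {
  toks <- sentence$tokens
  if (!nrow(toks)) return(empty_matches())
  if (is.null(direct)) direct <- empty_matches()
  text <- sentence$text
  s0 <- sentence$start_offset
  dstart <- direct$start
  dend <- direct$start + direct$length
  in_direct <- function(a0, b0) any(a0 < dend & dstart < b0)

  gsyms <- greek_symbols(cfg$greek)
  cands <- list()
  for (i in seq_len(nrow(toks))) {
    if (in_direct(toks$start0[i], toks$end0[i])) next
    rt <- root_term_of(toks$token[i], cfg$stoplist)
    if (is.na(rt)) next
    vocab <- dict$vocab[[rt]]

    # backward extension: longest acceptable contiguous run, max_back
    j <- i
    while (j > 1L && (i - j) < cfg$max_back) {
      cand <- j - 1L
      gap <- stringi::stri_sub(text, toks$end0[cand] - s0 + 1L,
                               toks$start0[j] - s0)
      if (!stringi::stri_detect_regex(gap, "^\\s*$")) break
      if (in_direct(toks$start0[cand], toks$end0[cand])) break
      tl <- stringi::stri_trans_tolower(toks$token[cand])
      ok <- (tl %in% vocab) ||
        (stringi::stri_detect_regex(
           tl, "^[\\p{L}\\p{N}][\\p{L}\\p{N}\\-/'’]*$") &&
         !(tl %in% cfg$function_words) &&
         !(tl %in% cfg$descriptive_modifiers))
      if (!ok) break
      j <- cand
    }
    a0 <- toks$start0[j]
    b0 <- toks$end0[i]

    # forward extension: one bracketed group, bare integer, or Greek letter
    rest <- stringi::stri_sub(text, b0 - s0 + 1L, nchar(text))
    br <- stringi::stri_match_first_regex(rest, "^\\s?\\(([^()]{1,80})\\)")
    if (!is.na(br[1, 1])) {
      b0 <- b0 + nchar(br[1, 1])
    } else if (i < nrow(toks)) {
      gap <- stringi::stri_sub(text, b0 - s0 + 1L, toks$start0[i + 1L] - s0)
      nt <- toks$token[i + 1L]
      if (gap == " " &&
          (stringi::stri_detect_regex(nt, "^\\p{N}+$") || nt %in% gsyms)) {
        b0 <- toks$end0[i + 1L]
      }
    }

    surface <- stringi::stri_sub(text, a0 - s0 + 1L, b0 - s0)
    cands[[length(cands) + 1L]] <-
      match_row(surface, a0, b0 - a0, rt, "keyword")
  }
  if (!length(cands)) return(empty_matches())
  resolve_overlaps(unique(do.call(rbind, cands)), fixed = direct)
}

#' Identify enzyme abbreviations from a definition map
#'
#' Runs the two-step matcher over each abbreviation's definition and
#' keeps the short forms whose definition contains an enzyme match
#' covering the definition's head (final) word.  Each kept short form
#' carries the identifier found for its definition (direct matches
#' preferred over keyword matches).
#'
#' @param abbrevs Named character vector, short form -> definition
#'   (see [read_abbreviations()]).
#' @param dict An `enzyme_dictionary`.
#' @param cfg A [rule_config()].
#' @return Named list: short form -> list(short_form, definition,
#'   identifier, method).
#' @export
find_enzyme_abbreviations <- function(abbrevs, dict, cfg = rule_config()) {
  out <- list()
  if (!length(abbrevs)) return(out)
  for (short in names(abbrevs)) {
    def <- as.character(abbrevs[[short]])
    if (!nzchar(trimws(def))) next
    sent <- new_sentence(def, 0L)
    if (!nrow(sent$tokens)) next
    dm <- direct_match(sent, dict)
    km <- keyword_match(sent, dict, cfg, dm)
    m <- rbind(dm, km)
    if (!nrow(m)) next
    nt <- nrow(sent$tokens)
    head_s <- sent$tokens$start0[nt]
    head_e <- sent$tokens$end0[nt]
    covers <- m$start <= head_s & (m$start + m$length) >= head_e
    m <- m[covers, , drop = FALSE]
    if (!nrow(m)) next
    m <- m[order(m$method != "direct"), , drop = FALSE] # direct first
    out[[short]] <- list(short_form = short, definition = def,
                         identifier = m$identifier[[1]],
                         method = m$method[[1]])
  }
  out
}

#' Annotate a BioC document with enzyme entities
#'
#' Every passage whose section label is in `cfg$sections` is sentence
#' split and run through [direct_match()] then [keyword_match()];
#' afterwards occurrences of enzyme abbreviations (short forms whose
#' definition resolved to an enzyme, see
#' [find_enzyme_abbreviations()]) are located in the passage text
#' (case-sensitively, at word boundaries) and annotated with the
#' definition's identifier.  Annotations get sequential ids in document
#' offset order; offsets are global 0-based article offsets; no two
#' annotations overlap (direct matches take precedence over keyword
#' matches, which take precedence over abbreviation occurrences).
#'
#' @param doc A [bioc_document()] with offset-consistent passages.
#' @param dict An `enzyme_dictionary`.
#' @param abbrevs Named character vector of abbreviation definitions for
#'   this document, or `NULL`.
#' @param cfg A [rule_config()].
#' @return The document with its `annotations` filled in.
#' @export
annotate_document <- function(doc, dict, abbrevs = NULL,
                              cfg = rule_config()) {
  validate_bioc(doc)
  tmpl <- find_enzyme_abbreviations(abbrevs, dict, cfg)
  ts <- cfg$timestamp %||% utc_now()

  per_passage <- vector("list", length(doc$passages))
  for (pi in seq_along(doc$passages)) {
    p <- doc$passages[[pi]]
    if (!(normalize_section(p$section_label) %in% cfg$sections)) {
      per_passage[[pi]] <- empty_matches()
      next
    }
    matches <- empty_matches()
    for (sent in split_sentences(p$text, p$offset)) {
      dm <- direct_match(sent, dict)
      km <- keyword_match(sent, dict, cfg, dm)
      matches <- rbind(matches, dm, km)
    }
    for (tm in tmpl) {
      pat <- paste0("(?<![\\p{L}\\p{N}])\\Q", tm$short_form,
                    "\\E(?![\\p{L}\\p{N}])")
      locs <- stringi::stri_locate_all_regex(p$text, pat)[[1]]
      if (is.na(locs[1, 1])) next
      for (r in seq_len(nrow(locs))) {
        a0 <- p$offset + locs[r, 1] - 1L
        len <- locs[r, 2] - locs[r, 1] + 1L
        if (nrow(matches) &&
            any(a0 < matches$start + matches$length &
                matches$start < a0 + len)) next
        matches <- rbind(matches,
                         match_row(stringi::stri_sub(p$text, locs[r, 1],
                                                     locs[r, 2]),
                                   a0, len, tm$identifier, "abbreviation"))
      }
    }
    per_passage[[pi]] <- matches[order(matches$start), , drop = FALSE]
  }

  counter <- 0L
  for (pi in seq_along(doc$passages)) {
    matches <- per_passage[[pi]]
    anns <- vector("list", nrow(matches))
    for (r in seq_len(nrow(matches))) {
      counter <- counter + 1L
      anns[[r]] <- bioc_annotation(
        text = matches$surface[r], identifier = matches$identifier[r],
        id = as.character(counter), offset = matches$start[r],
        length = matches$length[r], method = matches$method[r],
        annotator = cfg$annotator, updated_at = ts)
    }
    doc$passages[[pi]]$annotations <- anns
  }
  doc
}
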