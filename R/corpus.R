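# Training-corpus construction: abbreviation replacement, tagged-sentence
# extraction (SOBIE/BIO), stratified 75:10:15 splitting, corpus
# statistics and CoNLL export.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Replace enzyme abbreviations by their definitions
#'
#' Training-time transformation: every occurrence of an enzyme short
#' form (word-bounded, case-sensitive) in the document text is replaced
#' by its full definition.  Passage offsets and annotation offsets are
#' recomputed consistently; an annotation that covered exactly a short
#' form becomes an annotation of the definition.  Non-enzyme
#' abbreviations are untouched.
#'
#' @param doc A (typically annotated) [bioc_document()].
#' @param enzyme_abbrevs Either the named list returned by
#'   [find_enzyme_abbreviations()] or a named character vector
#'   short form -> definition.
#' @return The transformed document.
#' @export
replace_abbreviations <- function(doc, enzyme_abbrevs) {
  if (!length(enzyme_abbrevs)) return(doc)
  defs <- vapply(enzyme_abbrevs, function(x) {
    if (is.list(x)) x$definition else as.character(x)
  }, "")
  shorts <- names(defs)

  gaps <- integer(length(doc$passages))
  pos <- 0L
  for (i in seq_along(doc$passages)) {
    gaps[i] <- doc$passages[[i]]$offset - pos
    pos <- doc$passages[[i]]$offset + nchar(doc$passages[[i]]$text)
  }

  new_offset <- 0L
  for (pi in seq_along(doc$passages)) {
    p <- doc$passages[[pi]]
    occ <- list()
    for (k in seq_along(shorts)) {
      pat <- paste0("(?<![\\p{L}\\p{N}])\\Q", shorts[k],
                    "\\E(?![\\p{L}\\p{N}])")
      locs <- stringi::stri_locate_all_regex(p$text, pat)[[1]]
      if (is.na(locs[1, 1])) next
      for (r in seq_len(nrow(locs))) {
        occ[[length(occ) + 1L]] <- list(s = locs[r, 1], e = locs[r, 2],
                                        def = defs[[k]])
      }
    }
    if (length(occ)) {
      occ <- occ[order(vapply(occ, function(o) o$s, 1))]
      # drop overlapping later occurrences
      last_e <- 0L
      occ <- Filter(function(o) {
        ok <- o$s > last_e
        if (ok) last_e <<- o$e
        ok
      }, occ)
    }

    # rebuild text and an old->new position shift map
    pieces <- character(0)
    cur <- 1L
    shifts <- list() # each: old position threshold (1-based), delta after it
    delta <- 0L
    for (o in occ) {
      pieces <- c(pieces, stringi::stri_sub(p$text, cur, o$s - 1L), o$def)
      d <- nchar(o$def) - (o$e - o$s + 1L)
      shifts[[length(shifts) + 1L]] <- list(s = o$s, e = o$e, delta = delta,
                                            def = o$def)
      delta <- delta + d
      cur <- o$e + 1L
    }
    pieces <- c(pieces, stringi::stri_sub(p$text, cur, nchar(p$text)))
    new_text <- paste(pieces, collapse = "")

    shift_at <- function(pos1) { # shift for an old 1-based position
      d <- 0L
      for (sh in shifts) {
        if (sh$e < pos1) d <- d + nchar(sh$def) - (sh$e - sh$s + 1L)
      }
      d
    }

    anns <- p$annotations
    for (ai in seq_along(anns)) {
      a <- anns[[ai]]
      l <- a$locations[[1]]
      old_s1 <- l$offset - p$offset + 1L # 1-based within old passage text
      old_e1 <- old_s1 + l$length - 1L
      hit <- NULL
      for (sh in shifts) {
        if (sh$s == old_s1 && sh$e == old_e1) { hit <- sh; break }
      }
      if (!is.null(hit)) {
        a$text <- hit$def
        new_s1 <- old_s1 + hit$delta
        a$locations[[1]] <- list(offset = new_offset + gaps[pi] + new_s1 - 1L,
                                 length = nchar(hit$def))
      } else {
        grow <- 0L
        for (sh in shifts) { # replacement inside the annotation grows it
          if (sh$s > old_s1 && sh$e < old_e1) {
            grow <- grow + nchar(sh$def) - (sh$e - sh$s + 1L)
          }
        }
        new_s1 <- old_s1 + shift_at(old_s1)
        a$locations[[1]] <- list(offset = new_offset + gaps[pi] + new_s1 - 1L,
                                 length = l$length + grow)
        a$text <- stringi::stri_sub(new_text, new_s1,
                                    new_s1 + l$length + grow - 1L)
      }
      anns[[ai]] <- a
    }

    doc$passages[[pi]]$text <- new_text
    doc$passages[[pi]]$offset <- new_offset + gaps[pi]
    doc$passages[[pi]]$annotations <- anns
    new_offset <- new_offset + gaps[pi] + nchar(new_text)
  }
  validate_bioc(doc)
  doc
}

#' CoNLL-style tokenization
#'
#' Whitespace split, then leading/trailing punctuation groups are split
#' off as their own tokens; hyphens stay inside words (enzyme names
#' hyphenate).  Used for corpus-level tagging; model-specific subword
#' tokenizers are out of scope.
#'
#' @param text String to tokenize.
#' @param base0 0-based offset added to token offsets.
#' @return data.frame with columns `token`, `start0`, `end0`.
#' @export
tokenize_conll <- function(text, base0 = 0L) {
  empty <- data.frame(token = character(0), start0 = integer(0),
                      end0 = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  locs <- stringi::stri_locate_all_regex(text, "\\S+")[[1]]
  if (is.na(locs[1, 1])) return(empty)
  rows <- list()
  add <- function(tok, s0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      token = tok, start0 = as.integer(s0),
      end0 = as.integer(s0 + nchar(tok)), stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(locs))) {
    raw <- stringi::stri_sub(text, locs[r, 1], locs[r, 2])
    s0 <- base0 + locs[r, 1] - 1L
    lead <- stringi::stri_locate_first_regex(raw, "[\\p{L}\\p{N}]")[1, 1]
    if (is.na(lead)) { add(raw, s0); next }
    last <- stringi::stri_locate_last_regex(raw, "[\\p{L}\\p{N}]")[1, 1]
    if (lead > 1L) add(stringi::stri_sub(raw, 1L, lead - 1L), s0)
    add(stringi::stri_sub(raw, lead, last), s0 + lead - 1L)
    if (last < nchar(raw)) {
      add(stringi::stri_sub(raw, last + 1L, nchar(raw)), s0 + last)
    }
  }
  do.call(rbind, rows)
}

#' Construct a tagged sentence
#'
#' @param sentence_id Unique id "PMCID:section:paragraph:index".
#' @param tokens Character vector of tokens.
#' @param tags Label vector over O/S/B/I/E (SOBIE) or O/B/I (BIO),
#'   same length as `tokens`.
#' @param scheme `"sobie"` or `"bio"`.
#' @return Object of class `tagged_sentence`.
#' @export
tagged_sentence <- function(sentence_id, tokens, tags,
                            scheme = c("sobie", "bio")) {
  scheme <- match.arg(scheme)
  stopifnot(length(tokens) == length(tags))
  tags_to_spans(tags, scheme) # grammar check
  structure(list(sentence_id = sentence_id, tokens = tokens,
                 tags = tags, scheme = scheme),
            class = "tagged_sentence")
}

#' Convert token tags to entity token spans and back
#'
#' `tags_to_spans()` decodes a valid SOBIE (`(O | S | B I* E)*`) or BIO
#' sequence into 1-based token index ranges; invalid sequences error.
#' `spans_to_tags()` is its inverse.
#'
#' @param tags Label character vector.
#' @param scheme `"sobie"` or `"bio"`.
#' @param n Number of tokens.
#' @param spans List of `c(first, last)` token index pairs.
#' @return `tags_to_spans()`: list of integer pairs;
#'   `spans_to_tags()`: label vector.
#' @export
tags_to_spans <- function(tags, scheme = c("sobie", "bio")) {
  scheme <- match.arg(scheme)
  spans <- list()
  i <- 1L
  n <- length(tags)
  while (i <= n) {
    t <- tags[[i]]
    if (t == "O") {
      i <- i + 1L
    } else if (scheme == "sobie" && t == "S") {
      spans[[length(spans) + 1L]] <- c(i, i)
      i <- i + 1L
    } else if (t == "B") {
      j <- i + 1L
      if (scheme == "sobie") {
        while (j <= n && tags[[j]] == "I") j <- j + 1L
        if (j > n || tags[[j]] != "E") {
          stop("invalid SOBIE sequence: B not closed by E at token ", i)
        }
        spans[[length(spans) + 1L]] <- c(i, j)
        i <- j + 1L
      } else {
        while (j <= n && tags[[j]] == "I") j <- j + 1L
        spans[[length(spans) + 1L]] <- c(i, j - 1L)
        i <- j
      }
    } else {
      stop(sprintf("invalid %s sequence: unexpected '%s' at token %d",
                   toupper(scheme), t, i))
    }
  }
  spans
}

#' @rdname tags_to_spans
#' @export
spans_to_tags <- function(n, spans, scheme = c("sobie", "bio")) {
  scheme <- match.arg(scheme)
  tags <- rep("O", n)
  for (sp in spans) {
    a <- sp[[1]]
    b <- sp[[2]]
    stopifnot(a >= 1L, b <= n, a <= b)
    if (scheme == "sobie") {
      if (a == b) {
        tags[a] <- "S"
      } else {
        tags[a] <- "B"
        if (b - a > 1L) tags[(a + 1L):(b - 1L)] <- "I"
        tags[b] <- "E"
      }
    } else {
      tags[a] <- "B"
      if (b > a) tags[(a + 1L):b] <- "I"
    }
  }
  tags
}

#' Convert between SOBIE and BIO tag sequences
#'
#' Both conversions go through the entity spans the tags encode, so
#' `bio_to_sobie(sobie_to_bio(x)) == x` on valid SOBIE sequences.
#'
#' @param tags Valid label vector.
#' @return Label vector in the other scheme.
#' @export
sobie_to_bio <- function(tags) {
  spans_to_tags(length(tags), tags_to_spans(tags, "sobie"), "bio")
}

#' @rdname sobie_to_bio
#' @export
bio_to_sobie <- function(tags) {
  spans_to_tags(length(tags), tags_to_spans(tags, "bio"), "sobie")
}

#' Extract annotated sentences as tagged training data
#'
#' Only sentences overlapping at least one annotation are kept (the
#' corpus contains only sentences with enzyme entities).  Tokens are the
#' neutral CoNLL-style tokenization (punctuation split off, hyphens kept
#' inside words); a token overlapping an annotation by at least one
#' character is inside the entity.  Sentence ids are
#' `PMCID:section:paragraph:index`.
#'
#' @param docs A [bioc_document()] or list of them (annotated).
#' @param scheme `"sobie"` or `"bio"`.
#' @return List of [tagged_sentence()] objects.
#' @export
extract_tagged_sentences <- function(docs, scheme = c("sobie", "bio")) {
  scheme <- match.arg(scheme)
  if (inherits(docs, "bioc_document")) docs <- list(docs)
  out <- list()
  for (doc in docs) {
    for (pi in seq_along(doc$passages)) {
      p <- doc$passages[[pi]]
      if (!length(p$annotations)) next
      ann <- doc_annotations(bioc_document(doc$pmcid, list(p)))
      sents <- split_sentences(p$text, p$offset)
      for (si in seq_along(sents)) {
        sent <- sents[[si]]
        s_end <- sent$start_offset + nchar(sent$text)
        ov <- ann[ann$offset < s_end &
                  sent$start_offset < ann$offset + ann$length, , drop = FALSE]
        if (!nrow(ov)) next
        toks <- tokenize_conll(sent$text, sent$start_offset)
        if (!nrow(toks)) next
        spans <- list()
        for (r in seq_len(nrow(ov))) {
          idx <- which(toks$start0 < ov$offset[r] + ov$length[r] &
                       ov$offset[r] < toks$end0)
          if (!length(idx)) next
          spans[[length(spans) + 1L]] <- c(min(idx), max(idx))
        }
        if (!length(spans)) next
        tags <- spans_to_tags(nrow(toks), spans, scheme)
        out[[length(out) + 1L]] <- tagged_sentence(
          sentence_id = paste(doc$pmcid, p$section_label, pi, si, sep = ":"),
          tokens = toks$token, tags = tags, scheme = scheme)
      }
    }
  }
  out
}

#' Stratified 75:10:15 corpus split
#'
#' Per domain, with `n` documents: `validation = floor(0.10 n)`,
#' `test = floor(0.15 n)`, `train = n - validation - test` (this
#' rounding reproduces the published per-domain corpus counts, e.g.
#' 1006 metabolomics articles -> 756/100/150).  Membership is
#' randomized by `seed`; the per-domain counts depend only on `n`.
#'
#' @param doc_ids Character vector of document ids.
#' @param domains Domain label per document (`NULL`: one stratum).
#' @param ratios Train/validation/test proportions summing to 1.
#' @param seed Integer RNG seed.
#' @return Object of class `corpus_split`: lists `train`, `validation`,
#'   `test`, plus `ratios`, `seed` and a per-domain `counts` data.frame.
#' @export
split_corpus <- function(doc_ids, domains = NULL,
                         ratios = c(train = 0.75, validation = 0.10,
                                    test = 0.15),
                         seed = 42L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, length(ratios) == 3L)
  if (is.null(domains)) domains <- rep("all", length(doc_ids))
  stopifnot(length(domains) == length(doc_ids),
            !anyDuplicated(doc_ids))
  train <- val <- test <- character(0)
  counts <- list()
  with_seed(seed, {
    for (d in sort(unique(domains))) {
      ids <- doc_ids[domains == d]
      n <- length(ids)
      nv <- as.integer(floor(n * ratios[[2]]))
      nt <- as.integer(floor(n * ratios[[3]]))
      ntr <- n - nv - nt
      perm <- if (n > 1L) sample(ids) else ids
      train <- c(train, perm[seq_len(ntr)])
      if (nv) val <- c(val, perm[ntr + seq_len(nv)])
      if (nt) test <- c(test, perm[ntr + nv + seq_len(nt)])
      counts[[length(counts) + 1L]] <- data.frame(
        domain = d, n = n, train = ntr, validation = nv, test = nt,
        stringsAsFactors = FALSE)
    }
  })
  structure(
    list(train = train, validation = val, test = test,
         ratios = ratios, seed = seed, counts = do.call(rbind, counts)),
    class = "corpus_split"
  )
}

#' Corpus summary statistics
#'
#' Per-domain article and entity counts with mean and standard deviation
#' of entities per article, and a root-term-by-word-count table
#' (buckets 1, 2, 3, >3 words) over all annotations.
#'
#' @param docs List of annotated [bioc_document()] objects.
#' @param domains Optional domain label per document; defaults to each
#'   document's `domain_tag`.
#' @return List with data.frames `per_domain` (plus a "total" row) and
#'   `root_terms`.
#' @export
corpus_stats <- function(docs, domains = NULL) {
  if (inherits(docs, "bioc_document")) docs <- list(docs)
  if (is.null(domains)) {
    domains <- vapply(docs, function(d) d$domain_tag, "")
  }
  per_doc <- vapply(docs, function(d) nrow(doc_annotations(d)), 1L)
  rows <- list()
  for (d in sort(unique(domains))) {
    x <- per_doc[domains == d]
    rows[[length(rows) + 1L]] <- data.frame(
      domain = d, articles = length(x), entities = sum(x),
      mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    domain = "total", articles = length(per_doc), entities = sum(per_doc),
    mean = if (length(per_doc)) mean(per_doc) else NaN,
    sd = if (length(per_doc) > 1L) stats::sd(per_doc) else NA_real_,
    stringsAsFactors = FALSE)
  per_domain <- do.call(rbind, rows)

  texts <- unlist(lapply(docs, function(d) doc_annotations(d)$text))
  if (length(texts)) {
    roots <- vapply(stringi::stri_trans_tolower(texts), final_token, "",
                    USE.NAMES = FALSE)
    wc <- stringi::stri_count_regex(texts, "\\S+")
    bucket <- cut(wc, c(0, 1, 2, 3, Inf),
                  labels = c("1", "2", "3", ">3"))
    tab <- table(roots, bucket)
    root_terms <- data.frame(
      root = rownames(tab),
      `1` = as.integer(tab[, "1"]), `2` = as.integer(tab[, "2"]),
      `3` = as.integer(tab[, "3"]), `>3` = as.integer(tab[, ">3"]),
      check.names = FALSE, stringsAsFactors = FALSE)
    root_terms$total <- root_terms$`1` + root_terms$`2` +
      root_terms$`3` + root_terms$`>3`
    root_terms <- root_terms[order(-root_terms$total, root_terms$root), ]
    rownames(root_terms) <- NULL
  } else {
    root_terms <- data.frame(root = character(0), `1` = integer(0),
                             `2` = integer(0), `3` = integer(0),
                             `>3` = integer(0), total = integer(0),
                             check.names = FALSE, stringsAsFactors = FALSE)
  }
  list(per_domain = per_domain, root_terms = root_terms)
}

#' Write / read tagged sentences in CoNLL style
#'
#' One `token<TAB>tag` pair per line, a blank line between sentences,
#' each sentence preceded by a `# sentence_id = ...` comment; the file
#' starts with a `# scheme = ...` header.  `read_conll()` round-trips
#' `write_conll()` output.
#'
#' @param sentences List of [tagged_sentence()] objects.
#' @param path File path.
#' @return `write_conll()`: `path`, invisibly; `read_conll()`: list of
#'   [tagged_sentence()] objects.
#' @export
write_conll <- function(sentences, path) {
  lines <- character(0)
  if (length(sentences)) {
    lines <- paste0("# scheme = ", sentences[[1]]$scheme)
    for (s in sentences) {
      lines <- c(lines,
                 paste0("# sentence_id = ", s$sentence_id),
                 paste0(s$tokens, "\t", s$tags),
                 "")
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) return(list())
  scheme <- sub("^# scheme = ", "", lines[[1]])
  out <- list()
  id <- NULL
  toks <- tags <- character(0)
  flush <- function() {
    if (!is.null(id) && length(toks)) {
      out[[length(out) + 1L]] <<- tagged_sentence(id, toks, tags, scheme)
    }
    toks <<- tags <<- character(0)
    id <<- NULL
  }
  for (ln in lines[-1]) {
    if (startsWith(ln, "# sentence_id = ")) {
      flush()
      id <- sub("^# sentence_id = ", "", ln)
    } else if (!nzchar(ln)) {
      flush()
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      toks <- c(toks, parts[[1]])
      tags <- c(tags, parts[[2]])
    }
  }
  flush()
  out
}
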