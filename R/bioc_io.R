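# BioC-JSON readers/writers (Auto-CORPus dialect) and the stand-off
# annotation record: text / infons / id / locations.

#' Construct a BioC passage
#'
#' @param text Passage (paragraph) text; may be empty, never NULL.
#' @param offset 0-based character offset of the passage in the whole
#'   article text.
#' @param section_label Section name (IAO-derived), e.g. "methods".
#' @param infons Named list of passage infons, preserved verbatim.
#' @param annotations List of `bioc_annotation` objects.
#' @return An object of class `bioc_passage`.
#' @export
bioc_passage <- function(text, offset, section_label = "other",
                         infons = list(), annotations = list()) {
  if (is.null(text)) stop("passage text must not be NULL")
  structure(
    list(text = as.character(text), offset = as.integer(offset),
         section_label = as.character(section_label),
         infons = infons, annotations = annotations),
    class = "bioc_passage"
  )
}

#' Construct a BioC document
#'
#' @param pmcid Article identifier string.
#' @param passages Ordered list of [bioc_passage()] objects; offsets must
#'   be strictly increasing running character positions.
#' @param domain_tag One of "GWAS", "proteomics", "metabolomics",
#'   "microbiome", "other".
#' @return An object of class `bioc_document`.
#' @export
bioc_document <- function(pmcid, passages, domain_tag = "other") {
  structure(
    list(pmcid = as.character(pmcid), domain_tag = as.character(domain_tag),
         passages = passages),
    class = "bioc_document"
  )
}

#' Construct a stand-off enzyme annotation
#'
#' The record has exactly four top-level elements: `text` (surface
#' string as in the article), `infons` (identifier = EC number or root
#' word, type, annotator, updated_at, and the matching method), `id`,
#' and `locations` (offset/length pairs; offsets are 0-based characters
#' into the whole article).
#'
#' @param text Surface string.
#' @param identifier EC number (direct match) or root word.
#' @param id Annotation id string.
#' @param offset 0-based global character offset.
#' @param length Character count.
#' @param method "direct", "keyword" or "abbreviation".
#' @param annotator Annotator tag stored in infons.
#' @param updated_at ISO-8601 UTC timestamp string.
#' @return An object of class `bioc_annotation`.
#' @export
bioc_annotation <- function(text, identifier, id, offset, length,
                            method = "direct",
                            annotator = paste0("enzner ", enzner_version()),
                            updated_at = utc_now()) {
  structure(
    list(text = as.character(text),
         infons = list(identifier = as.character(identifier),
                       type = "enzyme",
                       annotator = annotator,
                       updated_at = updated_at,
                       method = method),
         id = as.character(id),
         locations = list(list(offset = as.integer(offset),
                               length = as.integer(length)))),
    class = "bioc_annotation"
  )
}

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

enzner_version <- function() {
  as.character(utils::packageVersion("enzner"))
}

section_label_from_infons <- function(infons) {
  lab <- infons$section_label %||% infons$iao_name_1 %||%
    infons$section_type %||% infons$section_title_1 %||%
    infons$section_title %||% "other"
  normalize_section(lab)
}

normalize_section <- function(x) {
  x <- stringi::stri_trans_tolower(trimws(as.character(x)))
  sub("\\s+section$", "", x)
}

parse_bioc_annotation <- function(a, where) {
  need <- c("text", "infons", "id", "locations")
  miss <- setdiff(need, names(a))
  if (length(miss)) {
    stop(sprintf("schema error at %s: missing '%s'", where, miss[[1]]))
  }
  locs <- lapply(a$locations, function(l) {
    list(offset = as.integer(l$offset), length = as.integer(l$length))
  })
  if (!length(locs)) stop(sprintf("schema error at %s: empty locations", where))
  structure(
    list(text = as.character(a$text), infons = a$infons,
         id = as.character(a$id), locations = locs),
    class = "bioc_annotation"
  )
}

#' Read a BioC-JSON article
#'
#' Accepts either a BioC collection (`{"documents": [...]}`, first
#' document used) or a bare document object.  Passage section labels are
#' taken from the `section_label` infon if present, else derived from
#' Auto-CORPus IAO infons (`iao_name_1`, `section_title_1`, ...);
#' unknown infons are preserved verbatim.
#'
#' @param path Path to a BioC-JSON file.
#' @return A [bioc_document()].
#' @export
read_bioc <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc <- if (!is.null(js$documents)) {
    if (!length(js$documents)) stop("schema error at /documents: empty")
    js$documents[[1]]
  } else {
    js
  }
  if (is.null(doc$passages)) {
    stop("schema error at /documents/0: missing 'passages'")
  }
  passages <- lapply(seq_along(doc$passages), function(i) {
    p <- doc$passages[[i]]
    where <- sprintf("/documents/0/passages/%d", i - 1L)
    if (is.null(p$text)) stop(sprintf("schema error at %s: missing 'text'", where))
    if (is.null(p$offset)) stop(sprintf("schema error at %s: missing 'offset'", where))
    infons <- p$infons %||% list()
    lab <- section_label_from_infons(infons)
    infons$section_label <- NULL
    if (!length(infons)) infons <- list()
    anns <- lapply(seq_along(p$annotations %||% list()), function(k) {
      parse_bioc_annotation(p$annotations[[k]],
                            sprintf("%s/annotations/%d", where, k - 1L))
    })
    bioc_passage(text = p$text, offset = p$offset, section_label = lab,
                 infons = infons, annotations = anns)
  })
  d <- bioc_document(
    pmcid = doc$id %||% doc$pmcid %||% "",
    passages = passages,
    domain_tag = (doc$infons %||% list())$domain %||% "other"
  )
  validate_bioc(d)
  d
}

#' Write a BioC-JSON article
#'
#' Emits a one-document BioC collection with fixed key ordering
#' (diff-friendly); `read_bioc(write_bioc(doc))` reproduces `doc`.
#'
#' @param doc A [bioc_document()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bioc <- function(doc, path) {
  stopifnot(inherits(doc, "bioc_document"))
  validate_bioc(doc)
  out <- list(documents = list(list(
    id = doc$pmcid,
    infons = list(domain = doc$domain_tag),
    passages = lapply(doc$passages, function(p) {
      infons <- p$infons
      infons$section_label <- p$section_label
      list(
        infons = infons,
        offset = p$offset,
        text = p$text,
        annotations = lapply(p$annotations, function(a) {
          list(text = a$text, infons = a$infons, id = a$id,
               locations = a$locations)
        })
      )
    })
  )))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Validate a BioC document against the annotation schema
#'
#' Checks that passage offsets are strictly increasing running character
#' positions, passage text is present, every annotation carries the four
#' required elements, and every annotation location slices the article
#' text to exactly the annotation's surface string.  A machine-readable
#' JSON Schema of the dialect ships at
#' `system.file("extdata", "bioc_schema.json", package = "enzner")`.
#'
#' @param doc A [bioc_document()].
#' @return `TRUE`, invisibly; errors name the offending passage.
#' @export
validate_bioc <- function(doc) {
  stopifnot(inherits(doc, "bioc_document"))
  pos <- -1L
  for (i in seq_along(doc$passages)) {
    p <- doc$passages[[i]]
    if (is.null(p$text)) {
      stop(sprintf("passage %d of %s: text is NULL", i, doc$pmcid))
    }
    if (p$offset <= pos) {
      stop(sprintf("passage %d of %s: offset %d not increasing",
                   i, doc$pmcid, p$offset))
    }
    pos <- p$offset + nchar(p$text)
    for (a in p$annotations) {
      for (l in a$locations) {
        local <- l$offset - p$offset
        if (local < 0L || local + l$length > nchar(p$text)) {
          stop(sprintf("annotation %s outside passage %d of %s",
                       a$id, i, doc$pmcid))
        }
        slice <- stringi::stri_sub(p$text, local + 1L, local + l$length)
        if (slice != a$text) {
          stop(sprintf(
            "annotation %s in passage %d of %s: text '%s' != slice '%s'",
            a$id, i, doc$pmcid, a$text, slice))
        }
      }
    }
  }
  invisible(TRUE)
}

#' Full article text of a document
#'
#' Reconstructs the concatenated article text implied by the passage
#' offsets (gaps between passages are filled with newlines).
#'
#' @param doc A [bioc_document()].
#' @return Single character string.
#' @export
doc_text <- function(doc) {
  pieces <- character(0)
  pos <- 0L
  for (p in doc$passages) {
    pieces <- c(pieces, strrep("\n", p$offset - pos), p$text)
    pos <- p$offset + nchar(p$text)
  }
  paste(pieces, collapse = "")
}

#' All annotations of a document as a data frame
#'
#' @param doc An annotated [bioc_document()].
#' @return data.frame with columns `id`, `text`, `identifier`, `method`,
#'   `offset`, `length`, `section_label`, `passage`.
#' @export
doc_annotations <- function(doc) {
  rows <- list()
  for (i in seq_along(doc$passages)) {
    p <- doc$passages[[i]]
    for (a in p$annotations) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = a$id, text = a$text,
        identifier = a$infons$identifier %||% NA_character_,
        method = a$infons$method %||% NA_character_,
        offset = a$locations[[1]]$offset,
        length = a$locations[[1]]$length,
        section_label = p$section_label, passage = i,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = character(0), text = character(0),
                      identifier = character(0), method = character(0),
                      offset = integer(0), length = integer(0),
                      section_label = character(0), passage = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read a per-article abbreviation map
#'
#' Tolerant reader for the abbreviation JSON (`{"ADH": "alcohol
#' dehydrogenase", ...}`).  Non-scalar values are reduced to their first
#' character element; duplicate short forms keep the first definition
#' with a warning.
#'
#' @param path Path to the abbreviation JSON file.
#' @return Named character vector (short form -> definition); may be
#'   empty.
#' @export
read_abbreviations <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(js)) return(stats::setNames(character(0), character(0)))
  vals <- vapply(js, function(v) {
    v <- unlist(v, use.names = FALSE)
    as.character(v[[1]])
  }, "")
  if (anyDuplicated(names(vals))) {
    warning("duplicate abbreviation short forms; keeping first definition")
    vals <- vals[!duplicated(names(vals))]
  }
  vals
}
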