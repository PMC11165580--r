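# Shared fixtures and independent oracles used across the test files.

# small hand-built dictionary exercising nesting, variants and non-ase
tiny_entries <- function() {
  list(
    enzyme_entry("1.1.1.1", c("alcohol dehydrogenase",
                              "aliphatic alcohol dehydrogenase")),
    enzyme_entry("3.1.3.1", c("alkaline phosphatase",
                              "alkaline phosphomonoesterase")),
    enzyme_entry("2.3.2.2", "gamma-glutamyl transpeptidase"),
    enzyme_entry("3.2.1.23", "beta-galactosidase"),
    enzyme_entry("3.2.1.17", "lysozyme"),
    enzyme_entry("1.11.1.6", "catalase"),
    enzyme_entry("2.7.1.1", "hexokinase")
  )
}

tiny_dict <- function() build_hierarchy(tiny_entries())

cached_mini_dict <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- mini_dictionary()
    d
  }
})

# brute-force flat-scan matcher: tries every dictionary form at every
# position of the text (case-insensitive, word-bounded: no letter, digit
# or hyphen adjacent), then removes contained/overlapping shorter spans.
brute_force_direct <- function(text, dict) {
  forms <- all_forms(dict)
  low <- stringi::stri_trans_tolower(text)
  n <- nchar(text)
  hits <- list()
  for (form in forms) {
    locs <- stringi::stri_locate_all_fixed(low, form)[[1]]
    if (is.na(locs[1, 1])) next
    for (r in seq_len(nrow(locs))) {
      s <- locs[r, 1]
      e <- locs[r, 2]
      before <- if (s > 1L) stringi::stri_sub(low, s - 1L, s - 1L) else ""
      after <- if (e < n) stringi::stri_sub(low, e + 1L, e + 1L) else ""
      bad <- "[\\p{L}\\p{N}-]"
      if (nzchar(before) && stringi::stri_detect_regex(before, bad)) next
      if (nzchar(after) && stringi::stri_detect_regex(after, bad)) next
      ec <- dict$ec_index[form]
      hits[[length(hits) + 1L]] <- data.frame(
        start = s - 1L, length = e - s + 1L,
        identifier = if (!is.na(ec)) unname(ec) else
          utils::tail(strsplit(form, " ")[[1]], 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), length = integer(0),
                      identifier = character(0), stringsAsFactors = FALSE))
  }
  h <- unique(do.call(rbind, hits))
  h <- h[order(-h$length, h$start), , drop = FALSE]
  keep <- logical(nrow(h))
  sel_s <- integer(0)
  sel_e <- integer(0)
  for (i in seq_len(nrow(h))) {
    s <- h$start[i]
    e <- s + h$length[i]
    if (!any(s < sel_e & sel_s < e)) {
      keep[i] <- TRUE
      sel_s <- c(sel_s, s)
      sel_e <- c(sel_e, e)
    }
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

# direct matches of a whole document via the package's sentence-wise path
doc_direct_matches <- function(doc, dict) {
  out <- list()
  for (p in doc$passages) {
    for (sent in split_sentences(p$text, p$offset)) {
      m <- direct_match(sent, dict)
      if (nrow(m)) out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), length = integer(0),
                      identifier = character(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  m[order(m$start), c("start", "length", "identifier")]
}

span_key <- function(df) sprintf("%d:%d:%s", df$start, df$length, df$identifier)

# build a one-passage document from sentences of text
one_passage_doc <- function(text, section = "results", pmcid = "PMC0000001",
                            offset = 0L) {
  bioc_document(pmcid, list(bioc_passage(text, offset,
                                         section_label = section)))
}

# random annotation sets on a non-overlapping lattice (slots of width 6
# every 10 chars), so any two spans are identical or disjoint and the
# confusion matrix is pure set arithmetic
random_lattice_set <- function(n_slots = 12L, p = 0.4) {
  slots <- which(stats::runif(n_slots) < p)
  data.frame(offset = (slots - 1L) * 10L,
             length = rep(6L, length(slots)),
             text = sprintf("slot%02d", slots),
             stringsAsFactors = FALSE)
}

fixed_cfg <- function(...) {
  rule_config(timestamp = "2024-01-01T00:00:00Z", ...)
}
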