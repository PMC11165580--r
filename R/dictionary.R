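# Enzyme nomenclature parsing, spelling-variant expansion and the
# hierarchical (root-term-branched) search dictionary.

#' Default Greek letter table
#'
#' Two-column table mapping lowercase Greek symbols to their Latin
#' spelled-out names, used both directions by [expand_variants()].
#' Covers the full Greek alphabet.
#'
#' @return A data.frame with character columns `symbol` and `name`.
#' @export
default_greek_table <- function() {
  data.frame(
    symbol = c("α", "β", "γ", "δ", "ε", "ζ",
               "η", "θ", "ι", "κ", "λ", "μ",
               "ν", "ξ", "ο", "π", "ρ", "σ",
               "τ", "υ", "φ", "χ", "ψ", "ω"),
    name = c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
             "eta", "theta", "iota", "kappa", "lambda", "mu",
             "nu", "xi", "omicron", "pi", "rho", "sigma",
             "tau", "upsilon", "phi", "chi", "psi", "omega"),
    stringsAsFactors = FALSE
  )
}

#' Default "-ase" stoplist
#'
#' Common English words ending in "ase" that must never seed a keyword
#' match (e.g. "phase", "database").
#'
#' @return Character vector of lowercase words.
#' @export
default_stoplist <- function() {
  c("phase", "database", "case", "base", "phrase", "increase",
    "decrease", "release", "disease", "purchase", "phase-")
}

#' Construct an enzyme nomenclature entry
#'
#' @param ec_number Dotted four-field EC identifier (e.g. `"1.1.1.1"`),
#'   or `""` when unknown.
#' @param names Character vector of surface names, primary name first.
#' @param source_line Provenance string (raw input line).
#' @return An object of class `enzyme_entry`.
#' @export
enzyme_entry <- function(ec_number = "", names, source_line = "") {
  names <- trimws(names)
  names <- names[nzchar(names)]
  if (!length(names)) stop("an enzyme entry needs at least one non-empty name")
  ec_number <- trimws(ec_number)
  if (nzchar(ec_number) && !grepl("^\\d+\\.\\d+\\.\\d+\\.\\d+$", ec_number)) {
    stop("malformed EC number: ", ec_number)
  }
  structure(
    list(ec_number = ec_number, names = names, source_line = source_line),
    class = "enzyme_entry"
  )
}

#' Load an enzyme nomenclature list
#'
#' Parses an EC-number-to-names list in one of two dialects:
#' * `"tsv"`: two tab-separated columns, `EC<TAB>name1; name2; ...`
#'   (the EC column may be empty);
#' * `"kegg"`: the KEGG REST flat dialect,
#'   `ec:1.1.1.1<WS>name1; name2; ...` (the `ec:` prefix is optional).
#'   Records flagged "Transferred to"/"Deleted entry" are skipped with
#'   a message.
#'
#' Blank lines and lines starting with `#` are ignored.  Duplicate
#' surface forms across records are preserved; EC conflicts are resolved
#' first-wins when the dictionary is built.
#'
#' @param path Path to the list file.
#' @param dialect `"tsv"` or `"kegg"`.
#' @return List of [enzyme_entry()] objects, with the file's md5 checksum
#'   attached as attribute `"checksum"`.
#' @export
load_enzyme_list <- function(path, dialect = c("tsv", "kegg")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read enzyme list: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  entries <- list()
  for (ln in lines[keep]) {
    if (dialect == "tsv") {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) next
      ec <- trimws(parts[[1]])
      names_field <- parts[[2]]
    } else {
      m <- stringi::stri_match_first_regex(
        ln, "^(?:ec:)?(\\d+\\.\\d+\\.\\d+\\.\\d+)\\s+(.*)$")
      if (is.na(m[1, 1])) next
      ec <- m[1, 2]
      names_field <- m[1, 3]
      if (stringi::stri_detect_regex(names_field,
                                     "^(Transferred to|Deleted entry)",
                                     case_insensitive = TRUE)) {
        message("skipping transferred/deleted EC record: ", ec)
        next
      }
    }
    nms <- trimws(strsplit(names_field, ";", fixed = TRUE)[[1]])
    nms <- nms[nzchar(nms)]
    if (!length(nms)) next
    entries[[length(entries) + 1L]] <- enzyme_entry(ec, nms, source_line = ln)
  }
  if (!length(entries)) {
    stop(sprintf("no enzyme entries parsed from '%s' with dialect '%s'",
                 path, dialect))
  }
  attr(entries, "checksum") <- unname(tools::md5sum(path))
  entries
}

# One-step rewrites of a surface form: toggle each internal hyphen/space,
# swap each Greek symbol <-> spelled-out name occurrence.
variant_neighbours <- function(s, greek) {
  out <- character(0)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  for (i in which(ch %in% c("-", " "))) {
    if (i == 1L || i == n) next
    if (!stringi::stri_detect_regex(ch[i - 1L], "[\\p{L}\\p{N}]") ||
        !stringi::stri_detect_regex(ch[i + 1L], "[\\p{L}\\p{N}]")) next
    alt <- ch
    alt[i] <- if (ch[i] == "-") " " else "-"
    out <- c(out, paste(alt, collapse = ""))
  }
  for (k in seq_len(nrow(greek))) {
    sym <- greek$symbol[k]
    nm <- greek$name[k]
    locs <- stringi::stri_locate_all_fixed(s, sym)[[1]]
    if (!is.na(locs[1, 1])) {
      for (r in seq_len(nrow(locs))) {
        out <- c(out, paste0(stringi::stri_sub(s, 1L, locs[r, 1] - 1L), nm,
                             stringi::stri_sub(s, locs[r, 2] + 1L)))
      }
    }
    # spelled-out name only swaps when not embedded in a longer word
    locs <- stringi::stri_locate_all_regex(
      s, paste0("(?<![\\p{L}])", nm, "(?![\\p{L}])"))[[1]]
    if (!is.na(locs[1, 1])) {
      for (r in seq_len(nrow(locs))) {
        out <- c(out, paste0(stringi::stri_sub(s, 1L, locs[r, 1] - 1L), sym,
                             stringi::stri_sub(s, locs[r, 2] + 1L)))
      }
    }
  }
  unique(out)
}

#' Expand spelling variants of an enzyme name
#'
#' Enzyme names vary in whether words are connected by hyphens or spaces
#' and in whether Greek letters are written as symbols or spelled out.
#' This returns the closure of the name under both transformations:
#' every internal hyphen may become a space and vice versa, and every
#' Greek symbol may become its Latin name and vice versa, in any
#' combination.  The result always contains `name` itself and is a fixed
#' point (expanding any output adds nothing new).
#'
#' @param name Non-empty surface string.
#' @param greek Greek letter table, see [default_greek_table()].
#' @param max_variants Safety cap on the closure size.
#' @return Sorted character vector of variant surface forms.
#' @export
#' @examples
#' expand_variants("beta-galactosidase")
expand_variants <- function(name, greek = default_greek_table(),
                            max_variants = 512L) {
  stopifnot(is.character(name), length(name) == 1L)
  name <- stringi::stri_trim_both(name)
  if (!nzchar(name)) stop("cannot expand an empty name")
  seen <- character(0)
  queue <- name
  while (length(queue) && length(seen) < max_variants) {
    s <- queue[[1L]]
    queue <- queue[-1L]
    if (s %in% seen) next
    seen <- c(seen, s)
    queue <- c(queue, setdiff(variant_neighbours(s, greek), seen))
  }
  sort(unique(seen))
}

final_token <- function(form) {
  toks <- strsplit(form, " ", fixed = TRUE)[[1]]
  toks[[length(toks)]]
}

#' Build the hierarchical enzyme dictionary
#'
#' Indexes every expanded variant of every entry name into a search tree
#' keyed by the name's final token (its "root term", e.g.
#' "dehydrogenase").  Names whose final token ends in "ase" go into
#' `branches`; all others into `non_ase`.  Within a branch, forms are
#' sorted longest-token-count first (ties: descending character length,
#' then lexicographic), which gives the greedy matcher its
#' longest-match-first guarantee.  `ec_index` maps each surface form to
#' the EC number of its (first) source entry; `vocab` holds, per branch,
#' all non-final tokens seen in that branch's forms, used by the keyword
#' matcher's backward extension rule.
#'
#' All dictionary keys and forms are lowercased; matching against
#' article text is case-insensitive while annotations keep the article's
#' original casing.
#'
#' @param entries Non-empty list of [enzyme_entry()] objects.
#' @param greek Greek letter table for variant expansion.
#' @return An object of class `enzyme_dictionary` with elements
#'   `branches`, `non_ase`, `ec_index`, `vocab` and `meta`.
#' @export
build_hierarchy <- function(entries, greek = default_greek_table()) {
  if (!length(entries)) stop("cannot build a dictionary from zero entries")
  forms <- character(0)
  ecs <- character(0)
  # expand every name of every entry; remember first-seen EC per form
  ec_of <- new.env(parent = emptyenv())
  for (e in entries) {
    for (nm in e$names) {
      for (v in expand_variants(stringi::stri_trans_tolower(nm), greek)) {
        prev <- get0(v, envir = ec_of, ifnotfound = NULL)
        if (is.null(prev)) {
          assign(v, e$ec_number, envir = ec_of)
          forms <- c(forms, v)
        } else if (!nzchar(prev) && nzchar(e$ec_number)) {
          assign(v, e$ec_number, envir = ec_of)
        } else if (nzchar(prev) && nzchar(e$ec_number) &&
                   prev != e$ec_number) {
          message(sprintf(
            "EC conflict for surface form '%s': keeping %s, ignoring %s",
            v, prev, e$ec_number))
        }
      }
    }
  }
  forms <- unique(forms)
  roots <- vapply(forms, final_token, "")
  is_ase <- endsWith(roots, "ase")

  split_sorted <- function(f, r) {
    br <- split(f, r)
    lapply(br, function(v) {
      ntok <- stringi::stri_count_fixed(v, " ") + 1L
      v[order(-ntok, -nchar(v), v)]
    })
  }
  branches <- split_sorted(forms[is_ase], roots[is_ase])
  non_ase <- split_sorted(forms[!is_ase], roots[!is_ase])

  ec_index <- vapply(forms, function(f) get(f, envir = ec_of), "")
  ec_index <- ec_index[nzchar(ec_index)]

  vocab <- c(
    lapply(branches, function(v) {
      toks <- unlist(lapply(strsplit(v, " ", fixed = TRUE),
                            function(t) t[-length(t)]))
      unique(toks)
    }),
    lapply(non_ase, function(v) {
      toks <- unlist(lapply(strsplit(v, " ", fixed = TRUE),
                            function(t) t[-length(t)]))
      unique(toks)
    })
  )

  structure(
    list(branches = branches, non_ase = non_ase, ec_index = ec_index,
         vocab = vocab,
         meta = list(
           n_entries = length(entries),
           n_forms = length(forms),
           built = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
           source_checksum = attr(entries, "checksum") %||% NA_character_)),
    class = "enzyme_dictionary"
  )
}

#' @export
print.enzyme_dictionary <- function(x, ...) {
  cat(sprintf(
    "<enzyme_dictionary> %d forms in %d '-ase' branches + %d other branches\n",
    x$meta$n_forms, length(x$branches), length(x$non_ase)))
  invisible(x)
}

#' All surface forms indexed in a dictionary
#'
#' @param dict An `enzyme_dictionary`.
#' @return Character vector of every indexed (lowercase) surface form.
#' @export
all_forms <- function(dict) {
  unname(c(unlist(dict$branches, use.names = FALSE),
           unlist(dict$non_ase, use.names = FALSE)))
}

#' Root-term test for a single token
#'
#' A token is a potential enzyme root when it ends in "ase"
#' (case-insensitively) and is not a stoplisted common word.
#'
#' @param token Character vector of single whitespace-free words.
#' @param stoplist Lowercase words to ignore, see [default_stoplist()].
#' @return Lowercased root word, or `NA_character_` when not a root;
#'   vectorized over `token`.
#' @export
#' @examples
#' root_term_of(c("kinase", "database", "Polymerase"))
root_term_of <- function(token, stoplist = default_stoplist()) {
  tl <- stringi::stri_trans_tolower(token)
  ok <- endsWith(tl, "ase") & !(tl %in% stringi::stri_trans_tolower(stoplist))
  ifelse(ok, tl, NA_character_)
}

#' Serialize / load a hierarchical dictionary as JSON
#'
#' The JSON carries the branch maps, EC index, per-branch vocabularies
#' and build metadata (timestamp, source checksum), so a dictionary can
#' be built once and shipped.
#'
#' @param dict An `enzyme_dictionary`.
#' @param path Output (input) JSON file path.
#' @return `write_dictionary()`: `path`, invisibly.
#'   `read_dictionary()`: an `enzyme_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "enzyme_dictionary"))
  jsonlite::write_json(
    list(branches = dict$branches, non_ase = dict$non_ase,
         ec_index = as.list(dict$ec_index), vocab = dict$vocab,
         meta = dict$meta),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_chr <- function(x) unname(vapply(x, as.character, ""))
  structure(
    list(branches = lapply(js$branches, as_chr),
         non_ase = lapply(js$non_ase, as_chr),
         ec_index = vapply(js$ec_index, as.character, ""),
         vocab = lapply(js$vocab, as_chr),
         meta = js$meta),
    class = "enzyme_dictionary"
  )
}

#' Bundled miniature enzyme dictionary
#'
#' Builds the hierarchical dictionary from the ~200-record nomenclature
#' fixture shipped with the package (all seven EC top classes, non-"ase"
#' enzymes such as lysozyme and trypsin, hyphen/Greek variant cases and
#' nested forms).
#'
#' @return An `enzyme_dictionary`.
#' @export
mini_dictionary <- function() {
  build_hierarchy(load_enzyme_list(mini_dictionary_path(), dialect = "tsv"))
}

#' @rdname mini_dictionary
#' @export
mini_dictionary_path <- function() {
  system.file("extdata", "mini_enzymes.tsv", package = "enzner",
              mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
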