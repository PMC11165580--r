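# Scoring: exact/partial match classification with MUC-style half
# credit, precision/recall/F1, and Jaccard inter-annotator agreement.

#' Match count tallies
#'
#' @param tp,fp,fn Exact true positives, false positives, false
#'   negatives.
#' @param pp Partial positives: predictions overlapping a gold entity
#'   where only the root term was found, or a trailing isoform marker
#'   differs.
#' @return Object of class `match_counts`.
#' @export
match_counts <- function(tp = 0, fp = 0, fn = 0, pp = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, pp >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, pp = pp),
            class = "match_counts")
}

# normalize annotation inputs (data.frame or list of bioc_annotation)
# to a data.frame with offset/length/text
as_span_df <- function(x) {
  if (is.null(x) || (is.list(x) && !length(x) && !is.data.frame(x))) {
    return(data.frame(offset = integer(0), length = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("offset", "length", "text") %in% names(x)))
    return(x[, c("offset", "length", "text")])
  }
  rows <- lapply(x, function(a) {
    if (inherits(a, "bioc_annotation")) {
      data.frame(offset = a$locations[[1]]$offset,
                 length = a$locations[[1]]$length,
                 text = a$text, stringsAsFactors = FALSE)
    } else {
      data.frame(offset = as.integer(a$offset), length = as.integer(a$length),
                 text = as.character(a$text), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

is_token_suffix <- function(short, long) {
  if (short == long || !endsWith(long, short)) return(FALSE)
  prev <- stringi::stri_sub(long, nchar(long) - nchar(short),
                            nchar(long) - nchar(short))
  prev %in% c(" ", "-", "/")
}

drop_trailing_isoform <- function(x) {
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  if (length(toks) < 2L) return(NA_character_)
  last <- toks[[length(toks)]]
  if (stringi::stri_detect_regex(
        last, "^(\\p{N}+[a-z]?|[ivxl]+|[a-z]|[α-ω])$")) {
    paste(toks[-length(toks)], collapse = " ")
  } else {
    NA_character_
  }
}

is_partial_match <- function(a, b) {
  a <- stringi::stri_trans_tolower(trimws(a))
  b <- stringi::stri_trans_tolower(trimws(b))
  if (is_token_suffix(a, b) || is_token_suffix(b, a)) return(TRUE)
  da <- drop_trailing_isoform(a)
  db <- drop_trailing_isoform(b)
  (!is.na(db) && db == a) || (!is.na(da) && da == b)
}

#' Classify predicted vs gold annotations into TP/FP/FN/PP
#'
#' Both sets must reference the same article text.  Pairing is greedy in
#' document order and one-to-one: each prediction is paired with the
#' first unconsumed gold annotation it overlaps.  Exact span-and-text
#' agreement counts as TP; an overlapping pair where one surface is the
#' other's root-term suffix, or differs only by a trailing isoform
#' marker (number, letter, roman numeral, Greek letter), counts as a
#' partial positive (PP); other overlapping pairs count as both FP and
#' FN.  Unmatched predictions are FPs, unmatched gold annotations FNs.
#' True negatives are never counted.
#'
#' @param pred,gold Annotation sets: data.frames with
#'   `offset`/`length`/`text` columns, or lists of `bioc_annotation`
#'   objects.
#' @return A [match_counts()] object.
#' @export
classify_matches <- function(pred, gold) {
  P <- as_span_df(pred)
  G <- as_span_df(gold)
  P <- P[order(P$offset, P$length), , drop = FALSE]
  G <- G[order(G$offset, G$length), , drop = FALSE]
  used <- rep(FALSE, nrow(G))
  tp <- fp <- fn <- pp <- 0L
  for (i in seq_len(nrow(P))) {
    ov <- which(!used &
                G$offset < P$offset[i] + P$length[i] &
                P$offset[i] < G$offset + G$length)
    if (!length(ov)) {
      fp <- fp + 1L
      next
    }
    j <- ov[[1]]
    used[j] <- TRUE
    if (G$offset[j] == P$offset[i] && G$length[j] == P$length[i] &&
        G$text[j] == P$text[i]) {
      tp <- tp + 1L
    } else if (is_partial_match(P$text[i], G$text[j])) {
      pp <- pp + 1L
    } else {
      fp <- fp + 1L
      fn <- fn + 1L
    }
  }
  fn <- fn + sum(!used)
  match_counts(tp = tp, fp = fp, fn = fn, pp = pp)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Proportions in \[0, 1\].
#' @return F1 score; 0 when both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  if ((precision + recall) == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Precision, recall and F1 with partial-positive half credit
#'
#' Partial positives are split equally: `tp' = tp + pp/2`,
#' `fn' = fn + pp/2`, and (by default) `fp' = fp + pp/2`; then
#' `precision = tp'/(tp' + fp')`, `recall = tp'/(tp' + fn')`, and F1 is
#' their harmonic mean.  All-zero counts give all-zero scores.
#'
#' @param counts A [match_counts()] object.
#' @param pp_in_fp Apply the pp/2 credit to the precision denominator
#'   too (default).  With `FALSE`, only TP and FN receive it.
#' @return Object of class `eval_scores` with elements `precision`,
#'   `recall`, `f1`.
#' @export
scores <- function(counts, pp_in_fp = TRUE) {
  stopifnot(inherits(counts, "match_counts"))
  tp <- counts$tp + counts$pp / 2
  fn <- counts$fn + counts$pp / 2
  fp <- counts$fp + if (pp_in_fp) counts$pp / 2 else 0
  precision <- if ((tp + fp) > 0) tp / (tp + fp) else 0
  recall <- if ((tp + fn) > 0) tp / (tp + fn) else 0
  structure(list(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall)),
            class = "eval_scores")
}

#' @export
print.eval_scores <- function(x, ...) {
  cat(sprintf("precision = %.3f  recall = %.3f  F1 = %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Inter-annotator agreement (Jaccard index)
#'
#' Entity level is exact: an annotation counts as agreed when offset,
#' length and text all match; the Jaccard index is
#' `agreed / (a_only + b_only + agreed)`.  Character level is an
#' overlap measure: the Jaccard index of the two sets of annotated
#' character positions.  Both are 0 when all counts are zero, and the
#' measure is symmetric in its arguments.
#'
#' @param a,b Annotation sets (as in [classify_matches()]) over the
#'   same article.
#' @param level Which level the `agreed`/`a_only`/`b_only` counts
#'   report; both Jaccard values are always computed.
#' @return Object of class `agreement_result` with `jaccard_entity`,
#'   `jaccard_character`, `level`, `agreed`, `a_only`, `b_only`.
#' @export
agreement <- function(a, b, level = c("entity", "character")) {
  level <- match.arg(level)
  A <- as_span_df(a)
  B <- as_span_df(b)
  keyA <- sprintf("%d:%d:%s", A$offset, A$length, A$text)
  keyB <- sprintf("%d:%d:%s", B$offset, B$length, B$text)
  keyA <- unique(keyA)
  keyB <- unique(keyB)
  agreed_e <- length(intersect(keyA, keyB))
  a_only_e <- length(setdiff(keyA, keyB))
  b_only_e <- length(setdiff(keyB, keyA))
  tot_e <- agreed_e + a_only_e + b_only_e
  jac_e <- if (tot_e > 0) agreed_e / tot_e else 0

  pos <- function(df) {
    if (!nrow(df)) return(integer(0))
    unique(unlist(lapply(seq_len(nrow(df)), function(i) {
      seq.int(df$offset[i], df$offset[i] + df$length[i] - 1L)
    })))
  }
  pa <- pos(A)
  pb <- pos(B)
  inter_c <- length(intersect(pa, pb))
  union_c <- length(union(pa, pb))
  jac_c <- if (union_c > 0) inter_c / union_c else 0

  if (level == "entity") {
    agreed <- agreed_e
    a_only <- a_only_e
    b_only <- b_only_e
  } else {
    agreed <- inter_c
    a_only <- length(setdiff(pa, pb))
    b_only <- length(setdiff(pb, pa))
  }
  structure(
    list(jaccard_entity = jac_e, jaccard_character = jac_c,
         level = level, agreed = agreed, a_only = a_only, b_only = b_only),
    class = "agreement_result"
  )
}
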