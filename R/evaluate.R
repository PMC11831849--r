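# Collapse a BIO tag to its category (O stays O).
tag_category <- function(tags) {
  ifelse(tags == "O", "O", substring(tags, 3))
}

#' Token-level confusion counts per PHI category
#'
#' Gold and predicted tags are compared token by token after collapsing
#' B/I to the category: a true positive when both agree on a non-O
#' category; a false negative for the gold category when gold is non-O
#' and the prediction disagrees; a false positive for the predicted
#' category when the prediction is non-O and gold disagrees. A non-O/non-O
#' disagreement therefore counts once on each side, keeping per-category
#' marginals consistent. O/O tokens are ignored.
#'
#' @param gold,pred Token data frames with `tag` columns, aligned
#'   token-for-token (same spans).
#' @return Data frame with columns `category`, `tp`, `fp`, `fn`.
#' @export
token_confusion <- function(gold, pred) {
  if (nrow(gold) != nrow(pred) ||
      (nrow(gold) > 0 && !is.null(gold$start) && !is.null(pred$start) &&
       !identical(gold$start, pred$start))) {
    d <- if (nrow(gold) != nrow(pred)) 1L else
      which(gold$start != pred$start)[1]
    stop("token_confusion: token misalignment at token ", d, call. = FALSE)
  }
  g <- tag_category(gold$tag)
  p <- tag_category(pred$tag)
  cats <- phi_categories()
  data.frame(
    category = cats,
    tp = vapply(cats, function(k) sum(g == k & p == k), integer(1)),
    fp = vapply(cats, function(k) sum(p == k & g != k), integer(1)),
    fn = vapply(cats, function(k) sum(g == k & p != k), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

sum_confusions <- function(counts_list) {
  out <- counts_list[[1]]
  for (k in counts_list[-1]) {
    out$tp <- out$tp + k$tp
    out$fp <- out$fp + k$fp
    out$fn <- out$fn + k$fn
  }
  out
}

#' Precision/recall/F1 from confusion counts
#'
#' Precision is TP/(TP+FP) and recall TP/(TP+FN), each defined as 0 for
#' 0/0; F1 is their harmonic mean (0 when P+R is 0). Micro totals sum the
#' per-category counts. Internal values are kept at full precision; the
#' print method renders them rounded half-up to two decimals, the
#' convention of the reported tables.
#'
#' @param counts Per-category count frame from [token_confusion()].
#' @return An object of class `eval_report`: the counts with `precision`,
#'   `recall`, `f1` columns and a `Total` micro row.
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(counts$tp >= 0), all(counts$fp >= 0), all(counts$fn >= 0))
  total <- data.frame(category = "Total", tp = sum(counts$tp),
                      fp = sum(counts$fp), fn = sum(counts$fn),
                      stringsAsFactors = FALSE)
  tab <- rbind(counts, total)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tab$precision <- safe_div(tab$tp, tab$tp + tab$fp)
  tab$recall <- safe_div(tab$tp, tab$tp + tab$fn)
  tab$f1 <- safe_div(2 * tab$precision * tab$recall,
                     tab$precision + tab$recall)
  structure(tab, class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, ...) {
  shown <- as.data.frame(x)
  for (col in c("precision", "recall", "f1")) {
    shown[[col]] <- sprintf("%.2f", round_half_up(shown[[col]], 2))
  }
  print(shown, row.names = FALSE)
  invisible(x)
}

# Coerce the various note containers to a named list of tagged token
# frames keyed by note_id.
as_tagged_list <- function(x) {
  if (inherits(x, "tagged_corpus")) {
    out <- lapply(x$notes, `[[`, "tokens")
    names(out) <- vapply(x$notes, function(e) e$note$note_id, character(1))
    return(out)
  }
  stopifnot(is.list(x), !is.null(names(x)) || length(x) == 0)
  x
}

#' Evaluate predictions against gold token tags
#'
#' Sums [token_confusion()] over the shared notes and computes the
#' per-category and micro metrics. Gold and predictions must cover the
#' same note set under the same tokenization.
#'
#' @param gold,pred Named lists of tagged token frames (note_id ->
#'   tokens), or `tagged_corpus` objects.
#' @return An `eval_report`.
#' @export
evaluate_corpus <- function(gold, pred) {
  gold <- as_tagged_list(gold)
  pred <- as_tagged_list(pred)
  missing <- setdiff(names(gold), names(pred))
  extra <- setdiff(names(pred), names(gold))
  if (length(missing) || length(extra)) {
    stop("evaluate_corpus: note sets differ (missing: ",
         paste(utils::head(missing, 3), collapse = ", "), "; extra: ",
         paste(utils::head(extra, 3), collapse = ", "), ")", call. = FALSE)
  }
  counts <- lapply(names(gold), function(id) {
    token_confusion(gold[[id]], pred[[id]])
  })
  if (!length(counts)) return(compute_metrics(token_confusion(
    data.frame(tag = character()), data.frame(tag = character()))))
  compute_metrics(sum_confusions(counts))
}

#' Tag notes with the rule engine
#'
#' Convenience wrapper producing token-level BIO predictions of the rule
#' engine for evaluation: applies the rules and projects the matches onto
#' the tokens.
#'
#' @param notes List of [clinical_note()] objects.
#' @param ruleset A [compile_ruleset()] result.
#' @return Named list of tagged token frames.
#' @export
rule_tag_notes <- function(notes, ruleset) {
  texts <- vapply(notes, function(n) n$text, character(1))
  raw <- rule_match_corpus(texts, ruleset)
  out <- lapply(seq_along(notes), function(i) {
    project_to_bio(tokenize_note(notes[[i]]), resolve_overlaps(raw[[i]]))
  })
  names(out) <- vapply(notes, function(n) n$note_id, character(1))
  out
}

#' Gold token tags for annotated notes
#'
#' Projects the gold `phi` annotations carried by the notes onto their
#' tokens.
#'
#' @param notes List of [clinical_note()] objects with `phi` tables.
#' @return Named list of tagged token frames.
#' @export
gold_tag_notes <- function(notes) {
  out <- lapply(notes, function(n) {
    project_to_bio(tokenize_note(n),
                   if (is.null(n$phi)) empty_annotations() else n$phi)
  })
  names(out) <- vapply(notes, function(n) n$note_id, character(1))
  out
}
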