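# Character script classes used by the tokenizer: 0 whitespace, 1 Hangul
# (syllables + compatibility jamo), 2 Latin letters/digits, 3 anything else.
char_classes <- function(text) {
  cp <- utf8ToInt(text)
  cls <- rep.int(3L, length(cp))
  cls[(cp >= 0xAC00 & cp <= 0xD7A3) | (cp >= 0x1100 & cp <= 0x11FF) |
        (cp >= 0x3130 & cp <= 0x318F)] <- 1L
  cls[(cp >= 0x30 & cp <= 0x39) | (cp >= 0x41 & cp <= 0x5A) |
        (cp >= 0x61 & cp <= 0x7A)] <- 2L
  cls[cp %in% c(0x20, 0x09, 0x0A, 0x0D, 0x0C, 0x0B, 0xA0)] <- 0L
  cls
}

#' Tokenize a clinical note
#'
#' Tokens are maximal runs split at whitespace and then at boundaries
#' between the Hangul, Latin/digit and punctuation script classes, so that
#' `"2019-02-04 촬영"` becomes `2019`, `-`, `02`, `-`, `04`, `촬영`.
#' Concatenating the tokens with the original inter-token text reconstructs
#' the note exactly.
#'
#' @param note A [clinical_note()] or a plain (normalized) string.
#' @return Data frame with columns `surface`, `start`, `end` (0-based,
#'   half-open, code points), in note order.
#' @export
tokenize_note <- function(note) {
  text <- if (inherits(note, "clinical_note")) note$text else
    normalize_text(note)
  if (!nzchar(text)) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  cls <- char_classes(text)
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(surface = stringi::stri_sub(text, starts[keep], ends[keep]),
             start = starts[keep] - 1L, end = ends[keep],
             stringsAsFactors = FALSE)
}

#' Project character-span matches onto BIO token tags
#'
#' A token receives category X when at least one of its characters
#' overlaps an X match (partial-overlap tokens inherit the category so
#' that masking never leaks a fragment); the first token covered by a
#' match gets `B-X` and the following ones `I-X`. Staff and patient
#' subcategories both map to `PER`. All other tokens are `O`.
#'
#' @param tokens Token data frame from [tokenize_note()].
#' @param matches Non-overlapping match/annotation data frame (`start`,
#'   `end`, `category`).
#' @return The token data frame with a `tag` column added.
#' @export
project_to_bio <- function(tokens, matches) {
  tags <- rep.int("O", nrow(tokens))
  if (!is.null(matches) && nrow(matches)) {
    m <- matches[order(matches$start), , drop = FALSE]
    if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
      stop("project_to_bio: overlapping matches", call. = FALSE)
    }
    for (i in seq_len(nrow(m))) {
      idx <- which(tokens$start < m$end[i] & tokens$end > m$start[i] &
                     tags == "O")
      if (!length(idx)) next
      tags[idx] <- paste0("I-", m$category[i])
      tags[idx[1]] <- paste0("B-", m$category[i])
    }
  }
  tokens$tag <- tags
  tokens
}

# Is a tag sequence BIO-valid (every I-X preceded by B-X or I-X of same X)?
bio_valid <- function(tags) {
  if (!length(tags)) return(TRUE)
  prev <- c("O", tags[-length(tags)])
  is_i <- startsWith(tags, "I-")
  ok <- !is_i | (substring(prev, 3) == substring(tags, 3) & prev != "O")
  all(ok)
}

# Count B-X runs per category in a list of tagged token frames.
count_phi_words <- function(tagged) {
  counts <- stats::setNames(integer(length(phi_categories())),
                            phi_categories())
  for (tk in tagged) {
    b <- tk$tag[startsWith(tk$tag, "B-")]
    if (length(b)) {
      tb <- table(substring(b, 3))
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
  }
  counts
}

#' Build a pseudo-labeled BIO corpus
#'
#' Applies the rule set to the candidate notes, keeps only notes with at
#' least one match (the tiers count PHI-bearing notes only), samples
#' `n_notes` of them uniformly without replacement under `seed`, and
#' projects the matches onto BIO token tags.
#'
#' @param notes List of [clinical_note()] objects.
#' @param ruleset A [compile_ruleset()] result.
#' @param tier Tier name (`"small"`, `"medium"`, `"large1"`, `"large2"`,
#'   `"custom"`).
#' @param n_notes Number of PHI-bearing notes to sample.
#' @param seed Integer seed controlling the sample.
#' @param prepared Optional precomputed pool from [prepare_pool()]; avoids
#'   re-running the rules when many corpora are drawn from one pool.
#' @return An object of class `tagged_corpus`: `tier`, `notes` (each a
#'   list with the note, its tagged tokens and its annotation spans) and
#'   `phi_word_counts` per category.
#' @export
build_corpus <- function(notes, ruleset, tier = "custom", n_notes,
                         seed = 1L, prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_pool(notes, ruleset)
  cand <- which(vapply(prepared$matches, nrow, integer(1)) > 0L)
  if (n_notes > length(cand)) {
    stop("build_corpus: requested ", n_notes, " notes but only ",
         length(cand), " contain at least one rule match", call. = FALSE)
  }
  sel <- with_seed(seed, cand[sample(length(cand))])[seq_len(n_notes)]
  entries <- lapply(sel, function(i) {
    tk <- project_to_bio(prepared$tokens[[i]], prepared$matches[[i]])
    list(note = prepared$notes[[i]], tokens = tk,
         phi = prepared$matches[[i]], pool_index = i)
  })
  new_tagged_corpus(tier, entries)
}

new_tagged_corpus <- function(tier, entries) {
  structure(list(tier = tier, notes = entries,
                 phi_word_counts = count_phi_words(
                   lapply(entries, `[[`, "tokens"))),
            class = "tagged_corpus")
}

#' @export
print.tagged_corpus <- function(x, ...) {
  cat(sprintf("<tagged_corpus '%s': %d notes, %d PHI words>\n",
              x$tier, length(x$notes), sum(x$phi_word_counts)))
  print(x$phi_word_counts)
  invisible(x)
}

#' Precompute rule matches and tokens for a note pool
#'
#' Runs the rule engine and tokenizer once over a pool of notes so that
#' repeated [build_corpus()] draws (different tiers and seeds) do not
#' re-match the same text.
#'
#' @inheritParams build_corpus
#' @return A list with `notes`, `tokens` and resolved `matches`, aligned
#'   by index.
#' @export
prepare_pool <- function(notes, ruleset) {
  texts <- vapply(notes, function(n) n$text, character(1))
  raw <- rule_match_corpus(texts, ruleset)
  matches <- lapply(seq_along(raw), function(i) {
    m <- resolve_overlaps(raw[[i]])
    m$surface <- stringi::stri_sub(texts[i], m$start + 1L, m$end)
    m
  })
  list(notes = notes, tokens = lapply(notes, tokenize_note),
       matches = matches)
}

#' Create a correction list
#'
#' @param removals Data frame (`note_id`, `start`, `end`) of false-positive
#'   annotation spans to delete.
#' @param additions List of [clinical_note()] objects carrying gold `phi`
#'   annotations (e.g. manually labeled notes from other departments).
#' @return An object of class `correction_list`.
#' @export
correction_list <- function(removals = NULL, additions = list()) {
  if (is.null(removals) || !nrow(removals)) {
    removals <- data.frame(note_id = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  }
  structure(list(removals = removals, additions = additions),
            class = "correction_list")
}

#' Flag pseudo-label false positives against gold annotations
#'
#' Compares a pseudo-labeled corpus with the gold annotations carried by
#' its notes and returns the rule matches that overlap no gold span of
#' the same note -- the corpus-level correction the manually corrected
#' tier applies.
#'
#' @param corpus A [build_corpus()] result whose notes carry gold `phi`.
#' @param additions Optional gold-annotated notes to append.
#' @return A [correction_list()].
#' @export
derive_corrections <- function(corpus, additions = list()) {
  rem <- lapply(corpus$notes, function(e) {
    gold <- e$note$phi
    m <- e$phi
    if (is.null(m) || !nrow(m)) return(NULL)
    fp <- vapply(seq_len(nrow(m)), function(i) {
      if (is.null(gold) || !nrow(gold)) return(TRUE)
      !any(m$start[i] < gold$end & m$end[i] > gold$start)
    }, logical(1))
    if (!any(fp)) return(NULL)
    data.frame(note_id = e$note$note_id, start = m$start[fp],
               end = m$end[fp], stringsAsFactors = FALSE)
  })
  correction_list(do.call(rbind, rem), additions)
}

#' Apply corpus-level corrections
#'
#' Removed spans revert their tokens to `O`; a note whose last annotation
#' is removed is dropped; addition notes (with gold annotations) are
#' appended and projected to BIO. This is the manual-correction workflow
#' that turns an uncorrected pseudo-labeled tier into its corrected
#' counterpart.
#'
#' @param corpus A `tagged_corpus`.
#' @param corrections A [correction_list()].
#' @param tier Tier name of the corrected corpus.
#' @return A new `tagged_corpus`.
#' @export
apply_corrections <- function(corpus, corrections, tier = "large2") {
  rem <- corrections$removals
  entries <- corpus$notes
  if (nrow(rem)) {
    ids <- vapply(entries, function(e) e$note$note_id, character(1))
    for (r in seq_len(nrow(rem))) {
      i <- match(rem$note_id[r], ids)
      hit <- if (!is.na(i))
        which(entries[[i]]$phi$start == rem$start[r] &
                entries[[i]]$phi$end == rem$end[r]) else integer(0)
      if (!length(hit)) {
        stop("apply_corrections: removal references no annotation (note ",
             rem$note_id[r], ", span [", rem$start[r], ",", rem$end[r],
             "))", call. = FALSE)
      }
      entries[[i]]$phi <- entries[[i]]$phi[-hit[1], , drop = FALSE]
    }
    entries <- lapply(entries, function(e) {
      e$tokens <- project_to_bio(e$tokens[setdiff(names(e$tokens), "tag")],
                                 e$phi)
      e
    })
    entries <- Filter(function(e) any(e$tokens$tag != "O"), entries)
  }
  for (note in corrections$additions) {
    stopifnot(inherits(note, "clinical_note"), !is.null(note$phi))
    tk <- project_to_bio(tokenize_note(note), note$phi)
    entries <- c(entries, list(list(note = note, tokens = tk,
                                    phi = note$phi)))
  }
  new_tagged_corpus(tier, entries)
}

#' Read / write a correction list as JSONL
#'
#' One JSON object per line. Removal records carry
#' `{"type":"removal","note_id":...,"start":...,"end":...}`; addition
#' records carry a full note (`type":"addition"`, `note_id`, `department`,
#' `text`, gold `phi`).
#'
#' @param path JSONL file path.
#' @return `read_corrections` returns a [correction_list()];
#'   `write_corrections` the path, invisibly.
#' @export
read_corrections <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  removals <- list()
  additions <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$type)) {
      stop("read_corrections: malformed record at line ", i, " of ", path,
           call. = FALSE)
    }
    if (rec$type == "removal") {
      removals[[length(removals) + 1L]] <- data.frame(
        note_id = rec$note_id, start = as.integer(rec$start),
        end = as.integer(rec$end), stringsAsFactors = FALSE)
    } else if (rec$type == "addition") {
      dep <- if (is.null(rec$department)) "radiology" else rec$department
      additions[[length(additions) + 1L]] <- clinical_note(
        rec$note_id, rec$text, dep,
        phi = if (!is.null(rec$phi) && length(rec$phi))
          as.data.frame(rec$phi))
    } else {
      stop("read_corrections: unknown record type '", rec$type,
           "' at line ", i, call. = FALSE)
    }
  }
  correction_list(do.call(rbind, removals), additions)
}

#' @rdname read_corrections
#' @param corrections A [correction_list()].
#' @export
write_corrections <- function(corrections, path) {
  rem <- corrections$removals
  lines <- character(0)
  if (!is.null(rem) && nrow(rem)) {
    lines <- vapply(seq_len(nrow(rem)), function(i) {
      jsonlite::toJSON(list(type = "removal", note_id = rem$note_id[i],
                            start = rem$start[i], end = rem$end[i]),
                       auto_unbox = TRUE)
    }, character(1))
  }
  lines <- c(lines, vapply(corrections$additions, function(n) {
    rec <- list(type = "addition", note_id = n$note_id,
                department = n$department, text = n$text)
    if (!is.null(n$phi) && nrow(n$phi)) rec$phi <- n$phi
    jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows", na = "null")
  }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a BIO corpus in CoNLL two-column format
#'
#' One `token TAB tag` line per token, blank line between notes.
#'
#' @param corpus A `tagged_corpus`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_conll <- function(corpus, path) {
  blocks <- vapply(corpus$notes, function(e) {
    paste(paste(e$tokens$surface, e$tokens$tag, sep = "\t"),
          collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Read a CoNLL two-column BIO corpus
#'
#' Inverse of [write_conll()] for tokens and tags (character offsets are
#' not stored in the format).
#'
#' @param path Path to the CoNLL file.
#' @return List of data frames with columns `surface` and `tag`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  grp <- cumsum(!nzchar(lines))
  keep <- nzchar(lines)
  parts <- split(lines[keep], grp[keep])
  unname(lapply(parts, function(ls) {
    sp <- stringi::stri_split_fixed(ls, "\t", n = 2, simplify = TRUE)
    data.frame(surface = sp[, 1], tag = sp[, 2], stringsAsFactors = FALSE)
  }))
}
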