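#' Path to the default rule-set configuration
#'
#' @return Path of the YAML file shipping the default 51-rule set.
#' @export
default_rules_path <- function() {
  system.file("extdata", "rules.yaml", package = "deidr", mustWork = TRUE)
}

# Expected per-family rule counts for the default set.
expected_rule_counts <- function() {
  c("DAT" = 18L, "PER/staff" = 8L, "PER/patient" = 3L, "ORG" = 13L,
    "LOC" = 1L, "NUM" = 4L, "ETC" = 4L)
}

# Escape regex metacharacters in a vocabulary entry.
regex_escape <- function(x) {
  stringi::stri_replace_all_regex(x, "([.^$|()\\[\\]{}*+?\\\\-])", "\\\\$1")
}

# Build an alternation over a vocabulary, longest alias first so that
# e.g. 고대안암 is preferred over its substring 안암. An empty vocabulary
# yields a pattern that can never match, keeping the rule count stable.
vocab_alternation <- function(vocab) {
  if (length(vocab) == 0) return("(?!x)x")
  vocab <- vocab[order(-stringi::stri_length(vocab))]
  paste(regex_escape(vocab), collapse = "|")
}

#' Compile a PHI rule set
#'
#' Reads a YAML rule configuration (see [default_rules_path()] for the
#' shipped default), interpolates the hospital/region/extension
#' vocabularies into the patterns, checks that every pattern compiles and
#' exposes its PHI capture group, and enforces the structural invariant of
#' the default family sizes: 18 DAT, 8 PER-staff, 3 PER-patient, 13 ORG,
#' 1 LOC, 4 NUM and 4 ETC rules -- 51 in total.
#'
#' @param config Path to a YAML file, or an already-parsed list with
#'   elements `rules` and `vocab`.
#' @param check_counts Enforce the 51-rule per-category invariant
#'   (disable when compiling a custom site-specific set).
#' @return An object of class `phi_ruleset`: a rule table plus the
#'   vocabularies it was compiled against.
#' @export
compile_ruleset <- function(config = default_rules_path(), check_counts = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  vocab <- config$vocab
  if (is.null(vocab)) vocab <- list()
  for (v in c("hospital", "region", "extension")) {
    if (is.null(vocab[[v]])) vocab[[v]] <- character()
    vocab[[v]] <- stringi::stri_trans_nfc(as.character(vocab[[v]]))
  }
  rows <- lapply(config$rules, function(r) {
    pattern <- stringi::stri_trans_nfc(r$pattern)
    for (v in names(vocab)) {
      pattern <- stringi::stri_replace_all_fixed(
        pattern, paste0("{", v, "}"), vocab_alternation(vocab[[v]]))
    }
    ok <- tryCatch({stringi::stri_detect_regex("", pattern); TRUE},
                   error = function(e) FALSE, warning = function(w) TRUE)
    if (!ok) {
      stop("compile_ruleset: pattern for rule '", r$id,
           "' does not compile", call. = FALSE)
    }
    n_groups <- stringi::stri_count_regex(pattern, "\\((?!\\?)")
    gi <- if (is.null(r$phi_group)) 1L else as.integer(r$phi_group)
    if (gi < 1 || gi > n_groups) {
      stop("compile_ruleset: phi_group ", gi, " not present in rule '",
           r$id, "'", call. = FALSE)
    }
    data.frame(rule_id = r$id, category = r$category,
               subcategory = if (is.null(r$subcategory)) NA_character_
                             else r$subcategory,
               pattern = pattern, phi_group = gi,
               priority = as.integer(r$priority),
               description = if (is.null(r$description)) ""
                             else r$description,
               stringsAsFactors = FALSE)
  })
  rules <- do.call(rbind, rows)
  if (anyDuplicated(rules$rule_id)) {
    stop("compile_ruleset: duplicate rule_id '",
         rules$rule_id[anyDuplicated(rules$rule_id)], "'", call. = FALSE)
  }
  if (!all(rules$category %in% phi_categories())) {
    stop("compile_ruleset: unknown category in rule set", call. = FALSE)
  }
  fam <- ifelse(rules$category == "PER",
                paste0("PER/", rules$subcategory), rules$category)
  counts <- table(fam)
  if (check_counts) {
    want <- expected_rule_counts()
    got <- as.integer(counts[names(want)])
    got[is.na(got)] <- 0L
    if (!identical(got, unname(want))) {
      off <- names(want)[which(got != unname(want))[1]]
      stop("compile_ruleset: rule count mismatch for ", off, ": expected ",
           want[[off]], ", got ", got[which(names(want) == off)],
           call. = FALSE)
    }
  }
  structure(list(rules = rules,
                 hospital_vocab = vocab$hospital,
                 region_vocab = vocab$region,
                 extension_vocab = vocab$extension,
                 category_counts = counts),
            class = "phi_ruleset")
}

#' @export
print.phi_ruleset <- function(x, ...) {
  cat(sprintf("<phi_ruleset: %d rules>\n", nrow(x$rules)))
  print(x$category_counts)
  invisible(x)
}

# Run (a subset of) the rules over a character vector of texts.
# Returns a list (one element per text) of raw match data frames with the
# PHI capture-group span only, 0-based half-open offsets.
rule_match_corpus <- function(texts, ruleset, categories = NULL,
                              subcategory = NULL) {
  rules <- ruleset$rules
  if (!is.null(categories)) rules <- rules[rules$category %in% categories, ]
  if (!is.null(subcategory)) rules <- rules[!is.na(rules$subcategory) &
                                              rules$subcategory %in% subcategory, ]
  acc <- vector("list", nrow(rules))
  for (k in seq_len(nrow(rules))) {
    locs <- stringi::stri_locate_all_regex(texts, rules$pattern[k],
                                           capture_groups = TRUE,
                                           omit_no_match = TRUE)
    ns <- vapply(locs, nrow, integer(1))
    hit <- which(ns > 0L)
    if (!length(hit)) next
    gmat <- do.call(rbind, lapply(locs[hit], function(m) {
      attr(m, "capture_groups")[[rules$phi_group[k]]]
    }))
    acc[[k]] <- data.frame(
      text_idx = rep.int(hit, ns[hit]),
      rule_id = rules$rule_id[k],
      category = rules$category[k],
      subcategory = rules$subcategory[k],
      start = as.integer(gmat[, 1]) - 1L,
      end = as.integer(gmat[, 2]),
      priority = rules$priority[k],
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, acc)
  out <- rep(list(empty_matches()), length(texts))
  if (is.null(all) || nrow(all) == 0) return(out)
  all <- all[!is.na(all$start), , drop = FALSE]
  for (i in unique(all$text_idx)) {
    m <- all[all$text_idx == i, setdiff(names(all), "text_idx"), drop = FALSE]
    rownames(m) <- NULL
    out[[i]] <- m
  }
  out
}

empty_matches <- function() {
  data.frame(rule_id = character(), category = character(),
             subcategory = character(), start = integer(), end = integer(),
             priority = integer(), stringsAsFactors = FALSE)
}

#' Resolve overlapping rule matches
#'
#' Conflicts between candidate matches are resolved by a total order:
#' the longer span wins; on equal length ORG beats LOC (a city name
#' adjoined to a known hospital is an organization), then DAT, PER, NUM,
#' ETC; remaining ties go to the leftmost span, then the lower rule
#' priority number, then the rule id. The result is a unique set of
#' pairwise non-overlapping matches sorted by start offset.
#'
#' @param matches Raw match data frame (as produced by the per-category
#'   matchers before resolution).
#' @return Non-overlapping match data frame sorted by span start.
#' @export
resolve_overlaps <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0) return(empty_matches())
  len <- matches$end - matches$start
  ord <- order(-len, category_rank(matches$category), matches$start,
               matches$priority, matches$rule_id)
  m <- matches[ord, , drop = FALSE]
  kept_start <- integer(0)
  kept_end <- integer(0)
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!any(m$start[i] < kept_end & m$end[i] > kept_start)) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, m$start[i])
      kept_end <- c(kept_end, m$end[i])
    }
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$start), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Shared implementation of the per-category matchers.
match_category <- function(note, ruleset, categories, subcategory = NULL) {
  stopifnot(inherits(note, "clinical_note"))
  raw <- rule_match_corpus(note$text, ruleset, categories, subcategory)[[1]]
  m <- resolve_overlaps(raw)
  m$surface <- stringi::stri_sub(note$text, m$start + 1L, m$end)
  m
}

#' Match date expressions
#'
#' Runs the DAT rule family (numeric formats such as `2019-02-04` and
#' `2019.02.04`, Korean 년/월/일 notation, abbreviated quote-mark years,
#' English month names, compact and time-stamped forms) and resolves
#' overlaps. Short numeric ranges such as `1.2-1.7` are not dates: the
#' dash/dot patterns require a plausible 4-digit year.
#'
#' @param note A [clinical_note()].
#' @param ruleset A [compile_ruleset()] result.
#' @return Match data frame (`rule_id`, `category`, `subcategory`,
#'   `start`, `end`, `priority`, `surface`), sorted by span start.
#' @export
match_dates <- function(note, ruleset) match_category(note, ruleset, "DAT")

#' Match person names (medical staff and patients)
#'
#' Staff names fire on action contexts (`NAME 확인함`, `confirmed by NAME`,
#' `by NAME`, `from NAME`), job-title markers (의료진, 판독의, 교수) and
#' slash-delimited physician initials (`/jmk/`). Patient names fire on the
#' 환자이름 / patient name identifier patterns. Only the name capture
#' group becomes the match span; identifier words are never masked. The
#' documented over-trigger of the 확인함 rule (e.g. 상기 in 상기확인함)
#' is reproduced deliberately.
#'
#' @inheritParams match_dates
#' @return Match data frame; `subcategory` is `"staff"` or `"patient"`.
#' @export
match_person <- function(note, ruleset) match_category(note, ruleset, "PER")

#' Match organizations and regions
#'
#' ORG matches come from the hospital vocabulary, words bearing
#' 병원/대학교/의원 and clinic-specialty suffixes, alias families and
#' English hospital names; the single LOC rule fires on configured
#' standalone region names. A city name adjoined to a known hospital
#' resolves to ORG, not LOC. Documented homonym false positives (고려 as
#' "considering", 중앙 in 중앙값, context-blind CMC) are reproduced, not
#' fixed: the pipeline corrects them downstream at the corpus level.
#'
#' @inheritParams match_dates
#' @return Match data frame with ORG and LOC rows.
#' @export
match_org_loc <- function(note, ruleset) {
  match_category(note, ruleset, c("ORG", "LOC"))
}

#' Match numbers and miscellaneous PHI
#'
#' NUM matches are identifier-anchored digit runs (전화번호, Tel., T.,
#' 환자번호, 내선) plus any vocabulary-listed extension numbers; a bare
#' 4-digit number with no identifier and no vocabulary hit is not matched
#' because it cannot be distinguished from a year. ETC matches cover age,
#' sex and nationality expressions.
#'
#' @inheritParams match_dates
#' @return Match data frame with NUM and ETC rows.
#' @export
match_num_etc <- function(note, ruleset) {
  match_category(note, ruleset, c("NUM", "ETC"))
}

#' Apply the full rule set to a note
#'
#' Runs every rule, keeps the PHI capture-group spans, resolves overlaps
#' with [resolve_overlaps()] and returns the matches sorted by span start.
#' Deterministic: identical text yields identical matches.
#'
#' @inheritParams match_dates
#' @return Match data frame over all six categories.
#' @export
apply_rules <- function(note, ruleset) match_category(note, ruleset, NULL)

#' Mask matched PHI spans
#'
#' Replaces each match span by its category placeholder (`[DAT]`, `[PER]`,
#' `[ORG]`, `[LOC]`, `[NUM]`, `[ETC]`); text outside the spans is
#' unchanged. Identifier words survive masking because they are never part
#' of the match span.
#'
#' @param note A [clinical_note()] (or a plain string).
#' @param matches Non-overlapping match data frame for that note.
#' @return The masked text.
#' @export
mask_text <- function(note, matches) {
  text <- if (inherits(note, "clinical_note")) note$text else
    normalize_text(note)
  if (is.null(matches) || nrow(matches) == 0) return(text)
  m <- matches[order(matches$start), , drop = FALSE]
  if (any(m$start < 0 | m$end > stringi::stri_length(text))) {
    stop("mask_text: span out of bounds", call. = FALSE)
  }
  if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
    stop("mask_text: overlapping spans", call. = FALSE)
  }
  for (i in rev(seq_len(nrow(m)))) {
    stringi::stri_sub(text, m$start[i] + 1L, m$end[i]) <-
      paste0("[", m$category[i], "]")
  }
  text
}
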