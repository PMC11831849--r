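# Shared fixtures, built in code. The default rule set is compiled once.
default_ruleset <- compile_ruleset()

note_of <- function(text, id = "t1", department = "radiology", phi = NULL) {
  clinical_note(id, text, department, phi = phi)
}

# Independent brute-force oracle for apply_rules: run every rule on its own,
# extract the PHI group spans directly, then resolve conflicts with a naive
# quadratic elimination under the documented total order.
oracle_apply_rules <- function(texts, ruleset) {
  rules <- ruleset$rules
  per_rule <- lapply(seq_len(nrow(rules)), function(k) {
    locs <- stringi::stri_locate_all_regex(texts, rules$pattern[k],
                                           capture_groups = TRUE)
    lapply(locs, function(m) {
      cg <- attr(m, "capture_groups")[[rules$phi_group[k]]]
      cg <- cg[!is.na(cg[, 1]), , drop = FALSE]
      if (!nrow(cg)) return(NULL)
      data.frame(rule_id = rules$rule_id[k], category = rules$category[k],
                 start = cg[, 1] - 1L, end = cg[, 2],
                 priority = rules$priority[k], stringsAsFactors = FALSE)
    })
  })
  lapply(seq_along(texts), function(i) {
    cand <- do.call(rbind, lapply(per_rule, `[[`, i))
    if (is.null(cand) || !nrow(cand)) {
      return(data.frame(start = integer(), end = integer(),
                        category = character()))
    }
    rank <- match(cand$category, c("ORG", "LOC", "DAT", "PER", "NUM", "ETC"))
    len <- cand$end - cand$start
    # repeatedly take the best remaining candidate, discard its overlaps
    kept <- list()
    remaining <- cand
    r_rank <- rank
    r_len <- len
    while (nrow(remaining)) {
      best <- order(-r_len, r_rank, remaining$start,
                    remaining$priority, remaining$rule_id)[1]
      b <- remaining[best, ]
      kept[[length(kept) + 1L]] <- b
      ok <- remaining$end <= b$start | remaining$start >= b$end
      remaining <- remaining[ok, , drop = FALSE]
      r_rank <- r_rank[ok]
      r_len <- r_len[ok]
    }
    out <- do.call(rbind, kept)
    out <- out[order(out$start), c("start", "end", "category")]
    rownames(out) <- NULL
    out
  })
}

# Independent brute-force tally for token_confusion: one explicit loop per
# token and per category.
oracle_confusion <- function(gold_tags, pred_tags) {
  strip <- function(x) ifelse(x == "O", "O", substring(x, 3))
  g <- strip(gold_tags)
  p <- strip(pred_tags)
  out <- data.frame(category = phi_categories(), tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(g)) {
    for (k in seq_len(nrow(out))) {
      cat <- out$category[k]
      if (g[i] == cat && p[i] == cat) out$tp[k] <- out$tp[k] + 1L
      if (p[i] == cat && g[i] != cat) out$fp[k] <- out$fp[k] + 1L
      if (g[i] == cat && p[i] != cat) out$fn[k] <- out$fn[k] + 1L
    }
  }
  out
}

random_tagseq <- function(n) {
  tags <- c("O", paste0("B-", phi_categories()), paste0("I-", phi_categories()))
  sample(tags, n, replace = TRUE, prob = c(10, rep(1, 12)))
}
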