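#' Pipeline configuration
#'
#' Desk-scale defaults for the end-to-end run: a training pool of 4,000
#' PHI-bearing synthetic notes, a 400-note held-out test set, 15% of PHI
#' instances rendered out of rule scope, and a training corpus of 3,200
#' notes (one tenth of the source study's largest tier).
#'
#' @param seed Master seed; every stage derives its stream from it.
#' @param n_pool Size of the PHI-bearing training pool.
#' @param n_test Held-out test-set size.
#' @param train_notes Pseudo-labeled notes to train on.
#' @param out_of_scope_fraction,homonym_trap_rate Generator settings shared
#'   by pool and test set.
#' @param epochs Tagger training epochs.
#' @param correct Apply the corpus-correction workflow (remove
#'   generator-flagged false positives) before training.
#' @param adapter Optional [tagger_adapter()]; defaults to the built-in
#'   averaged perceptron.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_pool = 4000L, n_test = 400L,
                            train_notes = 3200L,
                            out_of_scope_fraction = 0.15,
                            homonym_trap_rate = 0.05, epochs = 5L,
                            correct = FALSE, adapter = NULL) {
  structure(list(seed = as.integer(seed), n_pool = as.integer(n_pool),
                 n_test = as.integer(n_test),
                 train_notes = as.integer(train_notes),
                 out_of_scope_fraction = out_of_scope_fraction,
                 homonym_trap_rate = homonym_trap_rate,
                 epochs = as.integer(epochs), correct = isTRUE(correct),
                 adapter = adapter),
            class = "pipeline_config")
}

# Stage logging to stderr with per-stage counters.
pipe_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full de-identification pipeline
#'
#' Executes synth -> rules -> pseudo-label -> (optional corrections) ->
#' train -> predict -> evaluate, and returns both a rule-engine report and
#' a tagger report on the same held-out gold annotations -- the central
#' comparison between the weak labeler and the model it trains.
#'
#' @param config A [pipeline_config()].
#' @param ruleset A compiled rule set; the shipped default when omitted.
#' @param verbose Log per-stage counters to stderr.
#' @return List with `rule_report` and `tagger_report` (both
#'   `eval_report`s), the trained `model`, the training `corpus`, the test
#'   notes and the config.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         ruleset = compile_ruleset(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  adapter <- if (is.null(config$adapter)) reference_adapter() else
    config$adapter
  pool_cfg <- synth_config(
    seed = config$seed, n_notes = config$n_pool, phi_note_fraction = 1,
    out_of_scope_fraction = config$out_of_scope_fraction,
    homonym_trap_rate = config$homonym_trap_rate)
  test_cfg <- synth_config(
    seed = config$seed + 7919L, n_notes = config$n_test,
    phi_note_fraction = 1,
    out_of_scope_fraction = config$out_of_scope_fraction,
    homonym_trap_rate = config$homonym_trap_rate)
  pool <- generate_corpus(pool_cfg)
  test <- generate_corpus(test_cfg)
  pipe_log(verbose, "synth: %d pool notes, %d test notes (seed %d)",
           length(pool), length(test), config$seed)
  prepared <- prepare_pool(pool, ruleset)
  n_matches <- sum(vapply(prepared$matches, nrow, integer(1)))
  pipe_log(verbose, "rules: %d matches across the pool", n_matches)
  corpus <- build_corpus(pool, ruleset, tier = "large1",
                         n_notes = config$train_notes,
                         seed = config$seed + 1L, prepared = prepared)
  pipe_log(verbose, "pseudo-label: %d notes, %d PHI words",
           length(corpus$notes), sum(corpus$phi_word_counts))
  if (config$correct) {
    corrections <- derive_corrections(corpus)
    corpus <- apply_corrections(corpus, corrections, tier = "large2")
    pipe_log(verbose, "correct: removed %d false positives, %d notes remain",
             nrow(corrections$removals), length(corpus$notes))
  }
  model <- adapter$train(corpus, config$epochs, config$seed + 2L)
  pipe_log(verbose, "train: done (%d epochs)", config$epochs)
  gold <- gold_tag_notes(test)
  rule_pred <- rule_tag_notes(test, ruleset)
  tagger_pred <- lapply(test, function(n) {
    adapter$predict(model, tokenize_note(n))
  })
  names(tagger_pred) <- vapply(test, function(n) n$note_id, character(1))
  rule_report <- evaluate_corpus(gold, rule_pred)
  tagger_report <- evaluate_corpus(gold, tagger_pred)
  pipe_log(verbose,
           "evaluate: rule total P/R = %.3f/%.3f; tagger total P/R = %.3f/%.3f",
           rule_report$precision[rule_report$category == "Total"],
           rule_report$recall[rule_report$category == "Total"],
           tagger_report$precision[tagger_report$category == "Total"],
           tagger_report$recall[tagger_report$category == "Total"])
  list(rule_report = rule_report, tagger_report = tagger_report,
       model = model, corpus = corpus, test_notes = test, config = config)
}

# Shared benchmark setup: generate pool + test under the experiment
# conditions, prepare rule matches and features once.
benchmark_setup <- function(seed, n_pool, n_test, out_of_scope_fraction,
                            homonym_trap_rate, ruleset) {
  pool <- generate_corpus(synth_config(
    seed = seed, n_notes = n_pool, phi_note_fraction = 1,
    out_of_scope_fraction = out_of_scope_fraction,
    homonym_trap_rate = homonym_trap_rate))
  test <- generate_corpus(synth_config(
    seed = seed + 7919L, n_notes = n_test, phi_note_fraction = 1,
    out_of_scope_fraction = out_of_scope_fraction,
    homonym_trap_rate = homonym_trap_rate))
  prepared <- prepare_pool(pool, ruleset)
  list(pool = pool, test = test, prepared = prepared,
       pool_feats = lapply(prepared$tokens, featurize_tokens),
       test_tokens = lapply(test, tokenize_note),
       gold = gold_tag_notes(test),
       rule_pred = rule_tag_notes(test, ruleset))
}

predict_test_set <- function(model, setup) {
  test_feats <- lapply(setup$test_tokens, featurize_tokens)
  pred <- lapply(seq_along(setup$test_tokens), function(i) {
    predict_tags(model, setup$test_tokens[[i]], features = test_feats[[i]])
  })
  names(pred) <- names(setup$gold)
  pred
}

total_row <- function(report) {
  as.data.frame(report)[report$category == "Total",
                        c("precision", "recall", "f1")]
}

#' Data-size tier experiment
#'
#' Trains the reference tagger on nested pseudo-labeled corpora of
#' increasing size (default 800/1,600/3,200 notes, one tenth of the source
#' study's tiers) over several seeds, and evaluates each model and the
#' rule engine on the same held-out gold annotations. With a fraction of
#' PHI rendered outside the rule set, this reproduces the two directional
#' findings: held-out micro-F1 grows with the number of pseudo-labeled
#' training notes, and the learned tagger's total recall exceeds the rule
#' engine's.
#'
#' @param seed Master seed.
#' @param tiers Training-corpus sizes (PHI-bearing notes).
#' @param seeds Per-run seeds to average over.
#' @param n_pool,n_test Pool and held-out sizes.
#' @param out_of_scope_fraction,homonym_trap_rate Generator settings.
#' @param epochs Training epochs.
#' @param ruleset Compiled rule set.
#' @return List with per-run `results`, per-tier mean `summary`, and the
#'   rule engine's `rule_total` on the same test set.
#' @export
run_tier_experiment <- function(seed = 1L, tiers = c(800L, 1600L, 3200L),
                                seeds = 1:5, n_pool = 4000L, n_test = 400L,
                                out_of_scope_fraction = 0.15,
                                homonym_trap_rate = 0.05, epochs = 5L,
                                ruleset = compile_ruleset()) {
  setup <- benchmark_setup(seed, n_pool, n_test, out_of_scope_fraction,
                           homonym_trap_rate, ruleset)
  rows <- list()
  for (s in seeds) {
    for (n in tiers) {
      run_seed <- seed * 1000L + s
      corpus <- build_corpus(setup$pool, ruleset, tier = as.character(n),
                             n_notes = n, seed = run_seed,
                             prepared = setup$prepared)
      feats <- setup$pool_feats[vapply(corpus$notes, `[[`, integer(1),
                                       "pool_index")]
      model <- train_tagger(corpus, epochs = epochs, seed = run_seed,
                            features = feats)
      rep <- evaluate_corpus(setup$gold, predict_test_set(model, setup))
      tot <- total_row(rep)
      rows[[length(rows) + 1L]] <- data.frame(
        tier = n, seed = s, precision = tot$precision, recall = tot$recall,
        f1 = tot$f1)
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(precision, recall, f1) ~ tier, results,
                              mean)
  rule_rep <- evaluate_corpus(setup$gold, setup$rule_pred)
  list(results = results, summary = summary[order(summary$tier), ],
       rule_total = total_row(rule_rep), rule_report = rule_rep)
}

#' Correction-benefit experiment
#'
#' Builds a pseudo-labeled corpus under a raised homonym-trap rate, flags
#' the generator-known false positives, and trains the tagger on the
#' uncorrected and the corrected corpus (the latter also gains a few
#' gold-annotated other-department notes) with the same seeds. Removing
#' falsely detected words from the training data raises the model's
#' held-out precision.
#'
#' @inheritParams run_tier_experiment
#' @param n_notes Training-corpus size.
#' @param n_additions Gold other-department notes appended by the
#'   correction (scaled from the source workflow).
#' @return List with per-seed `results` and the mean precision under both
#'   conditions.
#' @export
run_correction_experiment <- function(seed = 1L, n_notes = 1600L,
                                      seeds = 1:5, n_pool = 2400L,
                                      n_test = 400L,
                                      out_of_scope_fraction = 0.15,
                                      homonym_trap_rate = 0.2,
                                      epochs = 5L, n_additions = 10L,
                                      ruleset = compile_ruleset()) {
  setup <- benchmark_setup(seed, n_pool, n_test, out_of_scope_fraction,
                           homonym_trap_rate, ruleset)
  additions <- generate_corpus(synth_config(
    seed = seed + 104729L, n_notes = n_additions, phi_note_fraction = 1,
    out_of_scope_fraction = out_of_scope_fraction,
    homonym_trap_rate = homonym_trap_rate, department_mix = 1))
  additions <- Filter(function(n) !is.null(n$phi) && nrow(n$phi) > 0,
                      additions)
  rows <- list()
  for (s in seeds) {
    run_seed <- seed * 1000L + s
    corpus <- build_corpus(setup$pool, ruleset, tier = "large1",
                           n_notes = n_notes, seed = run_seed,
                           prepared = setup$prepared)
    feats <- setup$pool_feats[vapply(corpus$notes, `[[`, integer(1),
                                     "pool_index")]
    corrected <- apply_corrections(corpus,
                                   derive_corrections(corpus, additions),
                                   tier = "large2")
    m_unc <- train_tagger(corpus, epochs = epochs, seed = run_seed,
                          features = feats)
    m_cor <- train_tagger(corrected, epochs = epochs, seed = run_seed)
    t_unc <- total_row(evaluate_corpus(setup$gold,
                                       predict_test_set(m_unc, setup)))
    t_cor <- total_row(evaluate_corpus(setup$gold,
                                       predict_test_set(m_cor, setup)))
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s,
      precision_uncorrected = t_unc$precision,
      precision_corrected = t_cor$precision,
      recall_uncorrected = t_unc$recall,
      recall_corrected = t_cor$recall)
  }
  results <- do.call(rbind, rows)
  list(results = results,
       mean_precision_uncorrected = mean(results$precision_uncorrected),
       mean_precision_corrected = mean(results$precision_corrected))
}
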