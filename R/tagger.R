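# Identifier words (lowercased token surfaces) that anchor PHI in the rule
# set; their presence in the +-1 context is a strong tagging cue.
identifier_tokens <- function() {
  c("환자이름", "환자", "이름",
    "판독의", "의료진", "교수",
    "확인함", "환자번호", "내선",
    "전화번호", "tel", "t", "by", "from", "confirmed",
    "세")
}

# Token shape: digits -> 9, Hangul -> H, Latin -> a, other kept; capped at
# 6 classes with a "+" marker for longer tokens.
token_shape <- function(surface) {
  sh <- stringi::stri_replace_all_regex(surface, "[0-9]", "9")
  sh <- stringi::stri_replace_all_regex(sh, "[가-힣ᄀ-ᇿ㄰-㆏]", "H")
  sh <- stringi::stri_replace_all_regex(sh, "[A-Za-z]", "a")
  long <- stringi::stri_length(sh) > 6
  sh[long] <- paste0(stringi::stri_sub(sh[long], 1, 6), "+")
  sh
}

# Per-token feature sets for a whole note, vectorized. Returns a list of
# character vectors, one per token.
featurize_tokens <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0) return(list())
  lo <- stringi::stri_trans_tolower(tokens$surface)
  sh <- token_shape(tokens$surface)
  first <- stringi::stri_sub(tokens$surface, 1, 1)
  cls <- as.character(char_classes(paste(first, collapse = "")))
  pad <- function(v, off) {
    if (off < 0) c(rep("<BOS>", -off), v[seq_len(max(n + off, 0))])
    else c(v[seq_len(max(n - off, 0)) + off], rep("<EOS>", min(off, n)))
  }
  cols <- list(
    paste0("w=", lo), paste0("sh=", sh), paste0("cl=", cls),
    paste0("w-1=", pad(lo, -1)), paste0("w+1=", pad(lo, 1)),
    paste0("w-2=", pad(lo, -2)), paste0("w+2=", pad(lo, 2)),
    paste0("sh-1=", pad(sh, -1)), paste0("sh+1=", pad(sh, 1)),
    paste0("sh-2=", pad(sh, -2)), paste0("sh+2=", pad(sh, 2)))
  m <- matrix(unlist(cols, use.names = FALSE), nrow = n)
  idw <- identifier_tokens()
  id0 <- lo %in% idw
  idm1 <- c(FALSE, id0[-n])
  idp1 <- c(id0[-1], FALSE)
  lapply(seq_len(n), function(i) {
    f <- m[i, ]
    if (id0[i]) f <- c(f, "id@0")
    if (idm1[i]) f <- c(f, "id@-1")
    if (idp1[i]) f <- c(f, "id@+1")
    if (i == 1L) f <- c(f, "<bos>")
    if (i == n) f <- c(f, "<eos>")
    f
  })
}

#' Extract tagging features at one token position
#'
#' Deterministic, position-local feature identifiers used by the reference
#' tagger: the token surface (lowercased), its shape (digits to `9`,
#' Hangul to `H`, Latin to `a`), its script class, surfaces and shapes of
#' the tokens at offsets -2..+2, flags marking identifier words (환자이름,
#' 판독의, Tel., 전화번호, by, confirmed, ...) in the +-1 context, and
#' sentence-boundary flags.
#'
#' @param tokens Token data frame from [tokenize_note()].
#' @param position 1-based token position.
#' @return Character vector of feature identifiers.
#' @export
extract_features <- function(tokens, position) {
  if (position < 1 || position > nrow(tokens)) {
    stop("extract_features: position ", position, " out of range 1..",
         nrow(tokens), call. = FALSE)
  }
  featurize_tokens(tokens)[[position]]
}

# Flatten per-token feature id lists into the (ids, offs) layout the C++
# backend consumes. Unknown features (NA ids) are dropped.
pack_features <- function(feat_ids) {
  lens <- vapply(feat_ids, length, integer(1))
  flat <- unlist(feat_ids, use.names = FALSE)
  if (is.null(flat)) flat <- integer(0)
  known <- !is.na(flat)
  tok <- rep.int(seq_along(lens), lens)[known]
  flat <- flat[known]
  offs <- c(0L, cumsum(tabulate(tok, nbins = length(lens))))
  list(ids = as.integer(flat[order(tok)]), offs = as.integer(offs))
}

#' Train the reference sequence tagger
#'
#' A feature-based averaged perceptron with greedy left-to-right decoding
#' and a previous-tag transition feature, standing in for a fine-tuned
#' transformer tagger: it consumes and produces exactly the corpus and tag
#' types an external pretrained model adapter would (see
#' [tagger_adapter()]), which is what makes the data-size and correction
#' behavior of pseudo-label training observable at desk scale.
#'
#' @param corpus A `tagged_corpus` from [build_corpus()].
#' @param epochs Training epochs (passes over the shuffled corpus).
#' @param seed Integer seed for the shuffle order; training is
#'   deterministic given the seed.
#' @param features Optional precomputed feature lists (one per corpus
#'   note, as produced by internal featurization) to avoid recomputation
#'   across repeated trainings.
#' @return An object of class `deid_tagger` holding the averaged feature
#'   and transition weights, the feature dictionary, the 13-tag BIO
#'   inventory and training metadata.
#' @export
train_tagger <- function(corpus, epochs = 5L, seed = 1L, features = NULL) {
  if (!inherits(corpus, "tagged_corpus") || length(corpus$notes) == 0) {
    stop("train_tagger: empty corpus", call. = FALSE)
  }
  if (is.null(features)) {
    features <- lapply(corpus$notes, function(e) featurize_tokens(e$tokens))
  }
  tagset <- deid_tagset()
  flat <- unlist(features, use.names = FALSE)
  dict <- unique(flat)
  ids_flat <- match(flat, dict)
  # rebuild the nested ids without repeated match() calls
  note_lens <- vapply(features, function(f) length(unlist(f, use.names = FALSE)),
                      integer(1))
  note_end <- cumsum(note_lens)
  note_start <- note_end - note_lens + 1L
  cpp_notes <- vector("list", length(features))
  for (i in seq_along(features)) {
    lens <- vapply(features[[i]], length, integer(1))
    offs <- c(0L, cumsum(lens))
    ids <- ids_flat[seq.int(note_start[i], length.out = note_lens[i])]
    tags <- match(corpus$notes[[i]]$tokens$tag, tagset)
    if (anyNA(tags)) stop("train_tagger: tag outside the BIO inventory",
                          call. = FALSE)
    cpp_notes[[i]] <- list(ids = as.integer(ids), offs = as.integer(offs),
                           tags = as.integer(tags))
  }
  ord <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(epochs),
                          function(e) sample(length(cpp_notes))))
  })
  fit <- ap_train_cpp(cpp_notes, length(dict), length(tagset), ord)
  structure(list(weights = fit$W, trans = fit$T, features = dict,
                 tags = tagset,
                 meta = list(tier = corpus$tier, epochs = as.integer(epochs),
                             seed = as.integer(seed),
                             n_notes = length(corpus$notes))),
            class = "deid_tagger")
}

#' @export
print.deid_tagger <- function(x, ...) {
  cat(sprintf(
    "<deid_tagger: %d features x %d tags; trained on %d notes ('%s'), %d epochs, seed %d>\n",
    length(x$features), length(x$tags), x$meta$n_notes, x$meta$tier,
    x$meta$epochs, x$meta$seed))
  invisible(x)
}

#' Repair a BIO tag sequence
#'
#' Any `I-X` not preceded by `B-X` or `I-X` of the same category is
#' rewritten to `B-X`. Idempotent; the output is always BIO-valid.
#'
#' @param tags Character vector of BIO tags.
#' @return Repaired tag vector.
#' @export
enforce_bio_validity <- function(tags) {
  if (!length(tags)) return(tags)
  for (i in seq_along(tags)) {
    if (startsWith(tags[i], "I-")) {
      ok <- i > 1 && tags[i - 1] != "O" &&
        substring(tags[i - 1], 3) == substring(tags[i], 3)
      if (!ok) tags[i] <- paste0("B-", substring(tags[i], 3))
    }
  }
  tags
}

#' Predict BIO tags for tokens
#'
#' Greedy left-to-right decoding with the trained averaged weights,
#' followed by [enforce_bio_validity()]. Deterministic.
#'
#' @param model A `deid_tagger` from [train_tagger()].
#' @param tokens Token data frame from [tokenize_note()] (or a
#'   [clinical_note()], which is tokenized first).
#' @param features Optional precomputed feature list for `tokens`.
#' @return The token data frame with a BIO-valid `tag` column.
#' @export
predict_tags <- function(model, tokens, features = NULL) {
  if (!inherits(model, "deid_tagger")) {
    stop("predict_tags: model is not a trained tagger", call. = FALSE)
  }
  if (inherits(tokens, "clinical_note")) tokens <- tokenize_note(tokens)
  if (nrow(tokens) == 0) {
    tokens$tag <- character(0)
    return(tokens)
  }
  feats <- if (is.null(features)) featurize_tokens(tokens) else features
  ids <- lapply(feats, function(f) match(f, model$features))
  packed <- pack_features(ids)
  pred <- ap_predict_cpp(packed$ids, packed$offs, model$weights, model$trans)
  tokens$tag <- enforce_bio_validity(model$tags[pred])
  tokens
}

#' Serialize / restore a tagger model as JSON
#'
#' The model is a flat weight table with metadata; zero-weight feature
#' rows are pruned on save.
#'
#' @param model A `deid_tagger`.
#' @param path Output (or input) path.
#' @return `save_tagger` returns the path invisibly; `load_tagger` the
#'   restored model.
#' @export
save_tagger <- function(model, path) {
  nonzero <- which(rowSums(abs(model$weights)) > 0)
  obj <- list(features = model$features[nonzero],
              weights = model$weights[nonzero, , drop = FALSE],
              trans = model$trans, tags = model$tags, meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.matrix(obj$weights),
                 trans = as.matrix(obj$trans),
                 features = obj$features, tags = obj$tags,
                 meta = as.list(obj$meta)),
            class = "deid_tagger")
}

#' Adapter contract for external pretrained taggers
#'
#' External sequence taggers (for example fine-tuned Korean BERT NER
#' models) can stand in for the reference tagger by satisfying this
#' contract: a `train(corpus, epochs, seed)` function consuming a
#' `tagged_corpus` and returning an opaque model, and a
#' `predict(model, tokens)` function returning the token frame with a
#' BIO-valid `tag` column. [run_pipeline()] accepts such an adapter in
#' place of the built-in perceptron.
#'
#' @param train Training function `(corpus, epochs, seed) -> model`.
#' @param predict Prediction function `(model, tokens) -> tokens + tag`.
#' @return An object of class `tagger_adapter`.
#' @export
tagger_adapter <- function(train, predict) {
  stopifnot(is.function(train), is.function(predict))
  structure(list(train = train, predict = predict),
            class = "tagger_adapter")
}

# The built-in reference tagger expressed as an adapter.
reference_adapter <- function() {
  tagger_adapter(
    train = function(corpus, epochs, seed) train_tagger(corpus, epochs, seed),
    predict = function(model, tokens) predict_tags(model, tokens))
}
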