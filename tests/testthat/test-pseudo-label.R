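test_that("tokenizer splits at whitespace and script boundaries", {
  tk <- tokenize_note(note_of("2019-02-04 촬영"))
  expect_identical(tk$surface, c("2019", "-", "02", "-", "04", "촬영"))
  expect_identical(tk$start, c(0L, 4L, 5L, 7L, 8L, 11L))
  expect_identical(tk$end, c(4L, 5L, 7L, 8L, 10L, 13L))
  expect_identical(nrow(tokenize_note("")), 0L)
  # mixed-script eojeol splits into script runs
  tk2 <- tokenize_note(note_of("45세 남자, Tel. 1234"))
  expect_identical(tk2$surface,
                   c("45", "세", "남자", ",", "Tel", ".", "1234"))
})

test_that("tokens reconstruct the note exactly", {
  notes <- generate_corpus(synth_config(seed = 5, n_notes = 300,
                                        phi_note_fraction = 0.4,
                                        out_of_scope_fraction = 0.2,
                                        homonym_trap_rate = 0.2))
  for (n in notes) {
    tk <- tokenize_note(n)
    expect_identical(stringi::stri_sub(n$text, tk$start + 1L, tk$end),
                     tk$surface)
    # inter-token gaps are pure whitespace
    gaps <- stringi::stri_sub(n$text, c(1L, tk$end + 1L),
                              c(tk$start, stringi::stri_length(n$text)))
    expect_true(all(grepl("^[[:space:]]*$", gaps)))
  }
})

test_that("BIO projection tags covered tokens and maps subcategories to PER", {
  n <- note_of("환자이름: 홍길동")
  tk <- tokenize_note(n)
  m <- apply_rules(n, default_ruleset)
  lt <- project_to_bio(tk, m)
  expect_identical(lt$tag, c("O", "O", "B-PER"))
  expect_identical(project_to_bio(tk, empty_matches())$tag, rep("O", 3))
  # multi-token span: B then I
  n2 <- note_of("2020년 3월 7일 촬영")
  lt2 <- project_to_bio(tokenize_note(n2), apply_rules(n2, default_ruleset))
  expect_identical(lt2$tag,
                   c("B-DAT", "I-DAT", "I-DAT", "I-DAT", "I-DAT", "I-DAT", "O"))
  # overlapping matches violate the contract
  bad <- data.frame(start = c(0L, 2L), end = c(5L, 8L),
                    category = c("DAT", "PER"))
  expect_error(project_to_bio(tokenize_note(note_of("0123456789")), bad),
               "overlap")
})

test_that("BIO runs recover the token-aligned hull of each match", {
  notes <- generate_corpus(synth_config(seed = 13, n_notes = 150,
                                        phi_note_fraction = 1))
  for (n in notes) {
    tk <- tokenize_note(n)
    m <- apply_rules(n, default_ruleset)
    lt <- project_to_bio(tk, m)
    expect_true(bio_valid(lt$tag))
    # recover spans from B/I runs
    runs <- list()
    for (i in seq_len(nrow(lt))) {
      if (startsWith(lt$tag[i], "B-")) {
        runs[[length(runs) + 1L]] <- c(i, i)
      } else if (startsWith(lt$tag[i], "I-")) {
        runs[[length(runs)]][2] <- i
      }
    }
    got <- lapply(runs, function(r) c(lt$start[r[1]], lt$end[r[2]]))
    hull <- lapply(seq_len(nrow(m)), function(j) {
      idx <- which(tk$start < m$end[j] & tk$end > m$start[j])
      c(tk$start[idx[1]], tk$end[idx[length(idx)]])
    })
    expect_identical(got, hull, info = n$note_id)
  }
})

test_that("build_corpus samples PHI-bearing notes reproducibly", {
  notes <- generate_corpus(synth_config(seed = 7, n_notes = 100,
                                        phi_note_fraction = 0.4))
  has_phi <- sum(vapply(notes, function(n) {
    nrow(apply_rules(n, default_ruleset)) > 0
  }, logical(1)))
  corpus <- build_corpus(notes, default_ruleset, tier = "small",
                         n_notes = 10, seed = 7)
  expect_s3_class(corpus, "tagged_corpus")
  expect_length(corpus$notes, 10L)
  expect_true(all(vapply(corpus$notes, function(e) any(e$tokens$tag != "O"),
                         logical(1))))
  # determinism
  corpus2 <- build_corpus(notes, default_ruleset, tier = "small",
                          n_notes = 10, seed = 7)
  expect_identical(corpus$phi_word_counts, corpus2$phi_word_counts)
  expect_identical(lapply(corpus$notes, `[[`, "tokens"),
                   lapply(corpus2$notes, `[[`, "tokens"))
  # requesting more notes than available is an error with counts
  expect_error(build_corpus(notes, default_ruleset, n_notes = has_phi + 1,
                            seed = 1),
               as.character(has_phi))
})

test_that("phi_word_counts equals the number of B runs and of spans", {
  notes <- generate_corpus(synth_config(seed = 15, n_notes = 200,
                                        phi_note_fraction = 1))
  corpus <- build_corpus(notes, default_ruleset, n_notes = 150, seed = 2)
  n_b <- sum(vapply(corpus$notes, function(e) {
    sum(startsWith(e$tokens$tag, "B-"))
  }, integer(1)))
  n_spans <- sum(vapply(corpus$notes, function(e) nrow(e$phi), integer(1)))
  expect_identical(sum(corpus$phi_word_counts), n_b)
  expect_identical(n_b, n_spans)
})

test_that("corrections revert tokens, drop emptied notes, append additions", {
  n1 <- note_of("orientation을 고려해 볼 때 2019-02-04 촬영", id = "c1")
  n2 <- note_of("측정치의 중앙값은 정상", id = "c2")
  corpus <- build_corpus(list(n1, n2), default_ruleset, n_notes = 2, seed = 1)
  # identity correction only renames the tier
  same <- apply_corrections(corpus, correction_list(), tier = "large2")
  expect_identical(lapply(same$notes, `[[`, "tokens"),
                   lapply(corpus$notes, `[[`, "tokens"))
  expect_identical(same$tier, "large2")
  # remove the 고려 false positive: note retained, its tokens become O
  ids <- vapply(corpus$notes, function(e) e$note$note_id, character(1))
  e1 <- corpus$notes[[match("c1", ids)]]
  fp <- e1$phi[e1$phi$category == "ORG", ]
  fixed <- apply_corrections(corpus, correction_list(
    removals = data.frame(note_id = "c1", start = fp$start, end = fp$end)))
  ids2 <- vapply(fixed$notes, function(e) e$note$note_id, character(1))
  t1 <- fixed$notes[[match("c1", ids2)]]$tokens
  expect_false(any(grepl("ORG", t1$tag)))
  expect_true(any(t1$tag == "B-DAT"))
  # removing the only annotation of c2 drops the note
  e2 <- corpus$notes[[match("c2", ids)]]
  gone <- apply_corrections(fixed, correction_list(
    removals = data.frame(note_id = "c2", start = e2$phi$start,
                          end = e2$phi$end)))
  expect_false("c2" %in% vapply(gone$notes, function(e) e$note$note_id, ""))
  # dangling removal is an error
  expect_error(apply_corrections(corpus, correction_list(
    removals = data.frame(note_id = "c1", start = 999L, end = 1000L))),
    "removal")
  # additions with gold annotations are appended
  extra <- generate_corpus(synth_config(seed = 33, n_notes = 8,
                                        phi_note_fraction = 1,
                                        department_mix = 1))
  extra <- Filter(function(n) !is.null(n$phi) && nrow(n$phi) > 0, extra)
  grown <- apply_corrections(corpus, correction_list(additions = extra))
  expect_length(grown$notes, length(corpus$notes) + length(extra))
  deps <- vapply(grown$notes, function(e) e$note$department, character(1))
  expect_true("other" %in% deps)
})

test_that("correction lists round-trip through JSONL", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  extra <- generate_corpus(synth_config(seed = 35, n_notes = 5,
                                        phi_note_fraction = 1,
                                        department_mix = 1))
  extra <- Filter(function(n) !is.null(n$phi) && nrow(n$phi) > 0, extra)
  cl <- correction_list(
    removals = data.frame(note_id = c("a", "b"), start = c(3L, 0L),
                          end = c(7L, 2L)),
    additions = extra)
  write_corrections(cl, path)
  back <- read_corrections(path)
  expect_equal(back$removals$note_id, cl$removals$note_id)
  expect_equal(back$removals$start, cl$removals$start)
  expect_length(back$additions, length(extra))
  for (i in seq_along(extra)) {
    expect_identical(back$additions[[i]]$text, extra[[i]]$text)
    expect_equal(back$additions[[i]]$phi$start, extra[[i]]$phi$start)
  }
  writeLines('{"note_id":"x"}', path)
  expect_error(read_corrections(path), "line 1")
})

test_that("CoNLL serialization round-trips tokens and tags", {
  path <- withr::local_tempfile(fileext = ".conll")
  notes <- generate_corpus(synth_config(seed = 17, n_notes = 60,
                                        phi_note_fraction = 1))
  corpus <- build_corpus(notes, default_ruleset, n_notes = 40, seed = 3)
  write_conll(corpus, path)
  back <- read_conll(path)
  expect_length(back, 40L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$surface, corpus$notes[[i]]$tokens$surface)
    expect_identical(back[[i]]$tag, corpus$notes[[i]]$tokens$tag)
  }
  # token count equals non-blank line count
  lines <- readLines(path, encoding = "UTF-8")
  expect_identical(sum(nzchar(lines)),
                   sum(vapply(corpus$notes, function(e) nrow(e$tokens),
                              integer(1))))
})
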