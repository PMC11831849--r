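test_that("the default rule set has the documented structure", {
  rs <- default_ruleset
  expect_s3_class(rs, "phi_ruleset")
  expect_identical(nrow(rs$rules), 51L)
  fam <- ifelse(rs$rules$category == "PER",
                paste0("PER/", rs$rules$subcategory), rs$rules$category)
  expect_identical(sum(fam == "DAT"), 18L)
  expect_identical(sum(fam == "PER/staff"), 8L)
  expect_identical(sum(fam == "PER/patient"), 3L)
  expect_identical(sum(fam == "ORG"), 13L)
  expect_identical(sum(fam == "LOC"), 1L)
  expect_identical(sum(fam == "NUM"), 4L)
  expect_identical(sum(fam == "ETC"), 4L)
  # compilation is deterministic
  rs2 <- compile_ruleset()
  expect_identical(rs$rules, rs2$rules)
})

test_that("compile_ruleset rejects malformed configurations", {
  cfg <- yaml::read_yaml(default_rules_path())
  bad <- cfg
  bad$rules[[1]]$pattern <- "([unclosed"
  expect_error(compile_ruleset(bad), bad$rules[[1]]$id)
  short <- cfg
  short$rules <- cfg$rules[-1]
  expect_error(compile_ruleset(short), "count mismatch")
  badgroup <- cfg
  badgroup$rules[[2]]$phi_group <- 9
  expect_error(compile_ruleset(badgroup), "phi_group")
})

test_that("date matcher covers the notation families and avoids ranges", {
  cases <- list(
    list("specific dates such as 2019-02-04", "2019-02-04"),
    list("2020년 3월 7일 촬영", "2020년 3월 7일"),
    list("외부 2019.02.04 CT와 비교", "2019.02.04"),
    list("f/u '19.2.4", "'19.2.4"),
    list("MRI on Feb 4, 2019", "Feb 4, 2019"),
    list("study done 02/04/2019", "02/04/2019"),
    list("2019-02-04 (월) 시행", "2019-02-04 (월)"),
    list("2019-02-04 13:45 촬영", "2019-02-04 13:45"))
  for (cs in cases) {
    m <- match_dates(note_of(cs[[1]]), default_ruleset)
    expect_identical(nrow(m), 1L, info = cs[[1]])
    expect_identical(m$surface, cs[[2]], info = cs[[1]])
    expect_identical(unique(m$category), "DAT")
  }
  # a short numeric range has no plausible 4-digit year
  expect_identical(nrow(match_dates(note_of("1.2-1.7 cm enhancing lesion"),
                                    default_ruleset)), 0L)
  expect_identical(nrow(match_dates(note_of("no date here"),
                                    default_ruleset)), 0L)
})

test_that("person matcher separates staff and patients and keeps identifiers", {
  m <- match_person(note_of("환자이름: 홍길동"), default_ruleset)
  expect_identical(nrow(m), 1L)
  expect_identical(m$surface, "홍길동")
  expect_identical(m$subcategory, "patient")
  # the documented over-trigger: both 상기 and the true name fire as staff
  m2 <- match_person(note_of("상기확인함 by 홍길동"), default_ruleset)
  expect_identical(m2$surface, c("상기", "홍길동"))
  expect_identical(unique(m2$subcategory), "staff")
  m3 <- match_person(note_of("final report /jmk/"), default_ruleset)
  expect_identical(m3$surface, "jmk")
  m4 <- match_person(note_of("confirmed by 김영수"), default_ruleset)
  expect_identical(m4$surface, "김영수")
  m5 <- match_person(note_of("판독의 이민준 판독함"), default_ruleset)
  expect_identical(m5$surface, "이민준")
})

test_that("org/loc matcher resolves aliases, suffixes and homonyms", {
  m <- match_org_loc(note_of("고려대병원 에서 전원"), default_ruleset)
  expect_identical(nrow(m), 1L)
  expect_identical(m$surface, "고려대병원")
  expect_identical(m$category, "ORG")
  # documented false positives, reproduced deliberately
  fp <- match_org_loc(note_of("orientation을 고려해 볼 때"), default_ruleset)
  expect_identical(fp$surface, "고려")
  expect_identical(fp$category, "ORG")
  fp2 <- match_org_loc(note_of("측정치의 중앙값은 정상"), default_ruleset)
  expect_identical(fp2$surface, "중앙")
  cmc <- match_org_loc(note_of("1st CMC joint"), default_ruleset)
  expect_identical(cmc$surface, "CMC")
  expect_identical(cmc$category, "ORG")
  # city + hospital resolves to ORG, standalone city to LOC
  city <- match_org_loc(note_of("분당 행복병원 외래"), default_ruleset)
  expect_identical(city$surface, "분당 행복병원")
  expect_identical(city$category, "ORG")
  loc <- match_org_loc(note_of("대구 local에서 시행"), default_ruleset)
  expect_identical(loc$surface, "대구")
  expect_identical(loc$category, "LOC")
  # 서울 inside 서울대병원 is the hospital, not the region
  seoul <- match_org_loc(note_of("서울대병원 외래 기록"), default_ruleset)
  expect_identical(seoul$category, "ORG")
  expect_identical(seoul$surface, "서울대병원")
})

test_that("num/etc matcher requires identifier anchors for digits", {
  m <- match_num_etc(note_of("Tel. 1234"), default_ruleset)
  expect_identical(m$surface, "1234")
  expect_identical(m$category, "NUM")
  # a bare 4-digit number is indistinguishable from a year: no match
  expect_identical(nrow(match_num_etc(note_of("measured 2019 units"),
                                      default_ruleset)), 0L)
  m2 <- match_num_etc(note_of("환자번호: 34567890"), default_ruleset)
  expect_identical(m2$surface, "34567890")
  etc <- match_num_etc(note_of("45세 남자"), default_ruleset)
  expect_identical(etc$surface, c("45세", "남자"))
  expect_identical(unique(etc$category), "ETC")
})

test_that("a configured extension vocabulary matches unanchored digits", {
  cfg <- yaml::read_yaml(default_rules_path())
  cfg$vocab$extension <- c("0424", "7788")
  rs <- compile_ruleset(cfg)
  m <- match_num_etc(note_of("연결 0424 바람"), rs)
  expect_identical(m$surface, "0424")
  expect_identical(m$category, "NUM")
  # absent from the vocabulary: still no match without an identifier
  expect_identical(nrow(match_num_etc(note_of("연결 0425 바람"), rs)), 0L)
})

test_that("overlap resolution applies the documented total order", {
  expect_identical(nrow(resolve_overlaps(empty_matches())), 0L)
  mk <- function(start, end, category, priority = 1L, id = "r") {
    data.frame(rule_id = id, category = category,
               subcategory = NA_character_, start = start, end = end,
               priority = priority, stringsAsFactors = FALSE)
  }
  # longer span wins
  r <- resolve_overlaps(rbind(mk(0L, 10L, "ORG"), mk(0L, 5L, "LOC")))
  expect_identical(nrow(r), 1L)
  expect_identical(r$category, "ORG")
  expect_identical(r$end, 10L)
  # equal spans: ORG beats LOC
  r2 <- resolve_overlaps(rbind(mk(3L, 7L, "LOC"), mk(3L, 7L, "ORG")))
  expect_identical(r2$category, "ORG")
  # then DAT > PER > NUM > ETC
  r3 <- resolve_overlaps(rbind(mk(3L, 7L, "ETC"), mk(3L, 7L, "NUM"),
                               mk(3L, 7L, "PER"), mk(3L, 7L, "DAT")))
  expect_identical(r3$category, "DAT")
  # non-overlapping spans all survive, sorted by start
  r4 <- resolve_overlaps(rbind(mk(5L, 8L, "DAT"), mk(0L, 5L, "PER")))
  expect_identical(r4$start, c(0L, 5L))
  # the order is total: shuffling the input changes nothing
  cand <- rbind(mk(0L, 4L, "DAT", 2L, "a"), mk(2L, 6L, "PER", 1L, "b"),
                mk(6L, 10L, "ORG", 1L, "c"), mk(6L, 10L, "LOC", 1L, "d"))
  set.seed(1)
  for (i in 1:10) {
    expect_identical(resolve_overlaps(cand[sample(nrow(cand)), ]),
                     resolve_overlaps(cand))
  }
})

test_that("masking replaces spans with category placeholders", {
  n <- note_of("2019-02-04 촬영")
  m <- apply_rules(n, default_ruleset)
  expect_identical(mask_text(n, m), "[DAT] 촬영")
  expect_identical(mask_text(n, empty_matches()), n$text)
  # identifier words survive masking
  n2 <- note_of("환자이름: 홍길동")
  expect_identical(mask_text(n2, apply_rules(n2, default_ruleset)),
                   "환자이름: [PER]")
  # overlapping input spans violate the contract
  bad <- data.frame(rule_id = c("a", "b"), category = c("DAT", "PER"),
                    subcategory = NA, start = c(0L, 3L), end = c(5L, 8L),
                    priority = 1L)
  expect_error(mask_text(note_of("0123456789"), bad), "overlap")
})

test_that("masked text is a fixed point of the rule engine", {
  notes <- generate_corpus(synth_config(seed = 21, n_notes = 120,
                                        phi_note_fraction = 0.6,
                                        homonym_trap_rate = 0.3))
  for (n in notes) {
    masked <- mask_text(n, apply_rules(n, default_ruleset))
    n2 <- note_of(masked, id = n$note_id)
    m2 <- apply_rules(n2, default_ruleset)
    # nothing in the masked text matches any rule again
    expect_identical(nrow(m2), 0L, info = n$note_id)
  }
})

test_that("apply_rules equals the independent run-all-rules oracle", {
  notes <- generate_corpus(synth_config(seed = 11, n_notes = 200,
                                        phi_note_fraction = 0.5,
                                        out_of_scope_fraction = 0.15,
                                        homonym_trap_rate = 0.2))
  texts <- vapply(notes, function(n) n$text, character(1))
  want <- oracle_apply_rules(texts, default_ruleset)
  for (i in seq_along(notes)) {
    got <- apply_rules(notes[[i]], default_ruleset)
    expect_identical(got[c("start", "end", "category")],
                     want[[i]][c("start", "end", "category")],
                     info = notes[[i]]$note_id)
  }
})

test_that("identical text always yields identical matches", {
  n <- note_of(paste("환자이름: 김길동 2019-02-04 촬영 고려대병원 전원",
                     "Tel. 1234 45세 남자"))
  m1 <- apply_rules(n, default_ruleset)
  m2 <- apply_rules(n, compile_ruleset())
  expect_identical(m1, m2)
})
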