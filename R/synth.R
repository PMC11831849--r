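# ---- Fictitious surface pools ------------------------------------------
# All names and institutions are synthetic; no real PHI appears anywhere.

synth_names <- function() {
  surnames <- c("김", "이", "박", "최", "정", "강", "조", "윤", "장", "임")
  given <- c("길동", "영수", "민준", "서연", "지훈", "수빈", "예진", "도현",
             "하은", "지우", "민서", "준호", "태양", "은지", "소연", "현우",
             "재원", "유진", "성민", "다은", "경미", "상철", "미래", "보람")
  as.vector(outer(surnames, given, paste0))
}

synth_initials <- function() c("jmk", "skd", "hjp", "lsy", "kth", "pjh")

synth_hospitals <- function() {
  vocab <- c("서울대병원", "연건", "본원", "고려대학교병원", "고려대병원",
             "고대병원", "고대안암", "안암", "김포우리병원", "강동성심병원",
             "CMC")
  prefixes <- c("행복", "미소", "튼튼", "한빛", "바른", "온누리", "푸른",
                "새봄", "가온", "누리")
  suffixes <- c("병원", "의원", "내과", "정형외과", "피부과", "의료원")
  english <- c("Hangang Medical Center", "Dongbu Hospital", "Seohae Clinic",
               "Namsan Hospital")
  city <- paste(rep(c("분당", "강동", "김포"), each = 3),
                paste0(c("행복", "한빛", "미소"), "병원"))
  c(vocab, as.vector(outer(prefixes, suffixes, paste0)), english, city)
}

synth_hospitals_oos <- function() {
  c("한마음메디칼", "드림헬스케어", "성심재활센터", "Dongbu Medical",
    "Haneul Center")
}

synth_regions <- function() c("서울", "대구", "부산", "인천", "광주", "대전",
                              "수원", "성남")
synth_regions_oos <- function() c("제주", "울산", "춘천", "포항")

# Radiology-style filler; every token is rule-inert by construction.
synth_filler <- function(department = "radiology") {
  radiology <- c(
    "No evidence of acute hemorrhage.",
    "Both lungs are clear.",
    "No significant interval change.",
    "Unremarkable study.",
    "Mild degenerative change is noted.",
    "No focal lesion is seen.",
    "Impression: benign finding.",
    "Recommend short term follow up.",
    "No abnormal enhancement.",
    "특이 소견 없음.",
    "이전 검사와 비교하여 변화 없음.",
    "간 실질 에코 정상.",
    "양측 신장 크기 정상.",
    "경미한 퇴행성 변화 관찰됨.",
    "추적 검사 권고함.",
    "작은 낭종 (1.2 cm) 관찰됨.",
    "판독 소견과 임상 소견 일치함.")
  other <- c(
    "Nerve conduction study shows normal latency.",
    "근전도 검사상 정상 소견임.",
    "뇌파 검사상 특이 소견 없음.",
    "상부 위장관 검사 시행함.",
    "Endoscopic finding: chronic gastritis.",
    "운동 기능 평가 결과 정상 범위임.")
  if (department == "other") c(other, radiology[10:15]) else radiology
}

# Non-PHI text the rule engine is known to false-positive on.
synth_traps <- function() {
  c("mass의 orientation을 고려해 볼 때 benign으로 생각됨.",
    "측정치의 중앙값은 정상 범위임.",
    "1st CMC joint에 경미한 퇴행성 변화.",
    "상기확인함.")
}

month_abbrev <- function() c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                             "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# ---- Per-category renderers --------------------------------------------
# Each renderer returns list(prefix, surface, suffix); the gold span is the
# surface. In-scope surfaces/contexts are drawn from notation families the
# rule set covers exactly; out-of-scope ones from documented variants no
# rule matches (verified by tests that call the rule engine).

pick <- function(x) x[[sample.int(length(x), 1L)]]

render_dat <- function(in_scope) {
  y <- sample(2015:2024, 1); m <- sample(1:12, 1); d <- sample(1:28, 1)
  surface <- if (in_scope) {
    switch(sample.int(14, 1),
           sprintf("%d-%02d-%02d", y, m, d),
           sprintf("%d.%02d.%02d", y, m, d),
           sprintf("%d/%02d/%02d", y, m, d),
           sprintf("%d%02d%02d", y, m, d),
           sprintf("%d년 %d월 %d일", y, m, d),
           sprintf("%d년 %d월", y, m),
           sprintf("%d월 %d일", m, d),
           sprintf("%d년", y),
           sprintf("'%02d.%d.%d", y %% 100, m, d),
           sprintf("%s %d, %d", month_abbrev()[m], d, y),
           sprintf("%d %s %d", d, month_abbrev()[m], y),
           sprintf("%02d/%02d/%d", m, d, y),
           sprintf("%d-%02d-%02d (%s)", y, m, d,
                   pick(c("월", "화", "수", "목", "금", "토", "일"))),
           sprintf("%d-%02d-%02d %02d:%02d", y, m, d,
                   sample(0:23, 1), sample(0:59, 1)))
  } else {
    switch(sample.int(3, 1),
           sprintf("%02d-%02d-%d", d, m, y),
           sprintf("%d %02d %02d", y, m, d),
           sprintf("%d.%d.%d", y %% 100, m, d))
  }
  ctx <- pick(list(c("", " 촬영"), c("", " 시행한 검사와 비교"),
                   c("on ", ""), c("", " follow-up 영상"),
                   c("외부 ", " 검사 참조"), c("since ", "")))
  list(prefix = ctx[1], surface = surface, suffix = ctx[2])
}

render_per <- function(subcategory, in_scope) {
  name <- pick(synth_names())
  if (!in_scope) {
    ctx <- if (subcategory == "staff") {
      pick(list(c("담당의 ", ""), c("Dr. ", ""), c("서명 ", ""),
                c("", " 드림")))
    } else {
      pick(list(c("환자 ", ""), c("보호자 ", "")))
    }
    return(list(prefix = ctx[1], surface = name, suffix = ctx[2]))
  }
  if (subcategory == "staff") {
    variant <- sample.int(8, 1)
    if (variant == 8L) {
      return(list(prefix = "final report /", surface = pick(synth_initials()),
                  suffix = "/"))
    }
    ctx <- list(c("", " 확인함"), c("confirmed by ", ""), c("by ", ""),
                c("from ", " 소견 청취"), c("의료진: ", ""),
                c("판독의 ", ""), c("", " 교수 판독"))[[variant]]
  } else {
    ctx <- pick(list(c("환자이름: ", ""), c("환자 이름: ", ""),
                     c("patient name: ", ""), c("환자성명: ", "")))
  }
  list(prefix = ctx[1], surface = name, suffix = ctx[2])
}

render_org <- function(in_scope) {
  surface <- if (in_scope) pick(synth_hospitals()) else
    pick(synth_hospitals_oos())
  ctx <- pick(list(c("", " 에서 전원됨"), c("외부 ", " 영상 비교"),
                   c("referred to ", ""), c("images from ", ""),
                   c("", " 외래 기록 참조")))
  list(prefix = ctx[1], surface = surface, suffix = ctx[2])
}

render_loc <- function(in_scope) {
  surface <- if (in_scope) pick(synth_regions()) else pick(synth_regions_oos())
  ctx <- pick(list(c("", " local에서 시행"), c("", " 지역에서 내원함"),
                   c("거주지 ", "")))
  list(prefix = ctx[1], surface = surface, suffix = ctx[2])
}

render_num <- function(in_scope) {
  d4 <- sprintf("%04d", sample(0:9999, 1))
  d8 <- as.character(sample(30000000:99999999, 1)) # cannot look like YYYYMMDD
  tel <- sprintf("03%d-%d-%04d", sample(1:3, 1), sample(100:999, 1),
                 sample(0:9999, 1))
  if (in_scope) {
    v <- pick(list(list("Tel. ", d4, ""), list("T. ", d4, ""),
                   list("전화번호: ", tel, ""),
                   list("환자번호: ", d8, ""), list("내선 ", d4, "")))
  } else {
    v <- pick(list(list("연락처 ", d4, ""), list("등록번호 ", d8, ""),
                   list("", d4, "번으로 문의")))
  }
  list(prefix = v[[1]], surface = v[[2]], suffix = v[[3]])
}

render_etc <- function(in_scope) {
  age <- sample(1:99, 1)
  if (in_scope) {
    v <- pick(list(
      list("", sprintf("%d세", age), " 환자의 검사"),
      list("", sprintf("%d-year-old", age), " patient"),
      list("성별: ", pick(c("남자", "여자", "남성", "여성", "male", "female")), ""),
      list("", pick(c("한국인", "미국인", "중국인", "일본인", "외국인")),
           " 환자임")))
  } else {
    v <- pick(list(list("나이 ", as.character(age), ""),
                   list("age ", as.character(age), ""),
                   list("국적 ", "한국", "")))
  }
  list(prefix = v[[1]], surface = v[[2]], suffix = v[[3]])
}

#' Render one PHI instance
#'
#' Draws a PHI surface and its context template from the notation families
#' of the given category, using the current RNG stream (seed with
#' [set.seed()] or let [generate_corpus()] manage seeding). With
#' `in_scope = TRUE` the rendered snippet is detected exactly by the
#' default rule set; with `in_scope = FALSE` it is a documented
#' out-of-scope variant (novel date punctuation, unanchored staff-name
#' contexts, unlisted clinic names, unanchored numbers) that no rule
#' matches.
#'
#' @param category PHI category code.
#' @param in_scope Draw from rule-covered (`TRUE`) or out-of-scope
#'   (`FALSE`) notation families.
#' @param subcategory For PER: `"staff"` or `"patient"`.
#' @return List with the full `snippet`, the gold `start`/`end` offsets of
#'   the PHI surface within it (0-based, half-open), `surface`, `category`
#'   and `subcategory`.
#' @export
render_phi <- function(category, in_scope = TRUE, subcategory = NULL) {
  stopifnot(category %in% phi_categories())
  if (category == "PER" && is.null(subcategory)) subcategory <- "staff"
  r <- switch(category,
              DAT = render_dat(in_scope),
              PER = render_per(subcategory, in_scope),
              ORG = render_org(in_scope),
              LOC = render_loc(in_scope),
              NUM = render_num(in_scope),
              ETC = render_etc(in_scope))
  start <- stringi::stri_length(r$prefix)
  end <- start + stringi::stri_length(r$surface)
  list(snippet = paste0(r$prefix, r$surface, r$suffix),
       start = start, end = end, surface = r$surface,
       category = category,
       subcategory = if (category == "PER") subcategory else NA_character_)
}

# ---- Configuration and corpus assembly ---------------------------------

#' Synthetic corpus configuration
#'
#' Defaults emulate the source data distribution: about 10% of notes
#' contain PHI, and the category mix is proportional to the observed PHI
#' word counts of the rule-development corpus (dates dominate at ~86% of
#' instances, staff names ~5%, patient names ~4%, hospitals ~4%, regions,
#' numbers and age/sex/nationality are rare).
#'
#' @param seed Integer seed; the corpus is byte-identical across runs at a
#'   fixed seed.
#' @param n_notes Number of notes to generate.
#' @param phi_note_fraction Fraction of notes carrying at least one PHI
#'   instance (set to 1 when generating training pools, which count
#'   PHI-bearing notes only).
#' @param category_mix Named weights over `DAT`, `PER_staff`,
#'   `PER_patient`, `ORG`, `LOC`, `NUM`, `ETC`.
#' @param out_of_scope_fraction Fraction of PHI instances rendered with
#'   pattern variants outside the rule set.
#' @param department_mix Fraction of non-radiology-flavored notes.
#' @param homonym_trap_rate Rate of injecting non-PHI homonym text the
#'   rules are known to false-positive on (고려해, 중앙값, CMC joint,
#'   상기확인함).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_notes = 1000L,
                         phi_note_fraction = 0.10,
                         category_mix = c(DAT = 1045, PER_staff = 56,
                                          PER_patient = 50, ORG = 47,
                                          LOC = 7, NUM = 3, ETC = 5),
                         out_of_scope_fraction = 0,
                         department_mix = 0.05,
                         homonym_trap_rate = 0) {
  fam <- c("DAT", "PER_staff", "PER_patient", "ORG", "LOC", "NUM", "ETC")
  if (!all(fam %in% names(category_mix)) || any(category_mix < 0) ||
      sum(category_mix) <= 0) {
    stop("synth_config: category_mix must be non-negative weights over ",
         paste(fam, collapse = ", "), call. = FALSE)
  }
  for (f in c("phi_note_fraction", "out_of_scope_fraction",
              "department_mix", "homonym_trap_rate")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("synth_config: ", f, " must be in [0,1]", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_notes = as.integer(n_notes),
                 phi_note_fraction = phi_note_fraction,
                 category_mix = category_mix[fam],
                 out_of_scope_fraction = out_of_scope_fraction,
                 department_mix = department_mix,
                 homonym_trap_rate = homonym_trap_rate),
            class = "synth_config")
}

# Assemble one note from filler sentences, PHI snippets and (optionally)
# homonym traps; returns the clinical_note with gold annotations.
assemble_note <- function(i, config) {
  department <- if (runif(1) < config$department_mix) "other" else "radiology"
  filler <- synth_filler(department)
  segments <- lapply(seq_len(sample(2:4, 1)),
                     function(j) list(text = pick(filler), phi = NULL))
  if (runif(1) < config$phi_note_fraction) {
    n_phi <- min(1L + stats::rpois(1, 0.8), 4L)
    for (j in seq_len(n_phi)) {
      fam <- sample(names(config$category_mix), 1, prob = config$category_mix)
      category <- sub("_.*$", "", fam)
      subcat <- if (category == "PER") sub("^PER_", "", fam) else NULL
      in_scope <- runif(1) >= config$out_of_scope_fraction
      r <- render_phi(category, in_scope, subcat)
      segments <- c(segments, list(list(text = paste0(r$snippet, "."),
                                        phi = r)))
    }
  }
  if (runif(1) < config$homonym_trap_rate) {
    segments <- c(segments, list(list(text = pick(synth_traps()), phi = NULL)))
  }
  segments <- segments[sample(length(segments))]
  offset <- 0L
  texts <- character(length(segments))
  phi_rows <- list()
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    texts[k] <- seg$text
    if (!is.null(seg$phi)) {
      phi_rows[[length(phi_rows) + 1L]] <- data.frame(
        start = offset + seg$phi$start, end = offset + seg$phi$end,
        category = seg$phi$category, subcategory = seg$phi$subcategory,
        surface = seg$phi$surface, stringsAsFactors = FALSE)
    }
    offset <- offset + stringi::stri_length(seg$text) + 1L # " " separator
  }
  phi <- if (length(phi_rows)) do.call(rbind, phi_rows) else NULL
  if (!is.null(phi)) phi <- phi[order(phi$start), , drop = FALSE]
  clinical_note(sprintf("synth-%06d", i), paste(texts, collapse = " "),
                department, phi = phi)
}

#' Generate a synthetic annotated corpus
#'
#' Builds bilingual radiology-style (and other-department) notes from
#' clinical filler templates with PHI instances injected according to the
#' configured category mix. Gold annotations carry exact spans and
#' staff/patient subcategories; they are generated directly (the rules are
#' the system under test, never the ground-truth authority). Deterministic
#' under the config seed.
#'
#' @param config A [synth_config()].
#' @return List of [clinical_note()] objects with gold `phi` tables.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_notes), assemble_note, config = config)
  })
}

#' Inject homonym traps into a note
#'
#' Appends, with probability `rate` per trap draw, non-PHI text that the
#' rule engine is known to false-positive on (고려해 "considering",
#' 중앙값 "median", CMC as a joint, 상기확인함). Gold annotations are
#' unchanged: traps are gold-O, and exist to exercise precision accounting
#' and the corpus-correction workflow.
#'
#' @param note A [clinical_note()].
#' @param rate Probability of injecting a trap.
#' @param seed Optional seed; defaults to the current RNG stream.
#' @return The (possibly extended) note.
#' @export
inject_homonym_traps <- function(note, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  draw <- function() {
    if (runif(1) < rate) {
      note$text <<- paste(note$text, pick(synth_traps()))
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
  note
}
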