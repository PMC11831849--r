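#' Normalize note text to NFC
#'
#' All text is canonically composed (Unicode NFC) at ingestion so that
#' Korean syllables have a single representation before regex matching.
#' Character offsets everywhere in the package refer to code points of the
#' NFC-normalized text, 0-based and half-open.
#'
#' @param raw Character vector of raw note text.
#' @param note_id Optional identifier used in error messages.
#' @return NFC-normalized character vector. Idempotent.
#' @export
normalize_text <- function(raw, note_id = NULL) {
  if (!is.character(raw)) {
    stop("normalize_text: text must be character",
         if (!is.null(note_id)) paste0(" (note_id: ", note_id, ")"), call. = FALSE)
  }
  if (anyNA(raw) || !all(stringi::stri_enc_isutf8(raw))) {
    stop("normalize_text: undecodable text",
         if (!is.null(note_id)) paste0(" in note ", note_id), call. = FALSE)
  }
  stringi::stri_trans_nfc(raw)
}

#' Construct a clinical note
#'
#' A note is a list with a unique `note_id`, a `department` flavor
#' (`"radiology"` or `"other"`), NFC-normalized `text`, and optionally a
#' `phi` annotation table (columns `start`, `end`, `category`,
#' `subcategory`, `surface`; offsets 0-based half-open in code points).
#'
#' @param note_id Opaque identifier string.
#' @param text Note text (normalized on construction).
#' @param department `"radiology"` or `"other"`.
#' @param phi Optional annotation data frame.
#' @return An object of class `clinical_note`.
#' @export
clinical_note <- function(note_id, text, department = c("radiology", "other"),
                          phi = NULL) {
  department <- match.arg(department)
  text <- normalize_text(text, note_id = note_id)
  if (!nzchar(text)) {
    stop("clinical_note: empty text after normalization (note_id: ",
         note_id, ")", call. = FALSE)
  }
  note <- structure(
    list(note_id = as.character(note_id), department = department, text = text),
    class = "clinical_note")
  if (!is.null(phi)) note$phi <- validate_annotations(phi, text, note_id)
  note
}

#' @export
print.clinical_note <- function(x, ...) {
  cat(sprintf("<clinical_note %s [%s], %d code points, %d annotations>\n",
              x$note_id, x$department, stringi::stri_length(x$text),
              if (is.null(x$phi)) 0L else nrow(x$phi)))
  invisible(x)
}

# Empty annotation table with the canonical columns.
empty_annotations <- function() {
  data.frame(start = integer(), end = integer(), category = character(),
             subcategory = character(), surface = character(),
             stringsAsFactors = FALSE)
}

# Check span bounds, category values, the PER-only subcategory contract and
# the surface/slice round trip.
validate_annotations <- function(phi, text, note_id = "?") {
  if (is.null(phi) || nrow(phi) == 0) return(empty_annotations())
  phi <- as.data.frame(phi, stringsAsFactors = FALSE)
  if (is.null(phi$subcategory)) phi$subcategory <- NA_character_
  n <- stringi::stri_length(text)
  bad <- phi$start < 0 | phi$end > n | phi$start >= phi$end
  if (any(bad)) {
    stop("invalid span in note ", note_id, ": [", phi$start[which(bad)[1]],
         ",", phi$end[which(bad)[1]], ") with text length ", n, call. = FALSE)
  }
  if (!all(phi$category %in% phi_categories())) {
    stop("unknown PHI category in note ", note_id, call. = FALSE)
  }
  has_sub <- !is.na(phi$subcategory)
  if (any(has_sub & phi$category != "PER") ||
      any(has_sub & !phi$subcategory %in% c("staff", "patient"))) {
    stop("subcategory is only valid as staff/patient on PER (note ",
         note_id, ")", call. = FALSE)
  }
  slice <- stringi::stri_sub(text, phi$start + 1L, phi$end)
  if (is.null(phi$surface)) {
    phi$surface <- slice
  } else if (!identical(phi$surface, slice)) {
    stop("annotation surface does not equal the text slice in note ",
         note_id, call. = FALSE)
  }
  phi[c("start", "end", "category", "subcategory", "surface")]
}

#' Create a PHI annotation table
#'
#' Convenience constructor for gold or predicted annotation rows.
#'
#' @param start,end Integer offsets (0-based, half-open, code points).
#' @param category PHI category codes (see [phi_categories()]).
#' @param subcategory `"staff"`/`"patient"` for PER rows, else `NA`.
#' @param text The note text the spans refer to (used to fill `surface`
#'   and validate bounds).
#' @return Annotation data frame.
#' @export
phi_annotation <- function(start, end, category, subcategory = NA_character_,
                           text) {
  phi <- data.frame(start = as.integer(start), end = as.integer(end),
                    category = category,
                    subcategory = rep_len(subcategory, length(start)),
                    stringsAsFactors = FALSE)
  validate_annotations(phi, text)
}

#' Read clinical notes from JSONL
#'
#' One JSON object per line with keys `note_id`, `department`, `text`, and
#' optionally `phi` (a list of objects with `start`, `end`, `category`,
#' `subcategory`). Text is NFC-normalized on read.
#'
#' @param path Path to a JSONL file.
#' @return List of [clinical_note()] objects.
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$note_id) || is.null(rec$text)) {
      stop("read_notes: malformed record at line ", i, " of ", path,
           call. = FALSE)
    }
    dep <- if (is.null(rec$department)) "radiology" else rec$department
    phi <- if (!is.null(rec$phi) && length(rec$phi)) as.data.frame(rec$phi)
    out[[i]] <- clinical_note(rec$note_id, rec$text, dep, phi = phi)
    ids[i] <- rec$note_id
  }
  if (anyDuplicated(ids)) {
    stop("read_notes: duplicate note_id '", ids[anyDuplicated(ids)],
         "' in ", path, call. = FALSE)
  }
  out
}

#' Write clinical notes as JSONL
#'
#' Inverse of [read_notes()]. Annotations, when present, are written under
#' key `phi`.
#'
#' @param notes List of [clinical_note()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_notes <- function(notes, path) {
  lines <- vapply(notes, function(n) {
    rec <- list(note_id = n$note_id, department = n$department, text = n$text)
    if (!is.null(n$phi) && nrow(n$phi)) rec$phi <- n$phi
    jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
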