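# ICD-10 code normalisation and chapter lookup.

# Chapter ranges, keyed by 3-character category. Boundaries follow the
# published ICD-10 tabular list: A00-B99 I, C00-D48 II, D50-D89 III,
# E00-E90 IV, F00-F99 V, G00-G99 VI, H00-H59 VII, H60-H95 VIII,
# I00-I99 IX, J00-J99 X, K00-K93 XI, L00-L99 XII, M00-M99 XIII,
# N00-N99 XIV, O00-O99 XV, P00-P96 XVI, Q00-Q99 XVII, R00-R99 XVIII,
# S00-T98 XIX, V01-Y98 XX, Z00-Z99 XXI, U00-U99 XXII.
.icd10_chapter_table <- data.frame(
  from    = c("A00", "C00", "D50", "E00", "F00", "G00", "H00", "H60", "I00",
              "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
              "S00", "V01", "Z00", "U00"),
  to      = c("B99", "D48", "D89", "E90", "F99", "G99", "H59", "H95", "I99",
              "J99", "K93", "L99", "M99", "N99", "O99", "P96", "Q99", "R99",
              "T98", "Y98", "Z99", "U99"),
  chapter = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
              "X", "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII",
              "XIX", "XX", "XXI", "XXII"),
  stringsAsFactors = FALSE
)

#' Round an ICD-10 code to its 3-character category
#'
#' Codes are upper-cased and truncated to their first 3 characters. A code
#' whose truncation does not match the `letter + 2 digits` category pattern is
#' rejected: the function returns `NA` for it rather than erroring, so callers
#' can log and drop invalid codes.
#'
#' @param x Character vector of raw ICD-10 codes (3 or 4 characters, with or
#'   without a decimal point, any case).
#' @return Character vector of 3-character categories, `NA` where rejected.
#' @examples
#' normalize_icd10(c("F31.8", "f200", "QQ1"))
#' @export
normalize_icd10 <- function(x) {
  x <- toupper(as.character(x))
  code3 <- substr(x, 1L, 3L)
  code3[!grepl("^[A-Z][0-9][0-9]$", code3)] <- NA_character_
  code3
}

#' ICD-10 chapter of a 3-character category
#'
#' Maps 3-character ICD-10 categories to their chapter (Roman numerals I-XXII)
#' via the published chapter ranges. Chapters XV-XXII cover obstetric,
#' perinatal, congenital, symptom, injury, external-cause, health-status and
#' special-purpose codes; the event-stream builder excludes them by default as
#' non-disease diagnoses.
#'
#' @param code3 Character vector of valid 3-character categories.
#' @return Character vector of chapter labels.
#' @examples
#' icd10_chapter(c("I10", "F17", "O80"))
#' @export
icd10_chapter <- function(code3) {
  code3 <- as.character(code3)
  bad <- !grepl("^[A-Z][0-9][0-9]$", code3)
  if (any(bad & !is.na(code3))) {
    stop("invalid 3-character ICD-10 code(s): ",
         paste(unique(code3[bad & !is.na(code3)]), collapse = ", "))
  }
  out <- rep(NA_character_, length(code3))
  tab <- .icd10_chapter_table
  for (i in seq_len(nrow(tab))) {
    hit <- !is.na(code3) & code3 >= tab$from[i] & code3 <= tab$to[i]
    out[hit] <- tab$chapter[i]
  }
  if (any(is.na(out) & !is.na(code3))) {
    # gaps in the tabular list (e.g. D49, H96-H99): assign by letter block
    gap <- is.na(out) & !is.na(code3)
    letter <- substr(code3[gap], 1L, 1L)
    out[gap] <- c(D = "III", E = "IV", H = "VIII", K = "XI", P = "XVI",
                  T = "XIX", U = "XXII", V = "XX", W = "XX", X = "XX",
                  Y = "XX")[letter]
  }
  out
}

#' Non-disease ICD-10 chapters excluded from the analysis
#'
#' @return Character vector of the chapter labels XV-XXII.
#' @export
excluded_chapters <- function() {
  c("XV", "XVI", "XVII", "XVIII", "XIX", "XX", "XXI", "XXII")
}
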