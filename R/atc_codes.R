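#' Anatomical Therapeutic Chemical (ATC) code handling
#'
#' The ATC system classifies drugs at five levels. The second level (one
#' anatomical main-group letter plus two digits, e.g. `"C09"` for agents
#' acting on the renin-angiotensin system, `"B01"` for antithrombotics) is
#' the therapeutic subgroup this pipeline classifies into. Full fifth-level
#' codes (e.g. `"C09BA03"`) appear in web search results and are truncated
#' to their first three characters.
#'
#' Validation here is purely syntactic: no ATC index is bundled (the WHO
#' index is versioned and licensed). An optional user-supplied allow-list
#' can tighten [parse_level2()] to a known code set.
#'
#' @name atc_codes
NULL

# The 14 WHO anatomical main groups.
ATC_MAIN_GROUPS <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N",
                     "P", "R", "S", "V")

#' Regular expression matching a full (fifth-level) ATC code
#'
#' Letter, two digits, two letters, two digits. This is the raw extraction
#' pattern used by the search benchmark; it deliberately accepts any capital
#' letter in first position (extraction fidelity beats strictness — strict
#' main-group validation happens in [parse_level2()]).
#'
#' @format A character scalar usable with [base::gregexpr()].
#' @export
ATC_FULL_CODE_REGEX <- "[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}"

#' Validate second-level ATC codes
#'
#' Upper-cases and trims the input, then checks it against the second-level
#' shape: one of the 14 WHO anatomical main-group letters followed by two
#' digits.
#'
#' @param text Character vector of candidate codes.
#' @param allow Optional character vector of permitted codes (e.g. from
#'   [read_atc_allowlist()]); when supplied, a syntactically valid code not
#'   in the list is rejected.
#' @return Character vector of validated, upper-cased codes.
#' @examples
#' parse_level2("C09")
#' parse_level2("b01")
#' @seealso [is_level2()] for a non-throwing predicate.
#' @export
parse_level2 <- function(text, allow = NULL) {
  code <- toupper(trimws(as.character(text)))
  ok <- is_level2(code, allow = allow)
  if (any(!ok)) {
    bad <- unique(code[!ok])
    stop("invalid second-level ATC code(s): ",
         paste(shQuote(bad), collapse = ", "), call. = FALSE)
  }
  code
}

#' Test whether strings are valid second-level ATC codes
#'
#' @inheritParams parse_level2
#' @return Logical vector.
#' @export
is_level2 <- function(text, allow = NULL) {
  code <- toupper(trimws(as.character(text)))
  pattern <- paste0("^[", paste(ATC_MAIN_GROUPS, collapse = ""), "][0-9]{2}$")
  ok <- !is.na(code) & grepl(pattern, code)
  if (!is.null(allow)) {
    ok <- ok & code %in% toupper(trimws(allow))
  }
  ok
}

#' Truncate full ATC codes to the second level
#'
#' A fifth-level code's first three characters are its second-level
#' therapeutic subgroup: `"C09BA03"` (lisinopril and diuretics) truncates
#' to `"C09"`.
#'
#' @param full Character vector of full 7-character ATC codes.
#' @return Character vector of second-level codes.
#' @export
truncate_to_level2 <- function(full) {
  full <- toupper(trimws(as.character(full)))
  bad <- !grepl(paste0("^", ATC_FULL_CODE_REGEX, "$"), full)
  if (any(bad)) {
    stop("not full ATC code(s): ",
         paste(shQuote(unique(full[bad])), collapse = ", "), call. = FALSE)
  }
  substr(full, 1L, 3L)
}

#' Read a second-level ATC allow-list file
#'
#' Plain text, one code per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of upper-cased codes.
#' @export
read_atc_allowlist <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_level2(lines)
}
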