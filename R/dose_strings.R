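#' Anonymized daily dose strings from raw dispense records
#'
#' A smart-dispenser drug table holds, per dispensed line item, a patient
#' identifier, the scheduled dispense date, a free-text drug name (often a
#' manufacturer-generic concatenation such as "apo-rosuvastatin" or a brand
#' name), a free-text strength ("50 mg", "50 MG", "25/100 MG", sometimes
#' missing), and a pill quantity that may be fractional. The classifier
#' never sees these records: it sees irreversibly anonymized *daily dose
#' strings* of the form
#'
#' ```
#' pms-quetiapine|2 pills of 200 mg, 4 pills of 25 mg
#' ```
#'
#' built by (1) summing pill quantity within (patient, date, drug name,
#' strength), (2) rendering each strength total as "{quantity} pill(s) of
#' {strength}", (3) joining multiple strengths of one drug-day with commas,
#' and (4) dropping the patient identifier and date and keeping distinct
#' strings only. Drug names are lower-cased and nothing else; missing
#' strengths become "UNK"; strengths of "0" pass through unchanged.
#'
#' @name dose_strings
NULL

#' Normalize a drug name
#'
#' Lower-cases and trims surrounding whitespace; interior text is left
#' untouched (no spelling correction, no manufacturer-prefix stripping —
#' downstream classifiers handle name variants).
#'
#' @param raw Character vector of drug names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_drug_name("Apo-Rosuvastatin")
#' @export
normalize_drug_name <- function(raw) {
  out <- tolower(trimws(as.character(raw)))
  if (any(is.na(out) | !nzchar(out))) {
    stop("invalid record: empty drug name", call. = FALSE)
  }
  out
}

#' Impute missing drug strengths
#'
#' Missing or empty strengths become `"UNK"`; any non-empty string —
#' including `"0"` — passes through unchanged. Strength text is never
#' case-normalized ("mg" and "MG" are used interchangeably upstream).
#'
#' @param raw Character vector of strength strings (may contain `NA`).
#' @return Character vector with no missing values.
#' @export
impute_strength <- function(raw) {
  raw <- as.character(raw)
  missing <- is.na(raw) | !nzchar(trimws(raw))
  raw[missing] <- "UNK"
  raw
}

#' Render a pill quantity as text
#'
#' `"1 pill"` when the quantity is exactly one, otherwise `"{q} pills"`
#' (fractions below one included: "0.5 pills"). Integer quantities render
#' without a decimal point; non-integers with up to two decimals, trailing
#' zeros stripped.
#'
#' @param quantity Numeric vector of positive pill counts.
#' @return Character vector.
#' @examples
#' format_quantity_string(c(1, 2, 0.5))
#' @export
format_quantity_string <- function(quantity) {
  quantity <- as.numeric(quantity)
  if (any(is.na(quantity) | quantity <= 0)) {
    stop("invalid quantity: must be > 0", call. = FALSE)
  }
  q_txt <- format_quantity_number(quantity)
  ifelse(quantity == 1, paste(q_txt, "pill"), paste(q_txt, "pills"))
}

# Integer quantities bare ("2"), non-integers with up to two decimals and
# trailing zeros stripped ("0.5", "0.25").
format_quantity_number <- function(q) {
  is_int <- abs(q - round(q)) < 1e-9
  out <- character(length(q))
  out[is_int] <- format(round(q[is_int]), scientific = FALSE, trim = TRUE)
  if (any(!is_int)) {
    txt <- formatC(q[!is_int], format = "f", digits = 2)
    txt <- sub("0+$", "", txt)
    txt <- sub("\\.$", "", txt)
    out[!is_int] <- txt
  }
  out
}

# Leading numeral of a strength string, NA when unparseable; used only to
# order multi-strength lists (largest strength first).
leading_strength_value <- function(strength) {
  vapply(seq_along(strength), function(i) {
    v <- regmatches(strength[i], regexpr("^[0-9]+(\\.[0-9]+)?", trimws(strength[i])))
    if (length(v) == 0) NA_real_ else as.numeric(v)
  }, numeric(1))
}

#' Aggregate dispense records into per-day per-drug dose totals
#'
#' Sums pill quantity within (patient, dispense date, lower-cased drug
#' name, imputed strength), then nests the strength totals per
#' (patient, date, drug). Within one drug-day, strengths are ordered by
#' descending numeric value of the strength's leading number; strengths
#' with no parseable leading number keep first-appearance order after the
#' parseable ones.
#'
#' @param records Data frame with columns `patient_id`, `dispense_date`,
#'   `drug_name`, `strength`, `quantity` (see [read_dispense_csv()]).
#' @return A tibble with one row per (patient, date, drug) and a
#'   `doses` list-column of tibbles (`strength`, `total_quantity`).
#' @export
aggregate_daily_doses <- function(records) {
  cols <- c("patient_id", "dispense_date", "drug_name", "strength", "quantity")
  if (nrow(records) == 0) {
    return(tibble::tibble(patient_id = character(), dispense_date = character(),
                          drug_name = character(), doses = list()))
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(records$quantity) | records$quantity < 0)) {
    stop("invalid record: quantity must be >= 0", call. = FALSE)
  }

  rec <- tibble::tibble(
    patient_id    = as.character(records$patient_id),
    dispense_date = as.character(records$dispense_date),
    drug_name     = normalize_drug_name(records$drug_name),
    strength      = impute_strength(records$strength),
    quantity      = as.numeric(records$quantity),
    .order        = seq_len(nrow(records))
  )

  per_strength <- rec |>
    dplyr::group_by(.data$patient_id, .data$dispense_date, .data$drug_name,
                    .data$strength) |>
    dplyr::summarise(total_quantity = sum(.data$quantity),
                     .first_seen = min(.data$.order), .groups = "drop")

  per_strength$.strength_value <- leading_strength_value(per_strength$strength)

  per_strength |>
    dplyr::arrange(.data$patient_id, .data$dispense_date, .data$drug_name,
                   is.na(.data$.strength_value),
                   dplyr::desc(.data$.strength_value), .data$.first_seen) |>
    dplyr::group_by(.data$patient_id, .data$dispense_date, .data$drug_name) |>
    dplyr::summarise(
      doses = list(dplyr::pick("strength", "total_quantity")),
      .groups = "drop"
    )
}

#' Render aggregates as anonymized daily dose strings
#'
#' Each (patient, date, drug) aggregate becomes
#' `<drug>|<q1> pill(s) of <s1>, <q2> pill(s) of <s2>, ...`. The patient
#' identifier and date are discarded and exact duplicates are collapsed,
#' so two patients on identical regimens contribute one string.
#'
#' @param aggregates Output of [aggregate_daily_doses()].
#' @return Character vector of distinct daily dose strings, in first
#'   appearance order.
#' @export
render_dose_strings <- function(aggregates) {
  if (nrow(aggregates) == 0) return(character())
  rendered <- vapply(seq_len(nrow(aggregates)), function(i) {
    d <- aggregates$doses[[i]]
    terms <- paste(format_quantity_string(d$total_quantity), "of", d$strength)
    paste0(aggregates$drug_name[i], "|", paste(terms, collapse = ", "))
  }, character(1))
  unique(rendered)
}

#' Build daily dose strings straight from dispense records
#'
#' Convenience composition of [aggregate_daily_doses()] and
#' [render_dose_strings()].
#'
#' @inheritParams aggregate_daily_doses
#' @return Character vector of distinct anonymized daily dose strings.
#' @export
build_dose_strings <- function(records) {
  render_dose_strings(aggregate_daily_doses(records))
}

#' Read a dispense-record CSV
#'
#' Expected header: `patient_id,dispense_date,drug_name,strength,quantity`
#' with ISO-8601 dates; `strength` may be empty.
#'
#' @param path CSV file path.
#' @return A tibble of dispense records.
#' @export
read_dispense_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    patient_id = "character", dispense_date = "character",
    drug_name = "character", strength = "character", quantity = "numeric"
  ))
  tibble::as_tibble(df)
}

#' Write dispense records to CSV
#'
#' @param records Tibble of dispense records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dispense_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write daily dose strings to disk
#'
#' One string per line, UTF-8. With `format = "jsonl"` writes JSON Lines
#' `{"input": "<string>"}` objects ready for the classifier stage.
#'
#' @param strings Character vector of daily dose strings.
#' @param path Output path.
#' @param format `"txt"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_dose_strings <- function(strings, path, format = c("txt", "jsonl")) {
  format <- match.arg(format)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "txt") {
    writeLines(strings, con)
  } else {
    writeLines(vapply(strings, function(s) {
      jsonlite::toJSON(list(input = s), auto_unbox = TRUE)
    }, character(1), USE.NAMES = FALSE), con)
  }
  invisible(path)
}

#' Read daily dose strings from disk
#'
#' @param path File path (plain text, one string per line, or JSON Lines
#'   with an `input` field; detected from the first non-empty line).
#' @return Character vector of dose strings.
#' @export
read_dose_strings <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(character())
  if (startsWith(trimws(lines[1]), "{")) {
    vapply(lines, function(l) jsonlite::fromJSON(l)$input, character(1),
           USE.NAMES = FALSE)
  } else {
    lines
  }
}
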