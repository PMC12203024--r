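#' Synthetic dispense records, mock backends and rule-based ATC truth
#'
#' Real dispense data is private, so everything needed to exercise the
#' pipeline offline is generated: multi-region-looking dispense records
#' (manufacturer-prefixed and brand drug names, unstandardized strength
#' strings, multi-strength regimens, fractional pills, missing strengths),
#' a deterministic rule-based mock completion backend whose ground truth is
#' dose-dependent (low-dose aspirin B01, high-dose N02; high-dose folic
#' acid B03; low-dose prednisone H02), and a mock search backend emitting
#' result pages with embedded full ATC codes.
#'
#' The bundled formulary is synthetic: drug names, aliases and strengths
#' are realistic, but the dose rules are simplifications built for
#' rule-based mocking, not clinical statements.
#'
#' @name synthetic_data
NULL

#' Load the bundled (or a user-supplied) formulary
#'
#' @param path Optional path to a formulary JSON file; defaults to the
#'   bundled synthetic formulary.
#' @return A list of formulary entries, each with `canonical_name`,
#'   `aliases`, `strengths`, `default_code`, `default_next`, `dose_rules`
#'   (ordered list of `min_mg`/`max_mg` predicates mapping total daily mg
#'   to a best / next-best code pair).
#' @export
load_formulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "formulary.json", package = "atcpipe",
                        mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- raw$entries
  for (e in entries) {
    codes <- c(e$default_code, e$default_next,
               unlist(lapply(e$dose_rules, function(r) c(r$best, r$next_best))))
    codes <- codes[!vapply(codes, is.null, logical(1))]
    if (length(codes) > 0) parse_level2(unlist(codes))
  }
  class(entries) <- c("formulary", "list")
  entries
}

#' @rdname load_formulary
#' @export
default_formulary <- function() {
  load_formulary()
}

# Alias-indexed lookup; returns the entry or NULL.
formulary_lookup <- function(formulary, drug_name) {
  name <- tolower(trimws(drug_name))
  for (e in formulary) {
    if (name %in% tolower(trimws(unlist(e$aliases)))) return(e)
  }
  NULL
}

#' Total daily milligrams implied by a dose list (mock arithmetic)
#'
#' Parses each "<q> pill(s) of <strength>" term, takes the leading numeral
#' of the strength (combination strengths like "25/100 MG" contribute their
#' first component; units are ignored) and multiplies by the pill count.
#' Returns `NA` when any strength lacks a leading numeral (e.g. "UNK").
#' This is a deliberate mock simplification, not dose arithmetic the real
#' pipeline performs — the classifier reasons about doses, the pipeline
#' never computes them.
#'
#' @param dose_text The portion of a daily dose string after the pipe.
#' @return Total in strength units, or `NA`.
#' @export
parse_dose_total_mg <- function(dose_text) {
  terms <- strsplit(dose_text, ",", fixed = TRUE)[[1]]
  total <- 0
  for (term in terms) {
    m <- regmatches(term,
                    regexec("^\\s*([0-9]+(?:\\.[0-9]+)?) pills? of (.*)$", term))[[1]]
    if (length(m) == 0) return(NA_real_)
    q <- as.numeric(m[2])
    sval <- leading_strength_value(m[3])
    if (is.na(sval)) return(NA_real_)
    total <- total + q * sval
  }
  total
}

#' Ground-truth classification of a daily dose string under a formulary
#'
#' Resolves the drug by alias, computes the mock total daily dose, and
#' applies the entry's ordered dose rules; when no rule matches (or the
#' dose is unparseable) the entry's default codes apply. Unknown drugs and
#' entries with no default code yield `NA` codes.
#'
#' @param formulary A formulary from [load_formulary()].
#' @param dose_string A daily dose string `<drug>|<dose list>`.
#' @return A list with `best` and `next_best` (character or `NA`).
#' @export
formulary_truth <- function(formulary, dose_string) {
  parts <- strsplit(dose_string, "|", fixed = TRUE)[[1]]
  drug <- parts[1]
  dose_text <- if (length(parts) >= 2) paste(parts[-1], collapse = "|") else ""
  entry <- formulary_lookup(formulary, drug)
  if (is.null(entry) || is.null(entry$default_code)) {
    return(list(best = NA_character_, next_best = NA_character_))
  }
  total <- parse_dose_total_mg(dose_text)
  if (!is.na(total)) {
    for (rule in entry$dose_rules) {
      lo <- rule$min_mg %||% -Inf
      hi <- rule$max_mg %||% Inf
      if (total >= lo && total <= hi) {
        return(list(best = rule$best,
                    next_best = rule$next_best %||% NA_character_))
      }
    }
  }
  list(best = entry$default_code,
       next_best = entry$default_next %||% NA_character_)
}

#' Mock backend configuration
#'
#' @param delimiter_error_rate Probability a completion is emitted
#'   malformed (pipe-free), mimicking the chain-of-thought failure mode
#'   where the model never stops reasoning to emit its delimited fields.
#' @param unknown_drug_rate Probability a completion is the
#'   "not familiar" `|NA|NA` form regardless of the drug.
#' @param seed Integer seed; per-input draws are keyed by a hash of the
#'   input so results do not depend on call order.
#' @return A list of class `mock_config`.
#' @export
mock_config <- function(delimiter_error_rate = 0, unknown_drug_rate = 0,
                        seed = 1L) {
  stopifnot(delimiter_error_rate >= 0, delimiter_error_rate <= 1,
            unknown_drug_rate >= 0, unknown_drug_rate <= 1)
  structure(list(delimiter_error_rate = delimiter_error_rate,
                 unknown_drug_rate = unknown_drug_rate,
                 seed = as.integer(seed)),
            class = "mock_config")
}

# Deterministic 31-bit hash of a string mixed with a seed.
string_hash <- function(s, seed = 0L) {
  h <- 0
  for (c in utf8ToInt(enc2utf8(s))) h <- (h * 131 + c) %% 2147483629
  as.integer((h + (as.numeric(seed) * 2654435)) %% 2147483629 + 1)
}

# k uniforms keyed by (input, seed); order-independent across inputs.
hashed_uniforms <- function(s, seed, k = 2) {
  with_local_seed(string_hash(s, seed), stats::runif(k))
}

#' Deterministic rule-based mock completion backend
#'
#' Emulates the chain-of-thought classifier: resolves the drug by alias,
#' computes the mock total daily dose, applies the formulary dose rules,
#' and emits a canonical `"<templated reasoning>|<best>|<next or NA>"`
#' completion. Fault injection (per [mock_config()]): a malformed pipe-free
#' completion with probability `delimiter_error_rate`, the `|NA|NA`
#' "not familiar" form with probability `unknown_drug_rate`. Deterministic
#' given the config seed and the input string.
#'
#' @param formulary A formulary from [load_formulary()].
#' @param config A [mock_config()].
#' @return A completion backend function usable with [classify_batch()].
#' @examples
#' backend <- mock_completion_backend(default_formulary(), mock_config())
#' backend(NULL, "aspirin|1 pill of 81mg", 0, 1000, "mock")
#' @export
mock_completion_backend <- function(formulary, config = mock_config()) {
  stopifnot(inherits(config, "mock_config"))
  function(system_text, user_text, temperature, max_tokens, model_id) {
    u <- hashed_uniforms(user_text, config$seed, 2)
    drug <- strsplit(user_text, "|", fixed = TRUE)[[1]][1]
    if (u[1] < config$delimiter_error_rate) {
      return(paste0("Considering ", drug,
                    " and its daily dose, the reasoning continued without ",
                    "ever emitting the delimited answer fields."))
    }
    if (u[2] < config$unknown_drug_rate) {
      return(paste0(drug, " is not an oral solid drug I am familiar with.|NA|NA"))
    }
    truth <- formulary_truth(formulary, user_text)
    if (is.na(truth$best)) {
      return(paste0(drug, " is not an oral solid drug I am familiar with.|NA|NA"))
    }
    dose_text <- sub("^[^|]*\\|", "", user_text)
    total <- parse_dose_total_mg(dose_text)
    dose_phrase <- if (is.na(total)) {
      paste0("The dose is unintelligible, but ", drug, " is recognised.")
    } else {
      paste0(dose_text, " is ", format_quantity_number(total),
             " per day. ", drug, " at this dose fits its usual indication.")
    }
    paste0(dose_phrase, " The most likely level 2 ATC code is ", truth$best,
           ".|", truth$best, "|",
           if (is.na(truth$next_best)) "NA" else truth$next_best)
  }
}

#' Deterministic mock search backend
#'
#' For queries built from formulary drugs, returns up to 10 result items
#' whose snippets embed full 7-character expansions of the drug's true
#' second-level code (one per item), plus `noise_codes_per_page` distractor
#' code occurrences spread over the page from the top. With zero noise the
#' majority vote recovers the true code; with 10 distractor occurrences the
#' vote ties. Unknown drugs yield code-free snippets.
#'
#' @param formulary A formulary from [load_formulary()].
#' @param noise_codes_per_page Number of distractor full-code occurrences
#'   on the whole result page.
#' @param seed Integer seed keying the deterministic distractor choice.
#' @return A search backend function usable with [classify_by_search()].
#' @export
mock_search_backend <- function(formulary, noise_codes_per_page = 0,
                                seed = 1L) {
  distractor_pool <- c("A02", "C07", "N05", "J01", "R06", "M01", "G03", "B05")
  function(query) {
    drug <- sub(" ATC Code$", "", query)
    entry <- formulary_lookup(formulary, drug)
    n_items <- 10L
    rank <- seq_len(n_items)
    title <- paste0(drug, " - drug classification, uses and dosage")
    if (is.null(entry) || is.null(entry$default_code)) {
      snippet <- paste0("No classification entry found for ", drug,
                        "; see the product monograph for details (item ",
                        rank, ").")
      return(tibble::tibble(rank = rank, title = title, snippet = snippet))
    }
    code <- entry$default_code
    pick <- string_hash(drug, seed) %% length(distractor_pool) + 1
    distractor <- distractor_pool[pick]
    if (distractor == code) {
      distractor <- distractor_pool[pick %% length(distractor_pool) + 1]
    }
    snippet <- paste0(drug, " is classified under ATC code ",
                      code, "AB0", rank %% 10,
                      " in the therapeutic subgroup ", code, ".")
    if (noise_codes_per_page > 0) {
      slots <- ((seq_len(noise_codes_per_page) - 1) %% n_items) + 1
      for (j in seq_len(noise_codes_per_page)) {
        i <- slots[j]
        snippet[i] <- paste0(snippet[i], " Related listings mention ",
                             distractor, "ZX0", j %% 10, ".")
      }
    }
    tibble::tibble(rank = rank, title = title, snippet = snippet)
  }
}

#' Generate synthetic dispense records
#'
#' Emulates a smart-dispenser drug table: each synthetic patient takes one
#' to four formulary drugs, dispensed once or twice daily over `days`
#' consecutive days starting 2024-01-01. Names are drawn from the entry's
#' aliases with occasional case-mangling; regimens may use two strengths
#' of one drug; quantities are occasionally fractional; strengths are
#' occasionally missing. Deterministic given `seed`.
#'
#' @param n_patients Number of patients.
#' @param days Days of scheduled dispenses per patient.
#' @param seed Integer seed.
#' @param formulary A formulary from [load_formulary()].
#' @param missing_strength_rate Probability a record's strength is missing.
#' @param multi_strength_rate Probability a drug regimen uses two strengths.
#' @param fractional_rate Probability a pill quantity is fractional.
#' @return A tibble of dispense records (`patient_id`, `dispense_date`,
#'   `drug_name`, `strength`, `quantity`).
#' @export
generate_drug_records <- function(n_patients, days = 7, seed = 1L,
                                  formulary = default_formulary(),
                                  missing_strength_rate = 0.05,
                                  multi_strength_rate = 0.15,
                                  fractional_rate = 0.10) {
  if (n_patients == 0) {
    return(tibble::tibble(patient_id = character(),
                          dispense_date = character(),
                          drug_name = character(), strength = character(),
                          quantity = numeric()))
  }
  with_local_seed(seed, {
    rows <- list()
    start <- as.Date("2024-01-01")
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%04d", p)
      n_drugs <- sample(1:4, 1)
      entries <- sample(seq_along(formulary), n_drugs)
      for (idx in entries) {
        e <- formulary[[idx]]
        alias <- sample(unlist(e$aliases), 1)
        if (stats::runif(1) < 0.2) alias <- toupper(alias)
        strengths <- unlist(e$strengths)
        use_two <- length(strengths) >= 2 && stats::runif(1) < multi_strength_rate
        regimen_strengths <- if (length(strengths) == 0) {
          NA_character_
        } else if (use_two) {
          sample(strengths, 2)
        } else {
          sample(strengths, 1)
        }
        per_dispense_qty <- vapply(regimen_strengths, function(s) {
          if (stats::runif(1) < fractional_rate) {
            sample(c(0.5, 1.5), 1)
          } else {
            sample(1:2, 1)
          }
        }, numeric(1))
        times_per_day <- sample(1:2, 1)
        for (d in seq_len(days)) {
          date <- as.character(start + (d - 1))
          for (t in seq_len(times_per_day)) {
            for (k in seq_along(regimen_strengths)) {
              s <- regimen_strengths[k]
              if (!is.na(s) && stats::runif(1) < missing_strength_rate) {
                s <- NA_character_
              }
              rows[[length(rows) + 1]] <- tibble::tibble(
                patient_id = pid, dispense_date = date, drug_name = alias,
                strength = s, quantity = per_dispense_qty[k]
              )
            }
          }
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Synthesize a finite population of distinct daily dose strings
#'
#' Enumerates drug-alias x strength x quantity combinations (including
#' two-strength regimens) over the formulary, shuffles them under `seed`,
#' and returns the first `N` distinct strings. The default `N` of 12294
#' mirrors the size of the dispense-string population this pipeline's
#' inference machinery is built around.
#'
#' @param N Population size.
#' @param formulary A formulary from [load_formulary()].
#' @param seed Integer seed for the shuffle.
#' @return Character vector of `N` distinct daily dose strings.
#' @export
synthesize_population <- function(N = 12294, formulary = default_formulary(),
                                  seed = 1L) {
  singles_q <- seq(0.5, 16, by = 0.5)
  pair_q <- c(0.5, 1, 2, 3, 4, 6)
  strings <- character(0)
  for (e in formulary) {
    aliases <- tolower(unlist(e$aliases))
    strengths <- unlist(e$strengths)
    if (length(strengths) == 0) strengths <- "UNK"
    for (a in aliases) {
      for (s in strengths) {
        strings <- c(strings, paste0(
          a, "|", format_quantity_string(singles_q), " of ", s))
      }
      if (length(strengths) >= 2) {
        pairs <- utils::combn(strengths, 2, simplify = FALSE)
        for (pr in pairs) {
          v <- leading_strength_value(pr)
          ord <- order(is.na(v), -ifelse(is.na(v), 0, v))
          pr <- pr[ord]
          for (q1 in pair_q) for (q2 in pair_q) {
            strings <- c(strings, paste0(
              a, "|", format_quantity_string(q1), " of ", pr[1], ", ",
              format_quantity_string(q2), " of ", pr[2]))
          }
        }
      }
    }
  }
  strings <- unique(strings)
  if (length(strings) < N) {
    stop("formulary cannot generate ", N, " distinct strings (capacity ",
         length(strings), ")", call. = FALSE)
  }
  with_local_seed(seed, sample(strings, N))
}

#' Auto-grade parsed classifications against formulary truth
#'
#' Applies the 3-point grading scale mechanically against the synthetic
#' ground truth (this exists for testing only; real outputs are graded by
#' humans and consumed as data): grade 1 when best and next-best both match
#' the truth (a truthful `NA`/`NA` refusal also earns 1), grade 2 when the
#' best code is right but the next-best is not, grade 3 for a wrong best
#' code, an unparseable completion, or a failed request.
#'
#' @param parsed Tibble from [parse_completions()], plus a `dose_string`
#'   column (or supply `dose_strings`).
#' @param formulary A formulary from [load_formulary()].
#' @param dose_strings Optional character vector aligned with `parsed`.
#' @return Integer vector of grades in \{1, 2, 3\}.
#' @export
auto_grade <- function(parsed, formulary = default_formulary(),
                       dose_strings = NULL) {
  if (is.null(dose_strings)) dose_strings <- parsed$dose_string
  stopifnot(length(dose_strings) == nrow(parsed))
  vapply(seq_len(nrow(parsed)), function(i) {
    truth <- formulary_truth(formulary, dose_strings[i])
    status <- parsed$status[i]
    if (status %in% c("failed", "delimiter_error")) return(3L)
    if (is.na(truth$best)) {
      return(if (status == "na") 1L else 3L)
    }
    if (status != "ok" || is.na(parsed$best[i])) return(3L)
    if (parsed$best[i] != truth$best) return(3L)
    next_match <- (is.na(parsed$next_best[i]) && is.na(truth$next_best)) ||
      (!is.na(parsed$next_best[i]) && !is.na(truth$next_best) &&
         parsed$next_best[i] == truth$next_best)
    if (next_match) 1L else 2L
  }, integer(1))
}
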