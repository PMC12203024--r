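#' Prompted chain-of-thought classification through a completion backend
#'
#' The classifier sends each anonymized daily dose string to a chat
#' completion backend under one of two bundled system prompts:
#'
#' * `"initial"` — few-shot prompt requesting a concise two-field
#'   `<best>|<next best>` answer;
#' * `"revised"` — chain-of-thought prompt requesting
#'   `<reasoning>|<best>|<next best or "NA">`, letting the model reason
#'   about the total daily dose (e.g. low-dose aspirin is antithrombotic,
#'   B01; high-dose aspirin is an analgesic, N02) before committing to
#'   codes.
#'
#' Backends are pluggable: any function with signature
#' `function(system_text, user_text, temperature, max_tokens, model_id)`
#' returning completion text (or signalling an error) works. The package
#' ships a deterministic rule-based mock ([mock_completion_backend()]) and
#' a thin live client ([openai_backend()]).
#'
#' @name llm_classifier
NULL

LLM_DEFAULT_MODEL <- "gpt-4o-2024-05-13"
LLM_DEFAULT_TEMPERATURE <- 0
LLM_DEFAULT_MAX_TOKENS <- 1000L

#' Load a bundled classification prompt
#'
#' @param version `"initial"` or `"revised"`.
#' @return A list with `name` and `system_text` (the verbatim prompt text
#'   from the bundled resource file).
#' @export
build_prompt <- function(version = c("revised", "initial")) {
  if (length(version) == 1 && !version %in% c("revised", "initial")) {
    stop("unknown prompt version: ", shQuote(version), call. = FALSE)
  }
  version <- match.arg(version)
  path <- system.file("prompts", paste0(version, ".txt"), package = "atcpipe",
                      mustWork = TRUE)
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  list(name = version, system_text = text)
}

#' Build a batch of classification requests
#'
#' One request per distinct dose string, with stable index-derived request
#' ids and the study's completion settings: temperature 0 (consistency over
#' creativity) and a 1000-token output cap (room for reasoning, not for
#' runaway essays).
#'
#' @param dose_strings Character vector of distinct daily dose strings.
#' @param prompt A prompt from [build_prompt()] (default: revised).
#' @param temperature Sampling temperature.
#' @param max_tokens Completion token cap.
#' @param model_id Backend model identifier (configuration only; no package
#'   behaviour depends on it).
#' @return A tibble with columns `request_id`, `system`, `user`,
#'   `temperature`, `max_tokens`, `model`.
#' @export
build_batch <- function(dose_strings, prompt = build_prompt("revised"),
                        temperature = LLM_DEFAULT_TEMPERATURE,
                        max_tokens = LLM_DEFAULT_MAX_TOKENS,
                        model_id = LLM_DEFAULT_MODEL) {
  dose_strings <- as.character(dose_strings)
  if (anyDuplicated(dose_strings)) {
    dup <- unique(dose_strings[duplicated(dose_strings)])
    stop("duplicate dose string(s) in batch: ",
         paste(shQuote(utils::head(dup, 3)), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    request_id  = sprintf("req-%06d", seq_along(dose_strings)),
    system      = rep(prompt$system_text, length(dose_strings)),
    user        = dose_strings,
    temperature = rep(as.numeric(temperature), length(dose_strings)),
    max_tokens  = rep(as.integer(max_tokens), length(dose_strings)),
    model       = rep(model_id, length(dose_strings))
  )
}

#' Run a request batch against a completion backend
#'
#' Calls the backend once per request. Errors signalled by the backend are
#' retried up to `max_retries` times with bounded exponential backoff;
#' requests still failing afterwards are recorded as failed items (empty
#' text, `status = "failed"`) rather than aborting the batch, so a batch
#' always completes.
#'
#' @param requests Tibble from [build_batch()].
#' @param backend A completion backend function
#'   `function(system_text, user_text, temperature, max_tokens, model_id)`.
#' @param max_retries Maximum retry attempts per request after the first.
#' @param backoff_base Seconds of backoff after the first failure; doubles
#'   per retry. Zero (the default) suits deterministic local backends.
#' @return A tibble with columns `request_id`, `text`, `status`
#'   (`"ok"`/`"failed"`), `error` (message for failed items, `NA`
#'   otherwise), aligned with `requests`.
#' @export
classify_batch <- function(requests, backend, max_retries = 2,
                           backoff_base = 0) {
  stopifnot(is.function(backend))
  n <- nrow(requests)
  text <- character(n)
  status <- rep("ok", n)
  err <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- NULL
    last_err <- NULL
    for (attempt in 0:max_retries) {
      if (attempt > 0 && backoff_base > 0) {
        Sys.sleep(min(backoff_base * 2^(attempt - 1), 30))
      }
      res <- tryCatch(
        backend(requests$system[i], requests$user[i], requests$temperature[i],
                requests$max_tokens[i], requests$model[i]),
        error = function(e) {
          last_err <<- conditionMessage(e)
          NULL
        }
      )
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      status[i] <- "failed"
      err[i] <- last_err %||% "backend returned NULL"
    } else {
      text[i] <- as.character(res)
    }
  }
  tibble::tibble(request_id = requests$request_id, text = text,
                 status = status, error = err)
}

#' Parse a chain-of-thought completion into a structured classification
#'
#' The requested output shape is `<reasoning>|<best>|<next best or "NA">`,
#' but completions may contain newlines and extra prose, and the reasoning
#' itself may contain pipes. Parsing therefore takes the *last two*
#' pipe-separated tokens (trimmed) as the candidate codes and everything
#' before them as reasoning. `"NA"` (case-insensitive) maps to a missing
#' code. Parsing is total — every input maps to one of three statuses:
#'
#' * `"ok"` — best is a valid second-level code (next best valid or absent);
#' * `"na"` — the model declined to classify (best is `NA`);
#' * `"delimiter_error"` — too few fields, empty fields, or an invalid code;
#'   the raw text is preserved for review.
#'
#' @param raw Completion text (single string).
#' @return A list with `reasoning`, `best`, `next_best`, `status`, `raw`.
#' @examples
#' parse_completion("aspirin is antithrombotic at this dose.|B01|NA")
#' @export
parse_completion <- function(raw) {
  raw <- if (is.null(raw) || length(raw) == 0) "" else as.character(raw)[1]
  failed <- function() list(reasoning = NA_character_, best = NA_character_,
                            next_best = NA_character_,
                            status = "delimiter_error", raw = raw)
  if (is.na(raw)) return(failed())

  parts <- strsplit(raw, "|", fixed = TRUE)[[1]]
  if (length(parts) < 3) return(failed())

  k <- length(parts)
  best_txt <- trimws(parts[k - 1])
  next_txt <- trimws(parts[k])
  reasoning <- trimws(paste(parts[seq_len(k - 2)], collapse = "|"))
  if (!nzchar(best_txt) || !nzchar(next_txt)) return(failed())

  as_code <- function(txt) {
    if (toupper(txt) == "NA") return(NA_character_)
    if (!is_level2(txt)) return(NULL)   # invalid code token
    parse_level2(txt)
  }
  best <- as_code(best_txt)
  next_best <- as_code(next_txt)
  if (is.null(best) || is.null(next_best)) return(failed())
  if (is.na(best) && !is.na(next_best)) return(failed())

  status <- if (is.na(best)) "na" else "ok"
  list(reasoning = reasoning, best = best, next_best = next_best,
       status = status, raw = raw)
}

#' Parse a batch of completions
#'
#' @param completions Tibble from [classify_batch()] (columns `request_id`,
#'   `text`, `status`). Transport failures become `status = "failed"` rows.
#' @return A tibble with one row per completion: `request_id`, `reasoning`,
#'   `best`, `next_best`, `status`.
#' @export
parse_completions <- function(completions) {
  rows <- lapply(seq_len(nrow(completions)), function(i) {
    if (!is.na(completions$status[i]) && completions$status[i] == "failed") {
      return(tibble::tibble(request_id = completions$request_id[i],
                            reasoning = NA_character_, best = NA_character_,
                            next_best = NA_character_, status = "failed"))
    }
    p <- parse_completion(completions$text[i])
    tibble::tibble(request_id = completions$request_id[i],
                   reasoning = p$reasoning, best = p$best,
                   next_best = p$next_best, status = p$status)
  })
  dplyr::bind_rows(rows)
}

#' Thin live chat-completion backend
#'
#' Builds a completion backend that posts one chat request per call to an
#' OpenAI-compatible endpoint through the system `curl` binary. The API key
#' is checked at construction time, so a misconfigured live run fails
#' before any request is sent. Not used by any test — the deterministic
#' [mock_completion_backend()] is the testing backend.
#'
#' @param api_key API key; defaults to the `OPENAI_API_KEY` environment
#'   variable.
#' @param base_url API base URL.
#' @return A completion backend function.
#' @export
openai_backend <- function(api_key = Sys.getenv("OPENAI_API_KEY"),
                           base_url = "https://api.openai.com/v1") {
  if (is.null(api_key) || !nzchar(api_key)) {
    stop("configuration error: no API key set (OPENAI_API_KEY)",
         call. = FALSE)
  }
  force(base_url)
  function(system_text, user_text, temperature, max_tokens, model_id) {
    body <- jsonlite::toJSON(list(
      model = model_id,
      temperature = as.numeric(temperature),
      max_tokens = as.integer(max_tokens),
      messages = list(
        list(role = "system", content = system_text),
        list(role = "user", content = user_text)
      )
    ), auto_unbox = TRUE)
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    writeLines(body, tmp)
    out <- suppressWarnings(system2("curl", c(
      "-sS", "-X", "POST", paste0(base_url, "/chat/completions"),
      "-H", shQuote("Content-Type: application/json"),
      "-H", shQuote(paste0("Authorization: Bearer ", api_key)),
      "-d", paste0("@", tmp)
    ), stdout = TRUE, stderr = TRUE))
    parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"),
                                 simplifyVector = FALSE)
    if (!is.null(parsed$error)) {
      stop("backend error: ", parsed$error$message, call. = FALSE)
    }
    parsed$choices[[1]]$message$content
  }
}

#' Write classification requests as JSON Lines
#'
#' One object per line with fields `request_id`, `system`, `user`,
#' `temperature`, `max_tokens`, `model` — a vendor-neutral batch dialect.
#'
#' @param requests Tibble from [build_batch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_requests_jsonl <- function(requests, path) {
  write_jsonl(requests, path)
}

#' @rdname write_requests_jsonl
#' @param completions Tibble from [classify_batch()].
#' @export
write_completions_jsonl <- function(completions, path) {
  write_jsonl(completions, path)
}

#' Read a JSON Lines file into a tibble
#'
#' @param path File path.
#' @return A tibble, one row per line.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    obj[vapply(obj, is.null, logical(1))] <- NA
    tibble::as_tibble(obj)
  })
  dplyr::bind_rows(rows)
}

write_jsonl <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
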