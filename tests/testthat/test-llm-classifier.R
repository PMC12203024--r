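# The worked chain-of-thought outputs for low- and high-dose aspirin: the
# delimited answer fields arrive only after multi-line free-text reasoning.
aspirin_low_completion <- paste0(
  "1 pill of 81mg is 81mg per day. Aspirin at this low dose is typically ",
  "used for its antiplatelet effects to prevent cardiovascular events such ",
  "as heart attacks and strokes. The primary ATC code for antithrombotic ",
  "agents is B01.\n",
  "Reasoning: Aspirin at 81mg is commonly used for cardiovascular ",
  "protection rather than for pain relief or anti-inflammatory purposes, ",
  "which would require higher doses.|B01|NA")

aspirin_high_completion <- paste0(
  "2 pills of 325mg is 650mg per day. Aspirin at this dose is typically ",
  "used for pain relief, anti-inflammatory purposes, and sometimes for ",
  "cardiovascular protection. The primary ATC code for aspirin when used ",
  "for pain and inflammation is N02: \"Analgesics.\" When used for ",
  "cardiovascular protection, the ATC code is B01: \"Antithrombotic ",
  "agents.\" Given the dosage, it is more likely to be used for pain ",
  "relief.\n",
  "Reasoning: 2 pills of 325mg is 650mg per day. Aspirin at this dose is ",
  "typically used for pain relief and anti-inflammatory purposes. The ",
  "primary code N02 refers to \"Analgesics.\"|N02|B01")

test_that("bundled prompts load verbatim and unknown versions fail", {
  revised <- build_prompt("revised")
  expect_equal(revised$name, "revised")
  expect_match(revised$system_text,
               "Reason step by step as demonstrated in the examples",
               fixed = TRUE)
  initial <- build_prompt("initial")
  expect_match(initial$system_text,
               "Return exactly two fields are separated by a pipe",
               fixed = TRUE)
  expect_error(build_prompt("v3"), "unknown prompt version")
})

test_that("batches carry study settings and stable unique ids", {
  reqs <- build_batch("aspirin|1 pill of 81mg")
  expect_equal(nrow(reqs), 1)
  expect_equal(reqs$temperature, 0)
  expect_equal(reqs$max_tokens, 1000L)
  expect_equal(reqs$model, "gpt-4o-2024-05-13")

  expect_equal(nrow(build_batch(character())), 0)

  many <- build_batch(paste0("drug", 1:200, "|1 pill of 1 MG"))
  expect_equal(nrow(many), 200)
  expect_equal(anyDuplicated(many$request_id), 0)
  expect_equal(many, build_batch(paste0("drug", 1:200, "|1 pill of 1 MG")))

  expect_error(build_batch(c("a|1 pill of UNK", "a|1 pill of UNK")),
               "duplicate dose string")
})

test_that("a batch always completes: failures become failed items", {
  flaky_calls <- new.env()
  flaky_calls$n <- 0
  backend <- function(system_text, user_text, temperature, max_tokens, model_id) {
    if (user_text == "bad|1 pill of UNK") stop("permanent transport failure")
    if (user_text == "flaky|1 pill of UNK") {
      flaky_calls$n <- flaky_calls$n + 1
      if (flaky_calls$n == 1) stop("transient timeout")
    }
    "fine.|A10|NA"
  }
  reqs <- build_batch(c("good|1 pill of UNK", "bad|1 pill of UNK",
                        "flaky|1 pill of UNK"))
  out <- classify_batch(reqs, backend)
  expect_equal(out$status, c("ok", "failed", "ok"))
  expect_equal(out$request_id, reqs$request_id)
  expect_match(out$error[2], "permanent transport failure")
  expect_equal(out$text[3], "fine.|A10|NA")
})

test_that("the mock pipeline is bit-reproducible across runs", {
  doses <- c("aspirin|1 pill of 81mg", "metformin|2 pills of 500MG",
             "xyz-1234|1 pill of 1 g")
  backend <- mock_completion_backend(default_formulary(),
                                     mock_config(delimiter_error_rate = 0.3,
                                                 seed = 5))
  run1 <- classify_batch(build_batch(doses), backend)
  run2 <- classify_batch(build_batch(doses), backend)
  expect_identical(run1, run2)
  # order independence: per-input draws keyed by input, not call order
  run3 <- classify_batch(build_batch(rev(doses)), backend)
  expect_identical(sort(run1$text), sort(run3$text))
})

test_that("multi-line reasoning parses into codes via the last two fields", {
  low <- parse_completion(aspirin_low_completion)
  expect_equal(low$status, "ok")
  expect_equal(low$best, "B01")
  expect_true(is.na(low$next_best))
  expect_match(low$reasoning, "antiplatelet effects to prevent cardiovascular events")

  high <- parse_completion(aspirin_high_completion)
  expect_equal(high$status, "ok")
  expect_equal(high$best, "N02")
  expect_equal(high$next_best, "B01")
  expect_match(high$reasoning, "more likely to be used for pain relief")
  # reasoning itself contained pipes-free prose but quoted colons survive
  expect_match(high$reasoning, "Analgesics")
})

test_that("parsing is total and partitions outcomes exhaustively", {
  expect_equal(parse_completion("some text with no pipes")$status,
               "delimiter_error")
  na_out <- parse_completion(
    "XYZ-1234 is not an oral solid drug I am familiar with.|NA|NA")
  expect_equal(na_out$status, "na")
  expect_true(is.na(na_out$best) && is.na(na_out$next_best))

  expect_equal(parse_completion("reasoning|B01|")$status, "delimiter_error")
  expect_equal(parse_completion("reasoning|XYZ|NA")$status, "delimiter_error")
  expect_equal(parse_completion("reasoning|NA|B01")$status, "delimiter_error")
  expect_equal(parse_completion("a|b")$status, "delimiter_error")
  expect_equal(parse_completion("")$status, "delimiter_error")
  expect_equal(parse_completion(NA_character_)$status, "delimiter_error")
  # case-insensitive NA, whitespace-tolerant fields
  mixed <- parse_completion("thinking...| b01 | na ")
  expect_equal(mixed$status, "ok")
  expect_equal(mixed$best, "B01")
  # delimiter errors always preserve the raw text
  raw <- "model never stopped reasoning"
  expect_equal(parse_completion(raw)$raw, raw)
})

test_that("canonical mock completions round-trip with the formulary truth", {
  formulary <- default_formulary()
  backend <- mock_completion_backend(formulary, mock_config())
  doses <- synthesize_population(150, formulary, seed = 21)
  for (d in doses) {
    parsed <- parse_completion(backend(NULL, d, 0, 1000, "mock"))
    truth <- formulary_truth(formulary, d)
    expect_true(parsed$status %in% c("ok", "na"))
    if (is.na(truth$best)) {
      expect_equal(parsed$status, "na")
    } else {
      expect_equal(parsed$best, truth$best)
      expect_equal(is.na(parsed$next_best), is.na(truth$next_best))
      if (!is.na(truth$next_best)) expect_equal(parsed$next_best, truth$next_best)
    }
  }
})

test_that("request and completion JSON Lines round-trip", {
  reqs <- build_batch(c("aspirin|1 pill of 81mg", "metformin|2 pills of 500MG"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_requests_jsonl(reqs, path)
  expect_equal(as.data.frame(read_jsonl(path)), as.data.frame(reqs))

  backend <- mock_completion_backend(default_formulary(), mock_config())
  comps <- classify_batch(reqs, backend)
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_completions_jsonl(comps, path2)
  back <- read_jsonl(path2)
  expect_equal(back$text, comps$text)
  expect_equal(back$status, comps$status)
})

test_that("a live backend without credentials fails at configuration time", {
  withr::local_envvar(OPENAI_API_KEY = "")
  expect_error(openai_backend(), "configuration error")
})
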