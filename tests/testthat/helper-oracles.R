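# Independent oracles used by property-style tests. Each is a deliberately
# naive re-derivation (loops, sliding windows, direct enumeration) kept
# separate from the implementation paths it checks.

# Brute-force group-and-sum over (patient, date, lowercased drug, strength).
oracle_group_sum <- function(records) {
  key <- paste(records$patient_id, records$dispense_date,
               tolower(trimws(records$drug_name)),
               ifelse(is.na(records$strength) | !nzchar(trimws(records$strength)),
                      "UNK", records$strength),
               sep = "\r")
  totals <- new.env()
  for (i in seq_len(nrow(records))) {
    k <- key[i]
    totals[[k]] <- (if (is.null(totals[[k]])) 0 else totals[[k]]) +
      records$quantity[i]
  }
  out <- sapply(ls(totals), function(k) totals[[k]])
  names(out) <- ls(totals)
  out
}

# Naive frequency count and argmax, loop-based.
oracle_majority <- function(codes) {
  if (length(codes) == 0) {
    return(list(winners = character(),
                tally = stats::setNames(integer(), character())))
  }
  uniq <- unique(codes)
  counts <- vapply(uniq, function(u) sum(codes == u), integer(1))
  names(counts) <- uniq
  winners <- sort(uniq[counts == max(counts)])
  list(winners = winners, tally = counts)
}

# Character-by-character sliding-window matcher for the full ATC code shape,
# leftmost non-overlapping, truncating matches to 3 characters.
oracle_sliding_codes <- function(text) {
  chars <- strsplit(text, "")[[1]]
  is_up <- function(c) c %in% LETTERS
  is_dig <- function(c) c %in% as.character(0:9)
  out <- character()
  i <- 1
  while (i + 6 <= length(chars)) {
    w <- chars[i:(i + 6)]
    if (is_up(w[1]) && is_dig(w[2]) && is_dig(w[3]) &&
        is_up(w[4]) && is_up(w[5]) && is_dig(w[6]) && is_dig(w[7])) {
      out <- c(out, paste(w[1:3], collapse = ""))
      i <- i + 7
    } else {
      i <- i + 1
    }
  }
  out
}

# Random dispense records exercising case variants, fractions and missing
# strengths; assumes the caller controls the RNG seed.
random_records <- function(n) {
  drugs <- c("Apo-Rosuvastatin", "pms-quetiapine", "Metformin", "ASPIRIN",
             "sandoz irbesartan")
  strengths <- c("25 mg", "200 mg", "500MG", "25/100 MG", "0", NA)
  tibble::tibble(
    patient_id = sample(sprintf("P%02d", 1:6), n, replace = TRUE),
    dispense_date = sample(c("2024-01-01", "2024-01-02", "2024-02-10"), n,
                           replace = TRUE),
    drug_name = sample(drugs, n, replace = TRUE),
    strength = sample(strengths, n, replace = TRUE),
    quantity = sample(c(0.5, 1, 1.5, 2, 3), n, replace = TRUE)
  )
}
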