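#' Grading and finite-population inference
#'
#' Classifier outputs are graded by humans: the LLM arm on a 3-point scale
#' (1 flawless; 2 more correct than incorrect; 3 more incorrect than
#' correct), the search arm as acceptable / not acceptable. Inference
#' targets the *finite population* of N distinct daily dose strings in the
#' source database — the estimand is the proportion p of at least mostly
#' correct grades (grade 1 or 2) among all N strings, not a parameter of
#' some superpopulation. Sampling is without replacement, so the standard
#' error carries the finite population correction (N - n) / N:
#'
#' \deqn{\hat p \pm z_{1-\alpha/2}
#'       \sqrt{\frac{N-n}{N}\,\frac{\hat p (1-\hat p)}{n}}}
#'
#' The same half-width formula, inverted, plans the sample size.
#'
#' @name evaluation
NULL

#' Sample items without replacement, reproducibly
#'
#' Uniform without-replacement sampling from a finite frame, with an
#' optional exclusion set (e.g. pilot items must not re-enter the
#' inference sample). Deterministic given `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param members Character vector: the population frame.
#' @param n Sample size.
#' @param seed Integer seed.
#' @param exclude Character vector of members to exclude before sampling.
#' @return Character vector of `n` distinct sampled members.
#' @export
sample_without_replacement <- function(members, n, seed, exclude = character()) {
  pool <- setdiff(members, exclude)
  if (n > length(pool)) {
    stop("sampling error: n = ", n, " exceeds available frame size ",
         length(pool), call. = FALSE)
  }
  with_local_seed(seed, sample(pool, size = n, replace = FALSE))
}

# Run code under a temporary RNG seed, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Proportion of at least mostly correct grades
#'
#' @param grades Integer vector of grades in \{1, 2, 3\}.
#' @return Proportion of grades that are 1 or 2.
#' @export
proportion_mostly_correct <- function(grades) {
  grades <- as.integer(grades)
  if (length(grades) == 0) stop("no grades supplied", call. = FALSE)
  if (any(is.na(grades) | !grades %in% 1:3)) {
    stop("grades must be 1, 2 or 3", call. = FALSE)
  }
  mean(grades <= 2)
}

#' Finite-population confidence interval for a proportion
#'
#' Point estimate `successes / n` with normal-approximation interval whose
#' standard error is shrunk by the finite population correction
#' `(N - n) / N`; at a census (n = N) the half-width is exactly zero.
#' Bounds are clamped to \[0, 1\]. The z quantile is computed from the
#' standard-normal inverse CDF, two-sided: `qnorm(1 - (1 - confidence)/2)`.
#'
#' @param successes Number of successes in the sample.
#' @param n Sample size.
#' @param N Population size (number of distinct daily dose strings).
#' @param confidence Confidence level in (0, 1), e.g. `0.80`.
#' @return A list of class `proportion_estimate`: `p_hat`, `ci_low`,
#'   `ci_high`, `half_width`, `confidence`, `n`, `N`.
#' @examples
#' finite_population_ci(185, 200, 12294, 0.80)
#' @export
finite_population_ci <- function(successes, n, N, confidence = 0.80) {
  if (successes < 0 || successes > n) {
    stop("need 0 <= successes <= n", call. = FALSE)
  }
  if (n > N) stop("need n <= N", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  p_hat <- successes / n
  hw <- fpc_half_width(p_hat, n, N, confidence)
  out <- list(p_hat = p_hat,
              ci_low = max(0, p_hat - hw),
              ci_high = min(1, p_hat + hw),
              half_width = hw,
              confidence = confidence, n = n, N = N)
  class(out) <- "proportion_estimate"
  out
}

# Normal-approximation half-width with FPC factor (N - n) / N.
fpc_half_width <- function(p, n, N, confidence) {
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  z * sqrt(((N - n) / N) * p * (1 - p) / n)
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("proportion estimate: %s (%d/%d, %g%% CI %s-%s), N = %d\n",
              format_percent(x$p_hat), round(x$p_hat * x$n), x$n,
              100 * x$confidence,
              format_percent(x$ci_low), format_percent(x$ci_high), x$N))
  invisible(x)
}

#' Format a proportion as a percentage string
#'
#' Rounds half away from zero to one decimal (the usual reporting style),
#' e.g. `0.925` becomes `"92.5%"`.
#'
#' @param p Proportion in \[0, 1\].
#' @param digits Decimal places.
#' @return Character vector like `"92.5%"`.
#' @export
format_percent <- function(p, digits = 1) {
  scaled <- p * 100 * 10^digits
  rounded <- sign(scaled) * floor(abs(scaled) + 0.5)  # half away from zero
  paste0(formatC(rounded / 10^digits, format = "f", digits = digits), "%")
}

#' Minimal sample size meeting a CI margin
#'
#' Smallest n (at most N) whose finite-population half-width at the
#' planning proportion is no larger than `margin`. Found by inverting the
#' half-width formula, then verified by direct evaluation at the candidate
#' and its neighbour (so the returned n is the exact integer minimum).
#'
#' @param margin Target half-width, e.g. `0.02`.
#' @param p_planning Planning proportion in (0, 1), e.g. `0.95`.
#' @param confidence Confidence level in (0, 1).
#' @param N Population size.
#' @return Integer sample size.
#' @examples
#' required_sample_size(0.02, 0.95, 0.80, 12294)
#' @export
required_sample_size <- function(margin, p_planning, confidence, N) {
  if (margin <= 0) stop("margin must be > 0", call. = FALSE)
  if (p_planning <= 0 || p_planning >= 1) {
    stop("p_planning must be in (0, 1)", call. = FALSE)
  }
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  pq <- p_planning * (1 - p_planning)
  # Algebraic inversion of margin = z * sqrt(((N-n)/N) * pq / n):
  n0 <- (z^2 * pq) / (margin^2 + z^2 * pq / N)
  n <- max(1L, min(as.integer(N), as.integer(ceiling(n0 - 1e-9))))
  # Integer verification: walk to the exact boundary.
  while (n < N && fpc_half_width(p_planning, n, N, confidence) > margin) {
    n <- n + 1L
  }
  while (n > 1 && fpc_half_width(p_planning, n - 1L, N, confidence) <= margin) {
    n <- n - 1L
  }
  n
}

#' Cross-tabulate LLM grades against search acceptability
#'
#' Joins the two grading arms on item and counts the 3 x 2 table
#' (LLM grade 1/2/3 by search acceptable / not acceptable) with margins.
#'
#' @param llm Data frame with columns `item`, `grade` (1/2/3).
#' @param search Data frame with columns `item`, `acceptable` (logical).
#' @return A list of class `grade_crosstab`: `counts` (3 x 2 integer
#'   matrix), `row_margins`, `col_margins`, `total`.
#' @export
cross_tabulate <- function(llm, search) {
  only_llm <- setdiff(llm$item, search$item)
  only_search <- setdiff(search$item, llm$item)
  if (length(only_llm) > 0 || length(only_search) > 0) {
    stop("join error: unmatched item(s): ",
         paste(shQuote(utils::head(c(only_llm, only_search), 5)),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(llm$item) || anyDuplicated(search$item)) {
    stop("join error: duplicate item(s)", call. = FALSE)
  }
  merged <- dplyr::inner_join(llm, search, by = "item")
  grade <- factor(merged$grade, levels = 1:3)
  acceptable <- factor(ifelse(merged$acceptable, "acceptable", "not_acceptable"),
                       levels = c("acceptable", "not_acceptable"))
  counts <- table(grade, acceptable)
  counts <- matrix(as.integer(counts), nrow = 3, ncol = 2,
                   dimnames = list(grade = c("1", "2", "3"),
                                   search = c("acceptable", "not_acceptable")))
  out <- list(counts = counts,
              row_margins = rowSums(counts),
              col_margins = colSums(counts),
              total = sum(counts))
  class(out) <- "grade_crosstab"
  out
}

#' @export
print.grade_crosstab <- function(x, ...) {
  m <- cbind(x$counts, margin = x$row_margins)
  m <- rbind(m, margin = c(x$col_margins, x$total))
  print(m)
  invisible(x)
}

#' Write a cross-tabulation as CSV
#'
#' Layout mirrors the usual published form: one row per LLM grade, columns
#' for acceptable / not acceptable, margins included.
#'
#' @param crosstab A `grade_crosstab` from [cross_tabulate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosstab_csv <- function(crosstab, path) {
  df <- data.frame(
    llm_grade = c("1", "2", "3", "margin"),
    acceptable = c(crosstab$counts[, 1], crosstab$col_margins[1]),
    not_acceptable = c(crosstab$counts[, 2], crosstab$col_margins[2]),
    margin = c(crosstab$row_margins, crosstab$total)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Grade a search classification given per-code acceptability
#'
#' The search arm output is acceptable iff at least one code was found and
#' *every* winning code is acceptable — a tie involving one inappropriate
#' code fails, a tie between two appropriate codes passes.
#'
#' @param classification A `search_classification` from [majority_vote()]
#'   or [classify_by_search()].
#' @param acceptability Named logical vector (or list) mapping second-level
#'   codes to acceptability; must cover every winner.
#' @return Logical: acceptable or not.
#' @export
grade_search_output <- function(classification, acceptability) {
  winners <- classification$winners
  if (length(winners) == 0) return(FALSE)
  acceptability <- unlist(acceptability)
  missing_codes <- setdiff(winners, names(acceptability))
  if (length(missing_codes) > 0) {
    stop("no acceptability entry for code(s): ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  }
  all(as.logical(acceptability[winners]))
}

#' Read grade CSV files
#'
#' LLM arm: `item,grade` with grades 1/2/3. Search arm: `item,acceptable`
#' with logical (TRUE/FALSE or 0/1) acceptability.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_llm_grades_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(item = "character"))
  stopifnot(all(c("item", "grade") %in% names(df)))
  df$grade <- as.integer(df$grade)
  tibble::as_tibble(df)
}

#' @rdname read_llm_grades_csv
#' @export
read_search_grades_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(item = "character"))
  stopifnot(all(c("item", "acceptable") %in% names(df)))
  df$acceptable <- as.logical(df$acceptable)
  tibble::as_tibble(df)
}

#' JSON accuracy report
#'
#' Serializes a `proportion_estimate` (plus grade counts when supplied) to
#' a JSON file.
#'
#' @param estimate A `proportion_estimate`.
#' @param path Output path.
#' @param grade_counts Optional named counts (grades 1/2/3).
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(estimate, path, grade_counts = NULL) {
  payload <- list(
    p_hat = estimate$p_hat, ci_low = estimate$ci_low,
    ci_high = estimate$ci_high, confidence = estimate$confidence,
    n = estimate$n, N = estimate$N
  )
  if (!is.null(grade_counts)) payload$grade_counts <- as.list(grade_counts)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
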