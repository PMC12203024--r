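test_that("without-replacement sampling is deterministic and respects exclusions", {
  members <- sprintf("item%05d", 1:1000)
  pilot <- sample_without_replacement(members, 20, seed = 7)
  s1 <- sample_without_replacement(members, 200, seed = 11, exclude = pilot)
  s2 <- sample_without_replacement(members, 200, seed = 11, exclude = pilot)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 200)
  expect_length(intersect(s1, pilot), 0)

  census <- sample_without_replacement(members, 1000, seed = 1)
  expect_setequal(census, members)

  expect_error(sample_without_replacement(members, 990, seed = 1,
                                          exclude = pilot),
               "sampling error")
})

test_that("sampling leaves the caller's RNG stream untouched", {
  set.seed(123)
  a <- stats::runif(1)
  set.seed(123)
  invisible(sample_without_replacement(letters, 5, seed = 99))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("mostly-correct proportion counts grades of 1 or 2", {
  grades <- c(rep(1L, 175), rep(2L, 10), rep(3L, 15))
  expect_equal(proportion_mostly_correct(grades), 0.925)
  expect_equal(proportion_mostly_correct(rep(1L, 7)), 1)
  expect_equal(proportion_mostly_correct(rep(3L, 10)), 0)
  expect_error(proportion_mostly_correct(integer()), "no grades")
  expect_error(proportion_mostly_correct(c(1L, 4L)), "must be 1, 2 or 3")
})

test_that("the finite-population CI matches hand-derived values", {
  # half-width = z * sqrt(((N-n)/N) * p(1-p)/n), z = qnorm(0.9) for 80%
  est <- finite_population_ci(50, 100, 10000, 0.80)
  z <- stats::qnorm(0.9)
  expect_equal(est$half_width, z * sqrt((9900 / 10000) * 0.25 / 100),
               tolerance = 1e-12)
  expect_equal(round(est$half_width, 4), 0.0638)

  census <- finite_population_ci(37, 37, 37, 0.95)
  expect_equal(census$half_width, 0)
  expect_equal(census$ci_low, 1)
  expect_equal(census$ci_high, 1)

  degenerate <- finite_population_ci(0, 10, 100, 0.80)
  expect_equal(degenerate$ci_low, 0)
  expect_error(finite_population_ci(11, 10, 100, 0.8), "successes")
  expect_error(finite_population_ci(5, 10, 9, 0.8), "n <= N")
  expect_error(finite_population_ci(5, 10, 100, 1), "confidence")
})

test_that("CI width shrinks in n and approaches the infinite-population CI", {
  widths <- vapply(c(50, 100, 200, 400, 800, 1600),
                   function(n) fpc_half_width(0.925, n, 12294, 0.80),
                   numeric(1))
  expect_true(all(diff(widths) < 0))

  big_n <- finite_population_ci(925, 1000, 1e12, 0.80)
  z <- stats::qnorm(0.9)
  infinite <- z * sqrt(0.925 * 0.075 / 1000)
  expect_equal(big_n$half_width, infinite, tolerance = 1e-6)
})

test_that("planned sample sizes are exact integer minima", {
  expect_equal(required_sample_size(0.02, 0.95, 0.80, 12294), 192L)
  expect_equal(required_sample_size(1, 0.5, 0.80, 1000), 1L)
  expect_equal(required_sample_size(1e-9, 0.5, 0.80, 10), 10L)

  set.seed(31)
  for (i in 1:50) {
    N <- sample(50:20000, 1)
    p <- stats::runif(1, 0.05, 0.95)
    conf <- sample(c(0.8, 0.9, 0.95), 1)
    margin <- stats::runif(1, 0.005, 0.2)
    n <- required_sample_size(margin, p, conf, N)
    expect_lte(fpc_half_width(p, n, N, conf), margin)
    if (n > 1) expect_gt(fpc_half_width(p, n - 1, N, conf), margin)
  }
})

test_that("percentages round half away from zero to one decimal", {
  expect_equal(format_percent(0.925), "92.5%")
  expect_equal(format_percent(0.90125), "90.1%")
  expect_equal(format_percent(0.82345), "82.3%")
  expect_equal(format_percent(0.0005), "0.1%")
})

test_that("cross-tabulation reconstructs margins from paired grades", {
  # paired records synthesized from published-style cell counts
  cells <- data.frame(grade = c(1, 1, 2, 2, 3, 3),
                      acceptable = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                      count = c(148, 27, 8, 2, 9, 6))
  items <- unlist(lapply(seq_len(nrow(cells)), function(i) {
    sprintf("g%d_a%d_%03d", cells$grade[i], cells$acceptable[i],
            seq_len(cells$count[i]))
  }))
  llm <- data.frame(item = items, grade = rep(cells$grade, cells$count))
  search <- data.frame(item = items,
                       acceptable = rep(cells$acceptable, cells$count))
  tab <- cross_tabulate(llm, search)
  expect_equal(unname(tab$row_margins), c(175, 10, 15))
  expect_equal(unname(tab$col_margins), c(165, 35))
  expect_equal(tab$total, 200)
  expect_equal(tab$counts["1", "acceptable"], 148L)
  expect_equal(sum(tab$counts), tab$total)
  expect_equal(unname(rowSums(tab$counts)), unname(tab$row_margins))
  expect_equal(unname(colSums(tab$counts)), unname(tab$col_margins))

  empty <- cross_tabulate(data.frame(item = character(), grade = integer()),
                          data.frame(item = character(), acceptable = logical()))
  expect_equal(empty$total, 0)
  expect_true(all(empty$counts == 0))

  one <- cross_tabulate(data.frame(item = "x", grade = 2),
                        data.frame(item = "x", acceptable = FALSE))
  expect_equal(one$counts["2", "not_acceptable"], 1L)
  expect_equal(sum(one$counts), 1)

  expect_error(cross_tabulate(data.frame(item = c("a", "b"), grade = c(1, 1)),
                              data.frame(item = "a", acceptable = TRUE)),
               "unmatched item")
})

test_that("search outputs grade acceptable only when every winner is", {
  both_ok <- majority_vote(c("C02", "G04"))
  expect_true(grade_search_output(both_ok, c(C02 = TRUE, G04 = TRUE)))
  one_bad <- majority_vote(c("B01", "X99"))
  expect_false(grade_search_output(one_bad, c(B01 = TRUE, X99 = FALSE)))
  expect_false(grade_search_output(majority_vote(character()),
                                   c(B01 = TRUE)))
  expect_error(grade_search_output(both_ok, c(C02 = TRUE)),
               "no acceptability entry")
})

test_that("grade files and reports round-trip through disk", {
  llm_csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(item = c("a|1 pill of UNK", "b|2 pills of 5 MG"),
                       grade = c(1, 3)), llm_csv, row.names = FALSE)
  llm <- read_llm_grades_csv(llm_csv)
  expect_equal(llm$grade, c(1L, 3L))

  search_csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(item = c("a|1 pill of UNK", "b|2 pills of 5 MG"),
                       acceptable = c(TRUE, FALSE)), search_csv,
            row.names = FALSE)
  search <- read_search_grades_csv(search_csv)
  expect_equal(search$acceptable, c(TRUE, FALSE))

  est <- finite_population_ci(185, 200, 12294, 0.80)
  json <- withr::local_tempfile(fileext = ".json")
  write_estimate_json(est, json, grade_counts = c(`1` = 175, `2` = 10, `3` = 15))
  back <- jsonlite::fromJSON(json)
  expect_equal(back$p_hat, 0.925)
  expect_equal(back$N, 12294)
  expect_equal(back$grade_counts$`1`, 175)

  tab <- cross_tabulate(data.frame(item = "x", grade = 2),
                        data.frame(item = "x", acceptable = FALSE))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_crosstab_csv(tab, csv)
  df <- read.csv(csv)
  expect_equal(df$margin[4], 1)
})
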