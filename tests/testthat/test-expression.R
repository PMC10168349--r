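test_that("cell classification follows the one-or-more-puncta positivity rule", {
  cells <- tibble::tibble(
    tdtomato_positive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    glun2c_puncta = c(0L, 1L, 0L, 2L, 5L),
    glun2d_puncta = c(3L, 1L, 0L, 0L, 5L)
  )
  cl <- classify_cells(cells)
  expect_identical(cl$class, c("only2d", "both", "neither", "only2c", NA))
  expect_error(classify_cells(transform(cells, glun2c_puncta = -1)),
               class = "nmdagain_invalid_input")
})

test_that("grand-total fixture reproduces the published overall percentages", {
  tbl <- marker_table_from_counts(
    data.frame(n_tdt = 521, n_2d = 476, n_2c = 42, n_both = 37))
  s <- summarize_expression(tbl)
  expect_identical(s$n_tdt, 521L)
  expect_equal(s$pct_2d, 91.4)
  expect_equal(s$pct_2c, 8.1)
  expect_equal(s$pct_both, 7.1)
  expect_equal(s$pct_only2d, 84.3)
  expect_equal(s$pct_only2c, 1.0)
  expect_equal(s$pct_neither, 7.7)
})

test_that("per-mouse and per-subdivision summaries reproduce the published tables", {
  per_mouse <- summarize_expression(
    marker_table_from_counts(glun2_slice_counts()), by = "mouse")
  m1 <- per_mouse[per_mouse$mouse == "mouse1", ]
  expect_identical(unlist(m1[c("n_tdt", "n_2d", "n_2c", "n_both")],
                          use.names = FALSE), c(149L, 139L, 9L, 9L))
  expect_equal(m1$pct_2d, 93.3)
  expect_equal(per_mouse$pct_2d[per_mouse$mouse == "mouse2"], 94.7)
  expect_equal(per_mouse$pct_2d[per_mouse$mouse == "mouse3"], 88.8)
  expect_equal(per_mouse$pct_2c, c(6.0, 13.3, 6.9))
  expect_equal(per_mouse$pct_both, c(6.0, 12.4, 5.4))

  per_sub <- summarize_expression(
    marker_table_from_counts(glun2_subdivision_counts()), by = "subdivision")
  cn <- per_sub[per_sub$subdivision == "central_nucleus", ]
  expect_identical(unlist(cn[c("n_tdt", "n_2d", "n_2c", "n_both")],
                          use.names = FALSE), c(356L, 326L, 31L, 28L))
  expect_equal(cn$pct_2d, 91.6)
  expect_equal(cn$pct_only2d, 83.7)
  expect_equal(per_sub$pct_2d[per_sub$subdivision == "dorsal_cortex"], 91.2)
  expect_equal(per_sub$pct_2d[per_sub$subdivision == "lateral_cortex"], 90.4)

  # the two fixture tables carry the same grand total
  overall <- summarize_expression(marker_table_from_counts(glun2_slice_counts()))
  expect_identical(unlist(overall[c("n_tdt", "n_2d", "n_2c", "n_both")],
                          use.names = FALSE), c(521L, 476L, 42L, 37L))
})

test_that("the exclusive classes always partition the tdTomato-positive cells", {
  checks <- list(
    summarize_expression(marker_table_from_counts(glun2_slice_counts()),
                         by = "mouse"),
    summarize_expression(marker_table_from_counts(glun2_subdivision_counts()),
                         by = c("subdivision", "mouse")),
    summarize_expression(gen_marker_table(400, seed = 2))
  )
  for (s in checks) {
    expect_identical(s$n_only2d + s$n_only2c + s$n_both + s$n_neither, s$n_tdt)
  }
})

test_that("count reconstruction round-trips through summarisation for random consistent marginals", {
  withr::with_seed(19, {
    for (i in 1:100) {
      n_tdt <- sample(5:200, 1)
      n_2d <- sample(0:n_tdt, 1)
      n_2c <- sample(0:n_tdt, 1)
      both_max <- min(n_2d, n_2c)
      both_min <- max(0, n_2d + n_2c - n_tdt)
      n_both <- both_min + sample.int(both_max - both_min + 1, 1) - 1
      cnt <- data.frame(n_tdt = n_tdt, n_2d = n_2d, n_2c = n_2c,
                        n_both = n_both)
      s <- summarize_expression(marker_table_from_counts(cnt))
      expect_identical(unlist(s[c("n_tdt", "n_2d", "n_2c", "n_both")],
                              use.names = FALSE),
                       as.integer(c(n_tdt, n_2d, n_2c, n_both)))
    }
  })
})

test_that("degenerate inputs are handled: single cell, empty groups, inconsistent marginals", {
  single <- marker_table_from_counts(
    data.frame(n_tdt = 1, n_2d = 1, n_2c = 0, n_both = 0))
  s <- summarize_expression(single)
  expect_equal(s$pct_only2d, 100.0)

  empty <- summarize_expression(gen_marker_table(0, seed = 1))
  expect_identical(empty$n_tdt, 0L)
  expect_true(is.na(empty$pct_2d)) # undefined, not 0 or NaN

  expect_error(marker_table_from_counts(
    data.frame(n_tdt = 10, n_2d = 8, n_2c = 5, n_both = 1)),
    class = "nmdagain_invalid_input") # 8 + 5 - 1 > 10
  expect_error(marker_table_from_counts(
    data.frame(n_tdt = 10, n_2d = 2, n_2c = 5, n_both = 4)),
    class = "nmdagain_invalid_input") # both > min(2d, 2c)
})

test_that("percentage rounding is half-away-from-zero at one decimal", {
  # 139/149 = 93.2886 -> 93.3 ; 476/521 = 91.3628 -> 91.4 ; and the
  # half-way case that distinguishes the rule from round-half-even
  tbl <- marker_table_from_counts(
    data.frame(n_tdt = 400, n_2d = 377, n_2c = 0, n_both = 0))
  expect_equal(summarize_expression(tbl)$pct_2d, 94.3) # 94.25 rounds up
})
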