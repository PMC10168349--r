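#' Classify marker expression of tdTomato-positive cells
#'
#' A cell is positive for a channel when one or more fluorescent puncta
#' co-localise with its tdTomato signal (puncta count >= 1). The four
#' resulting classes partition the tdTomato-positive population:
#' `only2d`, `only2c`, `both`, `neither`. tdTomato-negative rows get
#' class `NA` (they are retained but never enter denominators).
#'
#' @param cells A data frame with (at least) columns
#'   `tdtomato_positive` (logical), `glun2c_puncta`, `glun2d_puncta`
#'   (non-negative integer counts).
#' @return The input as a tibble with an added `class` column.
#' @export
#' @examples
#' classify_cells(tibble::tibble(tdtomato_positive = TRUE,
#'                               glun2c_puncta = 0, glun2d_puncta = 3))
classify_cells <- function(cells) {
  need <- c("tdtomato_positive", "glun2c_puncta", "glun2d_puncta")
  if (!all(need %in% names(cells)))
    stop_bad_input("cells needs columns %s", paste(need, collapse = ", "))
  if (any(cells$glun2c_puncta < 0, na.rm = TRUE) ||
      any(cells$glun2d_puncta < 0, na.rm = TRUE))
    stop_bad_input("puncta counts must be non-negative")
  dplyr::mutate(
    tibble::as_tibble(cells),
    class = dplyr::case_when(
      !.data$tdtomato_positive ~ NA_character_,
      .data$glun2c_puncta >= 1 & .data$glun2d_puncta >= 1 ~ "both",
      .data$glun2d_puncta >= 1 ~ "only2d",
      .data$glun2c_puncta >= 1 ~ "only2c",
      TRUE ~ "neither"
    )
  )
}

#' Summarise marker co-expression
#'
#' Tabulates, per group, the tdTomato-positive cell count and the
#' counts/percentages positive for each marker: Glun2d-positive,
#' Glun2c-positive, double-positive, and the exclusive classes. The
#' exclusive classes partition the tdTomato-positive cells exactly
#' (`n_only2d + n_only2c + n_both + n_neither == n_tdt`). Percentages are
#' 100 * count / n_tdt rounded half-away-from-zero to one decimal, and
#' are `NA` for groups with no tdTomato-positive cells.
#'
#' @param cells A per-cell data frame as in [classify_cells()], with any
#'   grouping columns (e.g. `mouse`, `subdivision`).
#' @param by Character vector of grouping column names, or `"overall"`
#'   (default) for a single grand-total row.
#' @return A tibble with one row per group: the grouping columns plus
#'   `n_tdt`, `n_2d`, `n_2c`, `n_both`, `n_only2d`, `n_only2c`,
#'   `n_neither`, and `pct_2d`, `pct_2c`, `pct_both`, `pct_only2d`,
#'   `pct_only2c`, `pct_neither`.
#' @export
#' @examples
#' tbl <- marker_table_from_counts(
#'   data.frame(n_tdt = 521, n_2d = 476, n_2c = 42, n_both = 37))
#' summarize_expression(tbl)
summarize_expression <- function(cells, by = "overall") {
  if (nrow(cells) == 0 && identical(by, "overall")) {
    cells <- tibble::tibble(tdtomato_positive = logical(),
                            glun2c_puncta = integer(),
                            glun2d_puncta = integer())
  }
  cl <- classify_cells(cells)
  grouped <- if (identical(by, "overall")) {
    dplyr::group_by(cl)
  } else {
    if (!all(by %in% names(cl)))
      stop_bad_input("grouping columns missing: %s",
                     paste(setdiff(by, names(cl)), collapse = ", "))
    dplyr::group_by(cl, dplyr::across(dplyr::all_of(by)))
  }
  out <- dplyr::summarise(
    grouped,
    n_tdt = sum(.data$tdtomato_positive),
    n_2d = sum(.data$class %in% c("only2d", "both")),
    n_2c = sum(.data$class %in% c("only2c", "both")),
    n_both = sum(.data$class %in% "both"),
    n_only2d = sum(.data$class %in% "only2d"),
    n_only2c = sum(.data$class %in% "only2c"),
    n_neither = sum(.data$class %in% "neither"),
    .groups = "drop"
  )
  if (identical(by, "overall") && nrow(out) == 0) {
    out <- tibble::tibble(n_tdt = 0L, n_2d = 0L, n_2c = 0L, n_both = 0L,
                          n_only2d = 0L, n_only2c = 0L, n_neither = 0L)
  }
  pct <- function(n, d) ifelse(d > 0, round_half_up(100 * n / d, 1), NA_real_)
  dplyr::mutate(
    out,
    pct_2d = pct(.data$n_2d, .data$n_tdt),
    pct_2c = pct(.data$n_2c, .data$n_tdt),
    pct_both = pct(.data$n_both, .data$n_tdt),
    pct_only2d = pct(.data$n_only2d, .data$n_tdt),
    pct_only2c = pct(.data$n_only2c, .data$n_tdt),
    pct_neither = pct(.data$n_neither, .data$n_tdt)
  )
}

#' Reconstruct a per-cell table from marginal counts
#'
#' Builds a minimal per-cell marker table consistent with printed group
#' marginals (tdTomato+, Glun2d+, Glun2c+ and double-positive counts),
#' one row of `counts` per group. Any additional columns of `counts`
#' (e.g. `mouse`, `slice`, `subdivision`) are carried onto the cells of
#' that group. [summarize_expression()] applied to the result reproduces
#' the input counts exactly.
#'
#' @param counts Data frame with columns `n_tdt`, `n_2d`, `n_2c`,
#'   `n_both` plus optional metadata columns.
#' @return A per-cell tibble with columns `cell_id`,
#'   `tdtomato_positive`, `glun2c_puncta`, `glun2d_puncta` and the
#'   metadata columns.
#' @export
#' @examples
#' marker_table_from_counts(
#'   data.frame(mouse = "m1", n_tdt = 149, n_2d = 139, n_2c = 9, n_both = 9))
marker_table_from_counts <- function(counts) {
  need <- c("n_tdt", "n_2d", "n_2c", "n_both")
  if (!all(need %in% names(counts)))
    stop_bad_input("counts needs columns %s", paste(need, collapse = ", "))
  meta_cols <- setdiff(names(counts), need)
  rows <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    if (any(unlist(r[need]) < 0) || any(unlist(r[need]) %% 1 != 0))
      stop_bad_input("counts must be non-negative integers")
    if (r$n_both > min(r$n_2d, r$n_2c))
      stop_bad_input("n_both exceeds a single-marker count (row %d)", i)
    n_only2d <- r$n_2d - r$n_both
    n_only2c <- r$n_2c - r$n_both
    n_neither <- r$n_tdt - (n_only2d + n_only2c + r$n_both)
    if (n_neither < 0)
      stop_bad_input("marginals inconsistent: n_2d + n_2c - n_both > n_tdt (row %d)", i)
    cls <- rep(c("both", "only2d", "only2c", "neither"),
               c(r$n_both, n_only2d, n_only2c, n_neither))
    cells <- tibble::tibble(
      tdtomato_positive = TRUE,
      glun2c_puncta = as.integer(cls %in% c("both", "only2c")),
      glun2d_puncta = as.integer(cls %in% c("both", "only2d"))
    )
    for (m in meta_cols) cells[[m]] <- r[[m]]
    cells
  })
  rows$cell_id <- sprintf("cell%05d", seq_len(nrow(rows)))
  dplyr::relocate(rows, "cell_id")
}

#' Published per-slice and per-subdivision marker counts
#'
#' The per-slice (by mouse) and per-subdivision (by mouse) counts of
#' tdTomato-positive IC neurons positive for Glun2d and/or Glun2c mRNA,
#' shipped as plain-text tables under `inst/extdata/`. These are the
#' fixture inputs for the co-expression summaries.
#'
#' @return A tibble of group counts suitable for
#'   [marker_table_from_counts()].
#' @export
#' @examples
#' summarize_expression(marker_table_from_counts(glun2_slice_counts()))
glun2_slice_counts <- function() {
  readr::read_tsv(system.file("extdata", "glun2_slice_counts.tsv",
                              package = "nmdagain"),
                  show_col_types = FALSE)
}

#' @rdname glun2_slice_counts
#' @export
glun2_subdivision_counts <- function() {
  readr::read_tsv(system.file("extdata", "glun2_subdivision_counts.tsv",
                              package = "nmdagain"),
                  show_col_types = FALSE)
}
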