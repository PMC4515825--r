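#' Affinity-purification yield accounting
#'
#' Summarises a step-wise elution table (one row per bait and elution
#' step): combined yield as the sum of the per-step percent column — the
#' accounting used for the bait-modified sorbents — alongside an
#' independent mg-based cross-check (100 x total eluted mg / protein
#' applied). Steps whose printed percent and mg disagree beyond the
#' rounding tolerance are flagged; with `strict = TRUE` they raise an
#' error instead.
#'
#' @param table Data frame with columns `bait`, `protein_applied_mg`,
#'   `eluted_mg`, `eluted_pct` (and optionally `step`, `eluant`,
#'   `specific_activity`).
#' @param tol Rounding tolerance in percentage points for the mg/percent
#'   consistency check (default 0.1).
#' @param strict Error on inconsistent steps instead of warning.
#' @return Tibble per bait: `combined_pct` (sum of step percents),
#'   `combined_mg`, `combined_pct_from_mg`, `n_steps`, `consistent`.
#' @examples
#' purification_summary(load_purification_table())
#' @export
purification_summary <- function(table, tol = 0.1, strict = FALSE) {
  table <- tibble::as_tibble(table)
  need <- c("bait", "protein_applied_mg", "eluted_mg", "eluted_pct")
  if (!all(need %in% names(table))) {
    tt_abort(
      paste0("`table` needs columns: ", paste(need, collapse = ", ")),
      "inconsistent_table"
    )
  }
  if (any(table$protein_applied_mg <= 0)) {
    tt_abort("`protein_applied_mg` must be positive.", "inconsistent_table")
  }
  if (any(table$eluted_mg < 0) || any(table$eluted_pct < 0)) {
    tt_abort("Eluted amounts must be non-negative.", "inconsistent_table")
  }
  table <- dplyr::mutate(
    table,
    pct_from_mg = 100 * .data$eluted_mg / .data$protein_applied_mg,
    step_consistent = abs(.data$eluted_pct - .data$pct_from_mg) <= tol + 1e-9
  )
  if (any(!table$step_consistent)) {
    msg <- paste0(
      "Step percent and mg disagree beyond ", tol, " percentage point(s) for bait(s): ",
      paste(unique(table$bait[!table$step_consistent]), collapse = ", ")
    )
    if (strict) tt_abort(msg, "inconsistent_table") else rlang::warn(msg)
  }
  table |>
    dplyr::group_by(bait = .data$bait) |>
    dplyr::summarise(
      protein_applied_mg = .data$protein_applied_mg[1],
      combined_mg = sum(.data$eluted_mg),
      combined_pct = sum(.data$eluted_pct),
      combined_pct_from_mg = 100 * sum(.data$eluted_mg) / .data$protein_applied_mg[1],
      n_steps = dplyr::n(),
      consistent = all(.data$step_consistent)
    ) |>
    dplyr::ungroup()
}

#' Known-binder fraction of a proteome
#'
#' The share of an affinity-eluted proteome consisting of proteins already
#' documented to bind the bait (or to partner with such proteins):
#' `100 x (+ rows for the proteome flag) / proteome size`.
#'
#' @param known Data frame of documented binders with `+`/`-` membership
#'   flag columns (see [load_known_binders()]).
#' @param proteome_size Total number of proteins identified in that
#'   proteome.
#' @param flag Name of the flag column to count (e.g. `"thiazolium"` or
#'   `"thiamin"`).
#' @return Percentage (unrounded).
#' @examples
#' known_binder_fraction(load_known_binders(), 150, "thiazolium")
#' @export
known_binder_fraction <- function(known, proteome_size, flag) {
  known <- tibble::as_tibble(known)
  if (proteome_size <= 0) {
    tt_abort("`proteome_size` must be positive.", "domain_error")
  }
  if (!flag %in% names(known)) {
    tt_abort(paste0("No flag column '", flag, "' in `known`."), "domain_error")
  }
  100 * sum(known[[flag]] == "+", na.rm = TRUE) / proteome_size
}

#' Overlap between two proteomes
#'
#' @param a,b Character vectors of protein ids.
#' @return Tibble with rows `shared`, `a_only`, `b_only`: the partition
#'   sizes and id lists.
#' @export
proteome_overlap <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  parts <- list(
    shared = intersect(a, b),
    a_only = setdiff(a, b),
    b_only = setdiff(b, a)
  )
  tibble::tibble(
    set = names(parts),
    n = unname(vapply(parts, length, integer(1))),
    ids = unname(parts)
  )
}

## One-sided (greater) Fisher exact p for a 2x2 enrichment table:
## a = query proteins with the term, K = background proteins with the term,
## n = query size, N = background size.
fisher_greater_p <- function(a, K, n, N) {
  m <- matrix(c(a, n - a, K - a, (N - n) - (K - a)), nrow = 2)
  stats::fisher.test(m, alternative = "greater")$p.value
}

#' Annotation-term enrichment by one-sided Fisher test
#'
#' For each annotation term, tests whether the query proteome carries the
#' term more often than expected from the background, via the one-sided
#' (greater) Fisher exact test on the 2x2 table (in query vs rest of
#' background, with term vs without). P-values are Benjamini-Hochberg
#' adjusted across the tested terms. This is a transparent local statistic,
#' not a replica of web annotation servers whose scores depend on their
#' database versions.
#'
#' @param query Character vector of protein ids; must be a subset of
#'   `background`.
#' @param annotations Data frame with columns `protein_id`, `term`
#'   (one row per protein-term assignment).
#' @param background Character vector of protein ids forming the universe.
#' @return Tibble sorted by p: `term`, `n_query` (query proteins carrying
#'   the term), `n_background`, `query_size`, `background_size`, `p`,
#'   `p_adj`.
#' @export
term_enrichment <- function(query, annotations, background) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (!all(query %in% background)) {
    tt_abort(
      "`query` must be a subset of `background`.",
      "background_mismatch"
    )
  }
  annotations <- tibble::as_tibble(annotations)
  if (!all(c("protein_id", "term") %in% names(annotations))) {
    tt_abort("`annotations` needs protein_id and term columns.", "domain_error")
  }
  ann <- annotations |>
    dplyr::filter(.data$protein_id %in% background) |>
    dplyr::distinct(.data$protein_id, .data$term)
  N <- length(background)
  n <- length(query)
  out <- ann |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(
      n_query = sum(.data$protein_id %in% query),
      n_background = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      query_size = n,
      background_size = N,
      p = purrr::map2_dbl(
        .data$n_query, .data$n_background,
        function(a, K) fisher_greater_p(a, K, n, N)
      ),
      p_adj = stats::p.adjust(.data$p, method = "BH")
    ) |>
    dplyr::arrange(.data$p, .data$term)
  out
}
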