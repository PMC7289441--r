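#' Stringent-filter thresholds
#'
#' The stringent filter removes protein IDs with (i) a single distinct peptide,
#' (ii) sequence coverage below 20 percent, and (iii) an overall search score
#' of 50 or less. Boundary semantics: coverage exactly 20 is retained (the
#' removal rule is strictly-below-20), while a score of exactly 50 is removed
#' (retention requires a score strictly above 50).
#'
#' @param min_distinct_peptides Minimum distinct peptide sequences (inclusive).
#' @param min_coverage Minimum percent coverage (inclusive).
#' @param min_score_exclusive Score that must be strictly exceeded.
#' @return A `filter_thresholds` object.
#' @export
filter_thresholds <- function(min_distinct_peptides = 2L, min_coverage = 20,
                              min_score_exclusive = 50) {
  check_scalar_number(min_distinct_peptides, "min_distinct_peptides", min = 1)
  check_scalar_number(min_coverage, "min_coverage", min = 0)
  check_scalar_number(min_score_exclusive, "min_score_exclusive", min = 0)
  structure(
    list(
      min_distinct_peptides = as.integer(min_distinct_peptides),
      min_coverage = min_coverage,
      min_score_exclusive = min_score_exclusive
    ),
    class = "filter_thresholds"
  )
}

#' Accumulate the false-positive database from negative-control pull-downs
#'
#' Every accession ever observed in a negative-control GFP-TRAP run is treated
#' as a non-specific binder and blacklisted. The database is the plain union
#' of control-run accessions (no frequency weighting), deduplicated and sorted
#' so the result is deterministic regardless of run order.
#'
#' @param controls A list of control [pulldown_run()] objects
#'   (`is_control = TRUE`); the study design accumulates eight.
#' @return A `false_positive_db` with fields `accessions`, `source_run_ids`
#'   and `n_control_runs`.
#' @export
build_false_positive_db <- function(controls) {
  if (!is.list(controls) ||
      !all(vapply(controls, inherits, logical(1), "pulldown_run"))) {
    stop_contract("`controls` must be a list of pulldown_run objects",
                  "coprecip_contract_error")
  }
  not_ctrl <- vapply(controls, function(r) !r$is_control, logical(1))
  if (any(not_ctrl)) {
    stop_contract(
      paste0("non-control run(s) supplied: ",
             paste(vapply(controls[not_ctrl], `[[`, character(1), "run_id"),
                   collapse = ", ")),
      "coprecip_contract_error"
    )
  }
  run_ids <- vapply(controls, `[[`, character(1), "run_id")
  accessions <- sort(unique(unlist(
    lapply(controls, function(r) r$records$accession),
    use.names = FALSE
  )))
  structure(
    list(
      accessions = accessions %||% character(),
      source_run_ids = run_ids,
      n_control_runs = length(unique(run_ids))
    ),
    class = "false_positive_db"
  )
}

#' @export
print.false_positive_db <- function(x, ...) {
  cat(sprintf("<false_positive_db> %d accessions accumulated from %d control run(s)\n",
              length(x$accessions), x$n_control_runs))
  invisible(x)
}

#' Top-3 peptide quantification (T3PQ)
#'
#' Protein abundance estimated as the mean of the three highest-abundance
#' peptides identified for the protein. When fewer than three peptides carry a
#' present (non-missing) area, the mean of the available areas is used; the
#' number actually averaged is returned in the `n_used` attribute so degraded
#' estimates can be audited. Missing areas are never treated as zero.
#'
#' @param areas Numeric vector of peptide abundance areas (may contain `NA`).
#' @return The T3PQ mean area, with attribute `n_used`.
#' @export
t3pq <- function(areas) {
  present <- areas[!is.na(areas)]
  if (!length(present)) {
    stop_contract("T3PQ is undefined: no peptide has a present abundance area",
                  "coprecip_undefined_quantity_error")
  }
  top <- sort(present, decreasing = TRUE)[seq_len(min(3L, length(present)))]
  structure(mean(top), n_used = length(top))
}

#' Apply the stringent interactor filter to a bait pull-down
#'
#' A protein ID survives iff it (a) has at least `min_distinct_peptides`
#' distinct peptide sequences, (b) has coverage of at least `min_coverage`
#' percent, (c) scores strictly above `min_score_exclusive`, and (d) is not
#' present in the accumulated false-positive database. Every input record —
#' survivor or casualty — receives a per-rule audit row, so
#' `nrow(survivors) + nrow(rejected audit rows)` equals the input size.
#'
#' @param run A bait [pulldown_run()].
#' @param db A [build_false_positive_db()] result.
#' @param thresholds A [filter_thresholds()].
#' @return An unranked `interactor_calls` tibble of survivors (columns
#'   `accession`, `description`, `score`, `coverage`, `n_peptides`,
#'   `t3pq_mean_area`, `t3pq_n_used`, `is_bait`, `rank` = `NA`), with the full
#'   per-record audit in `attr(, "audit")` (logical pass columns
#'   `pass_peptides`, `pass_coverage`, `pass_score`, `pass_blacklist`,
#'   `passed`).
#' @export
apply_stringent_filter <- function(run, db, thresholds = filter_thresholds()) {
  if (!inherits(run, "pulldown_run")) {
    stop_contract("`run` must be a pulldown_run", "coprecip_contract_error")
  }
  if (run$is_control) {
    stop_contract("`run` is a negative control; the filter applies to bait pull-downs",
                  "coprecip_contract_error")
  }
  if (!inherits(db, "false_positive_db")) {
    stop_contract("`db` must be a false_positive_db", "coprecip_contract_error")
  }
  rec <- run$records
  n_pep <- n_distinct_peptides(rec$peptides)
  t3 <- purrr::map(rec$peptides, function(p) {
    if (all(is.na(p$area))) return(list(value = NA_real_, n_used = 0L))
    v <- t3pq(p$area)
    list(value = as.numeric(v), n_used = attr(v, "n_used"))
  })
  audit <- tibble(
    accession = rec$accession,
    pass_peptides = n_pep >= thresholds$min_distinct_peptides,
    pass_coverage = rec$coverage >= thresholds$min_coverage,
    pass_score = rec$score > thresholds$min_score_exclusive,
    pass_blacklist = !(rec$accession %in% db$accessions),
    t3pq_defined = vapply(t3, function(x) x$n_used > 0L, logical(1)),
    t3pq_degraded = vapply(t3, function(x) x$n_used > 0L && x$n_used < 3L, logical(1))
  )
  audit$passed <- audit$pass_peptides & audit$pass_coverage &
    audit$pass_score & audit$pass_blacklist
  keep <- audit$passed
  calls <- tibble(
    accession = rec$accession[keep],
    description = rec$description[keep],
    score = rec$score[keep],
    coverage = rec$coverage[keep],
    n_peptides = n_pep[keep],
    t3pq_mean_area = vapply(t3[keep], function(x) x$value, numeric(1)),
    t3pq_n_used = vapply(t3[keep], function(x) x$n_used, integer(1)),
    is_bait = if (is.null(run$bait_accession)) rep(FALSE, sum(keep)) else
      rec$accession[keep] == run$bait_accession,
    rank = rep(NA_integer_, sum(keep))
  )
  structure(calls, class = c("interactor_calls", class(calls)),
            audit = audit, run_id = run$run_id,
            bait_accession = run$bait_accession)
}

#' Rank surviving interactors by T3PQ mean area
#'
#' Orders survivors by descending T3PQ mean area; ties are broken by
#' descending score, then lexicographic accession, so ranking is fully
#' deterministic. Ranks are contiguous from 1.
#'
#' @param calls An `interactor_calls` tibble with `t3pq_mean_area` populated.
#' @return The same tibble, sorted, with `rank` filled in.
#' @export
rank_interactors <- function(calls) {
  if (anyNA(calls$t3pq_mean_area)) {
    stop_contract("t3pq_mean_area must be populated (and defined) for all calls",
                  "coprecip_contract_error")
  }
  at <- attributes(calls)
  df <- tibble::new_tibble(as.list(as_tibble(calls)), nrow = nrow(calls))
  ord <- order(-df$t3pq_mean_area, -df$score, df$accession)
  out <- df[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("interactor_calls", "tbl_df", "tbl", "data.frame"),
            audit = at$audit, run_id = at$run_id,
            bait_accession = at$bait_accession)
}

#' Check that the bait tops the abundance ranking
#'
#' In a clean pull-down the tagged bait is the most abundant protein in the
#' precipitate; a bait that fails to hold rank 1 signals a problem upstream.
#'
#' @param ranked A ranked `interactor_calls` tibble.
#' @param bait Bait accession.
#' @return A list `(ok, bait_rank, top_accession, message)`.
#' @export
verify_bait_top <- function(ranked, bait) {
  ranked <- as_tibble(ranked)
  if (!nrow(ranked)) {
    stop_contract("ranked call list is empty", "coprecip_contract_error")
  }
  idx <- match(bait, ranked$accession)
  if (is.na(idx)) {
    stop_contract(paste0("bait accession absent from ranked calls: ", bait),
                  "coprecip_absent_bait_error")
  }
  ok <- ranked$rank[idx] == 1L
  list(
    ok = ok,
    bait_rank = ranked$rank[idx],
    top_accession = ranked$accession[ranked$rank == 1L],
    message = if (ok) "bait holds rank 1" else
      sprintf("bait %s holds rank %d; rank 1 is %s",
              bait, ranked$rank[idx], ranked$accession[ranked$rank == 1L])
  )
}

#' Call interactors for a bait pull-down (full stringent pipeline)
#'
#' Convenience wrapper chaining [build_false_positive_db()],
#' [apply_stringent_filter()] and [rank_interactors()], with an optional bait
#' sanity check. The bait itself is reported (flagged `is_bait`) but is not
#' counted among the specific interactors in [glance()].
#'
#' @param run Bait [pulldown_run()].
#' @param controls List of control runs (or an existing `false_positive_db`).
#' @param thresholds A [filter_thresholds()].
#' @return A ranked `interactor_calls` tibble.
#' @export
call_interactors <- function(run, controls, thresholds = filter_thresholds()) {
  db <- if (inherits(controls, "false_positive_db")) controls else
    build_false_positive_db(controls)
  rank_interactors(apply_stringent_filter(run, db, thresholds))
}

#' @export
print.interactor_calls <- function(x, ...) {
  cat(sprintf("<interactor_calls> %d surviving protein ID(s)", nrow(x)))
  if (!is.null(attr(x, "run_id"))) cat(" — run", attr(x, "run_id"))
  cat("\n")
  NextMethod()
}

#' @rdname call_interactors
#' @param x An `interactor_calls` object.
#' @param ... Unused.
#' @method tidy interactor_calls
#' @export
tidy.interactor_calls <- function(x, ...) {
  as_tibble(x)[, c("rank", "accession", "description", "score", "coverage",
                   "n_peptides", "t3pq_mean_area", "t3pq_n_used", "is_bait")]
}

#' @rdname call_interactors
#' @method glance interactor_calls
#' @export
glance.interactor_calls <- function(x, ...) {
  audit <- attr(x, "audit")
  bait <- attr(x, "bait_accession")
  tibble(
    n_input = if (is.null(audit)) NA_integer_ else nrow(audit),
    n_survivors = nrow(x),
    n_specific_interactors = sum(!x$is_bait),
    bait_rank = if (!is.null(bait) && bait %in% x$accession)
      as.integer(x$rank[match(bait, x$accession)]) else NA_integer_,
    n_rejected = if (is.null(audit)) NA_integer_ else sum(!audit$passed)
  )
}

#' Plot ranked interactor abundances
#'
#' Bar chart of T3PQ mean area by rank (log scale), bait highlighted — the
#' usual way a ranked AP-MS interactor list is displayed.
#'
#' @param object A ranked `interactor_calls` tibble.
#' @param top_n Show at most this many top-ranked proteins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interactor_calls
#' @export
autoplot.interactor_calls <- function(object, top_n = 20, ...) {
  df <- head(dplyr::arrange(as_tibble(object), .data$rank), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$accession, -.data$t3pq_mean_area),
    y = .data$t3pq_mean_area, fill = .data$is_bait
  )) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                               name = "bait") +
    ggplot2::labs(x = NULL, y = "T3PQ mean area (a.u., log scale)",
                  title = "Ranked co-precipitating proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
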