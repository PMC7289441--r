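#' The five categorical eye-size classes
#'
#' Adult eyes are scored by visual inspection into five classes relative to
#' the wild-type eye: 0 (eye absent), 25, 50 and 75 (eye smaller than 25, 50
#' and 75 percent of wild-type size, respectively) and 100 (essentially
#' normal size).
#'
#' @return Integer vector `c(0, 25, 50, 75, 100)`.
#' @export
eye_size_classes <- function() c(0L, 25L, 50L, 75L, 100L)

#' Resolve an ambiguous (dubious) eye-size call
#'
#' When visual classification between two adjacent classes is not clear-cut,
#' the assignment is deliberately conservative with respect to the hypothesis
#' being tested: without a rescue construct the eye goes to the *higher*
#' class (understating the knockdown phenotype; e.g. a dubious class-50 eye
#' is scored 75), and in the presence of a rescue construct it goes to the
#' *lower* class (understating the rescue).
#'
#' @param pair Numeric pair of adjacent classes, e.g. `c(50, 75)` (order
#'   irrelevant).
#' @param rescue_present Logical; is a rescue construct present?
#' @return The resolved class (scalar).
#' @export
resolve_ambiguous_class <- function(pair, rescue_present) {
  classes <- eye_size_classes()
  if (length(pair) != 2L || !all(pair %in% classes)) {
    stop_contract("`pair` must be two of the five size classes",
                  "coprecip_contract_error")
  }
  pair <- sort(as.integer(pair))
  if (diff(match(pair, classes)) != 1L) {
    stop_contract(
      sprintf("classes %d and %d are not adjacent", pair[1], pair[2]),
      "coprecip_contract_error"
    )
  }
  if (isTRUE(rescue_present)) pair[1] else pair[2]
}

#' Read per-eye phenotype records
#'
#' Input CSV columns: `genotype`, `eye_id`, `class` (one of 0/25/50/75/100 or
#' an ambiguous adjacent pair written `"50/75"`), `rescue_present`
#' (logical). Ambiguous entries are parsed into `ambiguous_low`/
#' `ambiguous_high` and left unresolved (`size_class = NA`); call
#' [resolve_eye_records()] before tabulating.
#'
#' @param path CSV path.
#' @return A tibble of eye records.
#' @export
read_eye_records <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    genotype = readr::col_character(),
    eye_id = readr::col_character(),
    class = readr::col_character(),
    rescue_present = readr::col_logical()
  ), progress = FALSE)
  classes <- eye_size_classes()
  parse_one <- function(cl) {
    parts <- suppressWarnings(as.integer(strsplit(cl, "/", fixed = TRUE)[[1]]))
    if (anyNA(parts) || !all(parts %in% classes) ||
        !(length(parts) %in% 1:2)) {
      stop_contract(paste0("unparseable class entry: ", cl),
                    "coprecip_format_error")
    }
    parts
  }
  parsed <- lapply(raw$class, parse_one)
  tibble(
    genotype = raw$genotype,
    eye_id = raw$eye_id,
    size_class = vapply(parsed, function(p)
      if (length(p) == 1L) p else NA_integer_, integer(1)),
    ambiguous_low = vapply(parsed, function(p)
      if (length(p) == 2L) min(p) else NA_integer_, integer(1)),
    ambiguous_high = vapply(parsed, function(p)
      if (length(p) == 2L) max(p) else NA_integer_, integer(1)),
    rescue_present = raw$rescue_present
  )
}

#' Resolve all ambiguous records with the conservative tie-break
#'
#' Applies [resolve_ambiguous_class()] row-wise; unambiguous records pass
#' through unchanged.
#'
#' @param records Eye-record tibble as returned by [read_eye_records()].
#' @return The tibble with `size_class` filled for every row.
#' @export
resolve_eye_records <- function(records) {
  records <- as_tibble(records)
  amb <- is.na(records$size_class)
  if (any(amb)) {
    records$size_class[amb] <- purrr::pmap_int(
      list(records$ambiguous_low[amb], records$ambiguous_high[amb],
           records$rescue_present[amb]),
      function(lo, hi, rescue)
        as.integer(resolve_ambiguous_class(c(lo, hi), rescue))
    )
  }
  records
}

#' Tabulate eye-size class distributions per genotype
#'
#' One tally per genotype (ordered by first appearance in the input): counts
#' and percentages over the five size classes, in long tidy format. Counts
#' always sum to the per-genotype total, and merging two record batches then
#' tabulating equals summing their tallies.
#'
#' @param records Resolved eye-record tibble (no `NA` in `size_class`).
#' @return An `eye_class_tally` tibble: `genotype`, `size_class`, `n`,
#'   `percent`, `n_total`.
#' @export
tabulate_classes <- function(records) {
  records <- as_tibble(records)
  if (!nrow(records)) {
    return(structure(
      tibble(genotype = character(), size_class = integer(), n = integer(),
             percent = numeric(), n_total = integer()),
      class = c("eye_class_tally", "tbl_df", "tbl", "data.frame")
    ))
  }
  if (anyNA(records$size_class)) {
    stop_contract("unresolved ambiguous record(s); run resolve_eye_records() first",
                  "coprecip_contract_error")
  }
  if (!all(records$size_class %in% eye_size_classes())) {
    stop_contract("size_class outside the five-class enumeration",
                  "coprecip_contract_error")
  }
  geno_levels <- unique(records$genotype)
  out <- records |>
    dplyr::mutate(genotype = factor(.data$genotype, levels = geno_levels),
                  size_class = factor(.data$size_class, levels = eye_size_classes())) |>
    dplyr::count(.data$genotype, .data$size_class, .drop = FALSE) |>
    dplyr::group_by(.data$genotype) |>
    dplyr::mutate(n_total = sum(.data$n), percent = 100 * .data$n / .data$n_total) |>
    dplyr::ungroup() |>
    dplyr::mutate(genotype = as.character(.data$genotype),
                  size_class = as.integer(as.character(.data$size_class))) |>
    dplyr::select("genotype", "size_class", "n", "percent", "n_total")
  structure(out, class = c("eye_class_tally", "tbl_df", "tbl", "data.frame"))
}

#' Write an eye-class tally in wide and long form
#'
#' The long CSV keeps raw counts and exact percentages; the wide CSV shows
#' one row per genotype with class percentages rounded to one decimal (a
#' display format; computation should use the long form).
#'
#' @param tally An `eye_class_tally`.
#' @param path Base path; writes `<path>` (long) and `<path>` with a `_wide`
#'   suffix.
#' @return `path`, invisibly.
#' @export
write_class_tally <- function(tally, path) {
  readr::write_csv(as_tibble(tally), path, progress = FALSE)
  wide <- as_tibble(tally) |>
    dplyr::mutate(percent = round(.data$percent, 1)) |>
    dplyr::select("genotype", "size_class", "percent") |>
    tidyr::pivot_wider(names_from = "size_class", values_from = "percent",
                       names_prefix = "class_")
  wide_path <- sub("(\\.[A-Za-z0-9]+)?$", "_wide\\1", path)
  readr::write_csv(wide, wide_path, progress = FALSE)
  invisible(path)
}

#' Plot eye-size class distributions
#'
#' Stacked percentage bars per genotype, the standard display for categorical
#' eye-size distributions.
#'
#' @param object An `eye_class_tally`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eye_class_tally
#' @export
autoplot.eye_class_tally <- function(object, ...) {
  df <- as_tibble(object)
  df$size_class <- factor(df$size_class, levels = rev(eye_size_classes()))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$genotype, levels = unique(.data$genotype)),
    y = .data$percent, fill = .data$size_class
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1,
                               name = "size class") +
    ggplot2::labs(x = NULL, y = "% of eyes", title = "Eye-size class distribution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
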