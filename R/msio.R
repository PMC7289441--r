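#' Describe the on-disk layout of a protein-level search-result table
#'
#' Protein-level AP-MS exports differ in delimiter, column naming and in how
#' per-peptide abundances are laid out. A dialect maps the pipeline's field
#' names onto the file's column names and selects between two peptide layouts:
#'
#' * `"wide"` — one row per protein; peptide sequences and abundance areas are
#'   packed into single cells, joined by `area_sep` (missing areas are empty
#'   fields, never 0).
#' * `"long"` — peptides live in a separate long table (one row per peptide:
#'   accession, sequence, area) supplied via `peptide_path` at read time.
#'
#' @param sep Field delimiter, `","` (CSV, default) or `"\t"` (TSV).
#' @param layout `"wide"` or `"long"` peptide layout.
#' @param area_sep Separator joining peptide-level cells in the wide layout.
#' @param col_map Named character vector mapping pipeline fields
#'   (`accession`, `description`, `score`, `coverage`, and for the wide layout
#'   `peptide_sequences`, `peptide_areas`; for the long layout `sequence`,
#'   `area`) onto the file's column names. Unnamed fields keep their defaults.
#' @return A `table_dialect` object.
#' @export
table_dialect <- function(sep = ",", layout = c("wide", "long"), area_sep = ";",
                          col_map = character()) {
  layout <- match.arg(layout)
  defaults <- c(
    accession = "accession", description = "description",
    score = "score", coverage = "coverage",
    peptide_sequences = "peptide_sequences", peptide_areas = "peptide_areas",
    sequence = "sequence", area = "area"
  )
  if (length(col_map)) {
    bad <- setdiff(names(col_map), names(defaults))
    if (length(bad)) {
      stop_contract(
        paste0("unknown col_map field(s): ", paste(bad, collapse = ", ")),
        "coprecip_config_error"
      )
    }
    defaults[names(col_map)] <- col_map
  }
  structure(
    list(sep = sep, layout = layout, area_sep = area_sep, col_map = defaults),
    class = "table_dialect"
  )
}

#' Construct a pull-down run
#'
#' A pull-down run bundles the protein-group records of one GFP-TRAP
#' experiment: either a bait precipitate (with a designated bait accession) or
#' a negative-control run used to accumulate the false-positive database.
#'
#' @param run_id Run identifier string.
#' @param records Tibble with columns `accession`, `description`, `score`,
#'   `coverage` and a `peptides` list-column of tibbles
#'   (`sequence`, `area`). Areas may be `NA` (observed but unquantified), never
#'   negative.
#' @param bait_accession Accession of the tagged bait, or `NULL` for control
#'   runs.
#' @param is_control Logical; control runs must not designate a bait.
#' @return A `pulldown_run` object.
#' @export
pulldown_run <- function(run_id, records, bait_accession = NULL,
                         is_control = FALSE) {
  if (!is.character(run_id) || length(run_id) != 1L || !nzchar(run_id)) {
    stop_contract("`run_id` must be a non-empty string", "coprecip_validation_error")
  }
  if (isTRUE(is_control) && !is.null(bait_accession)) {
    stop_contract("control runs must not designate a bait accession",
                  "coprecip_validation_error")
  }
  records <- as_tibble(records)
  needed <- c("accession", "description", "score", "coverage", "peptides")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_contract(
      paste0("records is missing column(s): ", paste(missing_cols, collapse = ", ")),
      "coprecip_format_error"
    )
  }
  dup <- records$accession[duplicated(records$accession)]
  if (length(dup)) {
    stop_contract(
      paste0("duplicate accession(s) within run: ", paste(unique(dup), collapse = ", ")),
      "coprecip_validation_error"
    )
  }
  structure(
    list(
      run_id = run_id,
      bait_accession = bait_accession,
      is_control = isTRUE(is_control),
      records = records[needed]
    ),
    class = "pulldown_run"
  )
}

#' @export
print.pulldown_run <- function(x, ...) {
  cat(sprintf(
    "<pulldown_run> %s (%s) — %d protein records\n", x$run_id,
    if (x$is_control) "negative control" else paste0("bait: ", x$bait_accession %||% "unset"),
    nrow(x$records)
  ))
  print(x$records, n = 5)
  invisible(x)
}

#' Number of distinct peptide sequences per record
#'
#' The single-peptide filter counts distinct peptide sequences, not
#' peptide-spectrum matches: repeated identifications of the same sequence add
#' no sequence-level evidence.
#'
#' @param peptides A list of peptide tibbles (`sequence`, `area`).
#' @return Integer vector of distinct-sequence counts.
#' @export
n_distinct_peptides <- function(peptides) {
  vapply(peptides, function(p) length(unique(p$sequence)), integer(1))
}

validate_record_rows <- function(df) {
  reasons <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    ifelse(bad & is.na(reasons), why, reasons)
  }
  reasons <- flag(is.na(df$accession) | !nzchar(df$accession), "empty accession")
  reasons <- flag(is.na(df$score) | df$score < 0, "score missing or negative")
  reasons <- flag(is.na(df$coverage) | df$coverage < 0 | df$coverage > 100,
                  "coverage outside [0, 100]")
  pep_bad <- vapply(df$peptides, function(p) {
    if (nrow(p) == 0L) return("no peptides")
    if (!all(is_valid_peptide_seq(p$sequence))) return("invalid peptide sequence")
    if (any(!is.na(p$area) & p$area < 0)) return("negative peptide area")
    NA_character_
  }, character(1))
  reasons <- ifelse(!is.na(pep_bad) & is.na(reasons), pep_bad, reasons)
  reasons
}

#' Read a protein-level search-result table into a pull-down run
#'
#' Reads a delimited protein-group table (one row per protein ID, carrying the
#' search score, percent sequence coverage and per-peptide abundance areas)
#' and validates every row. Rows violating the record invariants are rejected,
#' never silently dropped: they are returned as row-indexed diagnostics in
#' `attr(run, "diagnostics")`, and `nrow(records) + nrow(diagnostics)` always
#' equals the number of input rows.
#'
#' @param path Path to the protein table.
#' @param dialect A [table_dialect()] describing delimiter, column names and
#'   peptide layout.
#' @param run_id Run identifier; defaults to the file name.
#' @param bait_accession,is_control See [pulldown_run()].
#' @param peptide_path For the long layout, path to the peptide-level table.
#' @return A [pulldown_run()] with a `diagnostics` attribute (tibble with
#'   columns `row`, `accession`, `reason`).
#' @export
read_protein_table <- function(path, dialect = table_dialect(), run_id = NULL,
                               bait_accession = NULL, is_control = FALSE,
                               peptide_path = NULL) {
  if (!file.exists(path)) {
    stop_contract(paste0("file not found: ", path), "coprecip_format_error")
  }
  cm <- dialect$col_map
  raw <- readr::read_delim(path, delim = dialect$sep, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  mandatory <- c("accession", "score", "coverage")
  if (dialect$layout == "wide") {
    mandatory <- c(mandatory, "peptide_sequences", "peptide_areas")
  }
  for (field in mandatory) {
    if (!cm[[field]] %in% names(raw)) {
      stop_contract(
        sprintf("missing mandatory column `%s` (field %s)", cm[[field]], field),
        "coprecip_format_error"
      )
    }
  }
  n_in <- nrow(raw)
  desc <- if (cm[["description"]] %in% names(raw)) raw[[cm[["description"]]]] else rep("", n_in)
  df <- tibble(
    accession = raw[[cm[["accession"]]]],
    description = desc,
    score = suppressWarnings(as.numeric(raw[[cm[["score"]]]])),
    coverage = suppressWarnings(as.numeric(raw[[cm[["coverage"]]]]))
  )

  if (n_in == 0L) {
    df$peptides <- list()
  } else if (dialect$layout == "wide") {
    seq_col <- as.character(raw[[cm[["peptide_sequences"]]]])
    area_col <- as.character(raw[[cm[["peptide_areas"]]]])
    seqs <- strsplit(ifelse(is.na(seq_col), "", seq_col),
                     dialect$area_sep, fixed = TRUE)
    areas <- strsplit(ifelse(is.na(area_col), "", area_col),
                      dialect$area_sep, fixed = TRUE)
    df$peptides <- purrr::map2(seqs, areas, function(s, a) {
      # a shorter area list is right-padded with missing, never with zero
      a <- c(a, rep("", max(0L, length(s) - length(a))))[seq_along(s)]
      a[!nzchar(a)] <- NA_character_
      tibble(sequence = s, area = suppressWarnings(as.numeric(a)))
    })
  } else {
    if (is.null(peptide_path)) {
      stop_contract("long layout requires `peptide_path`", "coprecip_format_error")
    }
    pep <- readr::read_delim(peptide_path, delim = dialect$sep, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
    for (field in c("accession", "sequence", "area")) {
      if (!cm[[field]] %in% names(pep)) {
        stop_contract(
          sprintf("peptide table missing column `%s` (field %s)", cm[[field]], field),
          "coprecip_format_error"
        )
      }
    }
    pep <- tibble(
      accession = pep[[cm[["accession"]]]],
      sequence = pep[[cm[["sequence"]]]],
      area = suppressWarnings(as.numeric(pep[[cm[["area"]]]]))
    )
    split_pep <- split(pep[c("sequence", "area")], factor(pep$accession, levels = unique(df$accession)))
    df$peptides <- purrr::map(df$accession, function(acc) {
      p <- split_pep[[acc]]
      if (is.null(p)) tibble(sequence = character(), area = numeric()) else as_tibble(p)
    })
  }

  dup <- df$accession[duplicated(df$accession)]
  if (length(dup)) {
    stop_contract(
      paste0("duplicate accession(s): ", paste(unique(dup), collapse = ", ")),
      "coprecip_validation_error"
    )
  }

  reasons <- if (n_in) validate_record_rows(df) else character()
  keep <- is.na(reasons)
  diagnostics <- tibble(
    row = which(!keep),
    accession = df$accession[!keep],
    reason = reasons[!keep]
  )
  run <- pulldown_run(
    run_id = run_id %||% basename(path),
    records = df[keep, , drop = FALSE],
    bait_accession = bait_accession,
    is_control = is_control
  )
  attr(run, "diagnostics") <- diagnostics
  run
}

#' Write a pull-down run as a wide-layout CSV
#'
#' Peptide sequences and areas are packed into semicolon-joined cells; areas
#' are written with round-trip precision so `read_protein_table()` recovers the
#' run field-for-field (missing areas become empty fields).
#'
#' @param run A [pulldown_run()].
#' @param path Output path.
#' @param dialect A wide-layout [table_dialect()].
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(run, path, dialect = table_dialect()) {
  if (dialect$layout != "wide") {
    stop_contract("write_protein_table() writes the wide layout", "coprecip_config_error")
  }
  cm <- dialect$col_map
  rec <- run$records
  out <- tibble(
    !!cm[["accession"]] := rec$accession,
    !!cm[["description"]] := rec$description,
    !!cm[["score"]] := fmt_num(rec$score),
    !!cm[["coverage"]] := fmt_num(rec$coverage),
    !!cm[["peptide_sequences"]] := vapply(rec$peptides, function(p)
      paste(p$sequence, collapse = dialect$area_sep), character(1)),
    !!cm[["peptide_areas"]] := vapply(rec$peptides, function(p)
      paste(fmt_num(p$area), collapse = dialect$area_sep), character(1))
  )
  readr::write_delim(out, path, delim = dialect$sep, progress = FALSE)
  invisible(path)
}

#' Write a ranked interactor report
#'
#' Emits the ranked interactor table (the shape of a published AP-MS
#' interactor figure panel): one row per surviving protein ID ordered by rank,
#' with score, coverage, distinct-peptide count, T3PQ mean area and a bait
#' flag. A JSON run manifest (`<path>.manifest.json`) carrying run provenance
#' is written alongside. Writing is deterministic: identical input produces a
#' byte-identical file, and re-reading then re-writing a report is idempotent.
#'
#' @param calls A ranked `interactor_calls` tibble (see [rank_interactors()]):
#'   rank populated and contiguous from 1.
#' @param path Output CSV path.
#' @param run_id Optional run identifier recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_interactor_report <- function(calls, path, run_id = NULL) {
  calls <- as_tibble(calls)
  if (!"rank" %in% names(calls) || anyNA(calls$rank)) {
    stop_contract("calls must be ranked before writing (see rank_interactors())",
                  "coprecip_contract_error")
  }
  if (nrow(calls) && !identical(sort(as.integer(calls$rank)), seq_len(nrow(calls)))) {
    stop_contract("ranks must be contiguous from 1", "coprecip_contract_error")
  }
  calls <- dplyr::arrange(calls, .data$rank)
  out <- tibble(
    rank = as.integer(calls$rank),
    accession = calls$accession,
    description = calls$description,
    score = fmt_num(calls$score),
    coverage = fmt_num(calls$coverage),
    n_peptides = as.integer(calls$n_peptides),
    t3pq_mean_area = fmt_num(calls$t3pq_mean_area),
    bait_flag = as.logical(calls$is_bait)
  )
  readr::write_csv(out, path, progress = FALSE)
  manifest <- list(
    run_id = run_id %||% "unspecified",
    n_records = nrow(out),
    provenance = list(
      tool = "coprecip",
      version = as.character(utils::packageVersion("coprecip")),
      content_hash = rlang::hash(out)
    )
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read back a ranked interactor report
#'
#' @param path Path written by [write_interactor_report()].
#' @return A tibble with the report columns (rank-ordered).
#' @export
read_interactor_report <- function(path) {
  # numbers are parsed with base strtod (correctly rounded) so that a
  # read + re-write cycle is byte-identical
  rep <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  out <- tibble(
    rank = as.integer(rep$rank),
    accession = rep$accession,
    description = ifelse(is.na(rep$description), "", rep$description),
    score = as.numeric(rep$score),
    coverage = as.numeric(rep$coverage),
    n_peptides = as.integer(rep$n_peptides),
    t3pq_mean_area = as.numeric(rep$t3pq_mean_area),
    is_bait = as.logical(rep$bait_flag)
  )
  dplyr::arrange(out, .data$rank)
}
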