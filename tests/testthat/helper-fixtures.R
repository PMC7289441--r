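# Fixture builders shared across test files. All fixtures are built in code.

peptides_tbl <- function(areas, seqs = NULL) {
  if (is.null(seqs)) {
    seqs <- vapply(seq_along(areas), function(i)
      paste0("PEPTIDE", paste(LETTERS[(i %% 26) + 1], collapse = ""), i),
      character(1))
  }
  tibble::tibble(sequence = seqs, area = areas)
}

toy_record <- function(accession, score, coverage, areas, description = "",
                       seqs = NULL) {
  tibble::tibble(
    accession = accession, description = description,
    score = score, coverage = coverage,
    peptides = list(peptides_tbl(areas, seqs))
  )
}

toy_run <- function(records, run_id = "toy_run", bait = NULL, control = FALSE) {
  pulldown_run(run_id, records, bait_accession = bait, is_control = control)
}

control_with <- function(accessions, run_id = "ctrl") {
  recs <- dplyr::bind_rows(lapply(accessions, function(a)
    toy_record(a, score = 100, coverage = 50, areas = c(10, 20))))
  if (!length(accessions)) {
    recs <- toy_record("X", 100, 50, c(10, 20))[0, ]
  }
  toy_run(recs, run_id = run_id, control = TRUE)
}

# Random protein table for oracle-equivalence checks: mixes passing and
# failing records, missing areas, blacklisted accessions.
random_run <- function(n_records, blacklist_pool) {
  if (n_records == 0L) {
    return(toy_run(toy_record("X", 1, 1, 1)[0, ], run_id = "random_run"))
  }
  recs <- dplyr::bind_rows(lapply(seq_len(n_records), function(i) {
    n_pep <- sample(1:5, 1)
    areas <- stats::rlnorm(n_pep, 8, 2)
    areas[stats::runif(n_pep) < 0.15] <- NA
    if (all(is.na(areas))) areas[1] <- stats::rlnorm(1, 8, 2)
    acc <- if (stats::runif(1) < 0.25 && length(blacklist_pool))
      sample(blacklist_pool, 1) else sprintf("P%05d", sample.int(99999, 1))
    toy_record(
      accession = acc,
      score = stats::runif(1, 0, 200),
      coverage = stats::runif(1, 0, 100),
      areas = areas
    )
  }))
  recs <- recs[!duplicated(recs$accession), , drop = FALSE]
  toy_run(recs, run_id = "random_run")
}

# Independent brute-force re-implementation of the stringent filter, T3PQ and
# ranking, used as the oracle. Deliberately loop-based and separate from the
# package internals.
brute_force_pipeline <- function(run, db_accessions, thresholds) {
  rows <- list()
  for (i in seq_len(nrow(run$records))) {
    rec <- run$records[i, ]
    pep <- rec$peptides[[1]]
    n_distinct <- length(unique(pep$sequence))
    present <- pep$area[!is.na(pep$area)]
    ok <- n_distinct >= thresholds$min_distinct_peptides &&
      rec$coverage >= thresholds$min_coverage &&
      rec$score > thresholds$min_score_exclusive &&
      !(rec$accession %in% db_accessions)
    if (ok) {
      if (!length(present)) next
      srt <- sort(present, decreasing = TRUE)
      top <- srt[1:min(3, length(srt))]
      rows[[length(rows) + 1]] <- data.frame(
        accession = rec$accession, score = rec$score,
        t3pq = mean(top), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(accession = character(), score = numeric(),
                      t3pq = numeric(), rank = integer()))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$t3pq, -df$score, df$accession), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

# A hand-built single-plane stack whose masks are fully known.
manual_stack <- function(caspase, dapi = NULL, elav = NULL, pixel_size = 0.5) {
  H <- nrow(caspase); W <- ncol(caspase)
  if (is.null(dapi)) dapi <- matrix(100, H, W)
  if (is.null(elav)) elav <- matrix(0, H, W)
  structure(
    list(
      channels = list(
        dapi = array(dapi, dim = c(H, W, 1)),
        elav = array(elav, dim = c(H, W, 1)),
        caspase = array(caspase, dim = c(H, W, 1))
      ),
      z_step = 0.5, pixel_size = pixel_size
    ),
    class = "disc_image_stack"
  )
}
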