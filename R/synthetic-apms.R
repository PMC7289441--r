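#' Configuration for the spike-in AP-MS simulator
#'
#' The simulator emulates the structure of a GFP-TRAP AP-MS study: one bait
#' pull-down containing the bait, a set of true interactors (present only in
#' the bait precipitate) and a pool of background contaminants; plus a panel
#' of negative-control pull-downs in which each contaminant reappears
#' independently with a fixed probability. Default laws are "clear-margin":
#' both classes clear the peptide/coverage/score thresholds comfortably, so
#' that the blacklist — not the thresholds — is what separates contaminants
#' from true interactors, and the expected number of escaping contaminants is
#' analytically `n_contaminants * (1 - presence_prob)^n_control_runs`.
#'
#' Abundance areas are log-normal: true interactors `meanlog = 12, sdlog = 1`,
#' contaminants `meanlog = 8, sdlog = 1.5` (arbitrary area units).
#'
#' @param n_true_interactors Number of true interactors spiked into the bait run.
#' @param n_contaminants Size of the background contaminant pool.
#' @param n_control_runs Number of negative-control runs accumulated (the
#'   study design uses 8).
#' @param contaminant_control_presence_prob Probability that a given
#'   contaminant appears in a given control run.
#' @param true_abundance_meanlog,true_abundance_sdlog Log-normal law for true
#'   interactor peptide areas.
#' @param contaminant_abundance_meanlog,contaminant_abundance_sdlog Log-normal
#'   law for contaminant peptide areas.
#' @param true_score_range,contaminant_score_range Uniform score ranges;
#'   defaults sit well above the score-50 cut.
#' @param true_coverage_range,contaminant_coverage_range Uniform percent
#'   coverage ranges; defaults sit well above the 20 percent cut.
#' @param true_peptide_range,contaminant_peptide_range Inclusive integer
#'   ranges for distinct peptide counts; lower bounds of at least 2 keep both
#'   classes clear of the single-peptide rule.
#' @param seed Integer seed governing all randomness.
#' @return An `apms_sim_config` object.
#' @export
apms_sim_config <- function(n_true_interactors = 12L,
                            n_contaminants = 200L,
                            n_control_runs = 8L,
                            contaminant_control_presence_prob = 0.9,
                            true_abundance_meanlog = 12,
                            true_abundance_sdlog = 1,
                            contaminant_abundance_meanlog = 8,
                            contaminant_abundance_sdlog = 1.5,
                            true_score_range = c(150, 400),
                            contaminant_score_range = c(80, 250),
                            true_coverage_range = c(35, 80),
                            contaminant_coverage_range = c(30, 70),
                            true_peptide_range = c(3L, 8L),
                            contaminant_peptide_range = c(2L, 6L),
                            seed = 1L) {
  check_scalar_number(n_true_interactors, "n_true_interactors", min = 0)
  check_scalar_number(n_contaminants, "n_contaminants", min = 0)
  check_scalar_number(n_control_runs, "n_control_runs", min = 0)
  check_scalar_number(contaminant_control_presence_prob,
                      "contaminant_control_presence_prob", min = 0, max = 1)
  if (true_abundance_sdlog < 0 || contaminant_abundance_sdlog < 0) {
    stop_contract("abundance sdlog must be nonnegative", "coprecip_config_error")
  }
  for (nm in c("true_score_range", "contaminant_score_range",
               "true_coverage_range", "contaminant_coverage_range",
               "true_peptide_range", "contaminant_peptide_range")) {
    r <- get(nm)
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < 0) {
      stop_contract(paste0("`", nm, "` must be a nondecreasing nonnegative pair"),
                    "coprecip_config_error")
    }
  }
  if (true_peptide_range[1] < 2L) {
    stop_contract("true interactors need at least 2 distinct peptides to clear the filter",
                  "coprecip_config_error")
  }
  check_scalar_number(seed, "seed")
  structure(
    list(
      n_true_interactors = as.integer(n_true_interactors),
      n_contaminants = as.integer(n_contaminants),
      n_control_runs = as.integer(n_control_runs),
      contaminant_control_presence_prob = contaminant_control_presence_prob,
      true_abundance_meanlog = true_abundance_meanlog,
      true_abundance_sdlog = true_abundance_sdlog,
      contaminant_abundance_meanlog = contaminant_abundance_meanlog,
      contaminant_abundance_sdlog = contaminant_abundance_sdlog,
      true_score_range = true_score_range,
      contaminant_score_range = contaminant_score_range,
      true_coverage_range = true_coverage_range,
      contaminant_coverage_range = contaminant_coverage_range,
      true_peptide_range = as.integer(true_peptide_range),
      contaminant_peptide_range = as.integer(contaminant_peptide_range),
      seed = as.integer(seed)
    ),
    class = "apms_sim_config"
  )
}

# sample() with a length-1 x samples 1:x; guard the degenerate range
sample_int_range <- function(a, b, n) {
  if (a == b) rep(as.integer(a), n) else sample(seq.int(a, b), n, replace = TRUE)
}

random_peptide_seqs <- function(n, min_len = 8L, max_len = 15L) {
  if (!n) return(character())
  lens <- sample_int_range(min_len, max_len, n)
  draw <- function(lens) {
    letters_all <- sample(AA_LETTERS[1:20], sum(lens), replace = TRUE)
    vapply(split(letters_all, rep.int(seq_along(lens), lens)),
           paste, character(1), collapse = "")
  }
  seqs <- draw(lens)
  while (anyDuplicated(seqs)) {
    dup <- duplicated(seqs)
    seqs[dup] <- draw(lens[dup])
  }
  seqs
}

sim_records <- function(accessions, descriptions, score_range, coverage_range,
                        peptide_range, meanlog, sdlog) {
  n <- length(accessions)
  if (!n) {
    return(tibble(accession = character(), description = character(),
                  score = numeric(), coverage = numeric(), peptides = list()))
  }
  n_pep <- sample_int_range(peptide_range[1], peptide_range[2], n)
  # one batched draw for all peptides of the run, then split per record
  grp <- rep.int(seq_len(n), n_pep)
  seqs <- split(random_peptide_seqs(sum(n_pep)), grp)
  areas <- split(rlnorm(sum(n_pep), meanlog = meanlog, sdlog = sdlog), grp)
  tibble(
    accession = accessions,
    description = descriptions,
    score = runif(n, score_range[1], score_range[2]),
    coverage = runif(n, coverage_range[1], coverage_range[2]),
    peptides = unname(purrr::map2(seqs, areas, function(s, a)
      tibble::new_tibble(list(sequence = unname(s), area = unname(a)),
                         nrow = length(s))))
  )
}

#' Simulate a spike-in AP-MS experiment with known ground truth
#'
#' Generates one bait pull-down (bait + true interactors + the full
#' contaminant pool), `n_control_runs` negative-control runs (each contaminant
#' present in each control independently with the configured probability, with
#' freshly drawn scores/areas per run), and the ground truth. The bait's
#' peptide areas are set after all other draws so that its T3PQ mean area
#' strictly exceeds every other protein's — in a clean pull-down the bait is
#' the most abundant precipitated protein.
#'
#' The same configuration (including `cfg$seed`) always yields identical
#' output.
#'
#' @param cfg An [apms_sim_config()].
#' @return A list with elements `bait_run` ([pulldown_run()]), `controls`
#'   (list of control runs) and `truth` (list: `bait_accession`,
#'   `true_interactor_accessions`, `contaminant_accessions`).
#' @export
generate_apms_experiment <- function(cfg = apms_sim_config()) {
  if (!inherits(cfg, "apms_sim_config")) {
    stop_contract("`cfg` must be an apms_sim_config", "coprecip_config_error")
  }
  set.seed(cfg$seed)
  bait_acc <- "BAIT_GFP"
  true_acc <- if (cfg$n_true_interactors)
    sprintf("TRUE_%03d", seq_len(cfg$n_true_interactors)) else character()
  cont_acc <- if (cfg$n_contaminants)
    sprintf("CONT_%03d", seq_len(cfg$n_contaminants)) else character()

  true_rec <- sim_records(
    true_acc, paste("true interactor", seq_along(true_acc)),
    cfg$true_score_range, cfg$true_coverage_range, cfg$true_peptide_range,
    cfg$true_abundance_meanlog, cfg$true_abundance_sdlog
  )
  cont_rec <- sim_records(
    cont_acc, paste("background contaminant", seq_along(cont_acc)),
    cfg$contaminant_score_range, cfg$contaminant_coverage_range,
    cfg$contaminant_peptide_range,
    cfg$contaminant_abundance_meanlog, cfg$contaminant_abundance_sdlog
  )
  others <- dplyr::bind_rows(true_rec, cont_rec)
  max_t3pq <- if (nrow(others))
    max(vapply(others$peptides, function(p) as.numeric(t3pq(p$area)), numeric(1)))
  else exp(cfg$true_abundance_meanlog)
  bait_rec <- sim_records(
    bait_acc, "GFP-tagged bait",
    cfg$true_score_range, cfg$true_coverage_range, cfg$true_peptide_range,
    cfg$true_abundance_meanlog, cfg$true_abundance_sdlog
  )
  # pin the bait to the top of the abundance ranking
  bait_rec$peptides[[1]]$area <- rep(2 * max_t3pq, nrow(bait_rec$peptides[[1]]))

  bait_run <- pulldown_run(
    run_id = "bait_pulldown",
    records = dplyr::bind_rows(bait_rec, true_rec, cont_rec),
    bait_accession = bait_acc,
    is_control = FALSE
  )

  controls <- lapply(seq_len(cfg$n_control_runs), function(i) {
    present <- if (length(cont_acc))
      cont_acc[runif(length(cont_acc)) < cfg$contaminant_control_presence_prob]
    else character()
    rec <- sim_records(
      present, paste("background contaminant seen in control", i),
      cfg$contaminant_score_range, cfg$contaminant_coverage_range,
      cfg$contaminant_peptide_range,
      cfg$contaminant_abundance_meanlog, cfg$contaminant_abundance_sdlog
    )
    pulldown_run(run_id = sprintf("control_%02d", i), records = rec,
                 is_control = TRUE)
  })

  list(
    bait_run = bait_run,
    controls = controls,
    truth = structure(
      list(
        bait_accession = bait_acc,
        true_interactor_accessions = true_acc,
        contaminant_accessions = cont_acc
      ),
      class = "apms_ground_truth"
    )
  )
}

#' Compare called interactors with simulator ground truth
#'
#' @param ranked A ranked `interactor_calls` tibble.
#' @param truth The `truth` element of [generate_apms_experiment()].
#' @return A one-row tibble: `n_called` (non-bait survivors), `n_true`,
#'   `true_positives`, `false_positives`, `false_negatives`, `precision`,
#'   `recall`.
#' @export
score_against_truth <- function(ranked, truth) {
  called <- setdiff(ranked$accession, truth$bait_accession)
  tp <- length(intersect(called, truth$true_interactor_accessions))
  fp <- length(setdiff(called, truth$true_interactor_accessions))
  fn <- length(setdiff(truth$true_interactor_accessions, called))
  tibble(
    n_called = length(called),
    n_true = length(truth$true_interactor_accessions),
    true_positives = tp,
    false_positives = fp,
    false_negatives = fn,
    precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(truth$true_interactor_accessions)) tp /
      length(truth$true_interactor_accessions) else NA_real_
  )
}
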