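test_that("the false-positive database is the order-independent union of control accessions", {
  expect_equal(build_false_positive_db(list())$n_control_runs, 0L)
  expect_equal(build_false_positive_db(list())$accessions, character())

  c1 <- control_with(c("A", "B"), "ctrl1")
  c2 <- control_with(c("B", "C"), "ctrl2")
  db12 <- build_false_positive_db(list(c1, c2))
  db21 <- build_false_positive_db(list(c2, c1))
  expect_equal(db12$accessions, c("A", "B", "C"))
  expect_equal(db12$accessions, db21$accessions)
  expect_equal(db12$n_control_runs, 2L)

  # union monotonicity: a DB over more runs contains the DB over a subset
  c3 <- control_with(c("D"), "ctrl3")
  db123 <- build_false_positive_db(list(c1, c2, c3))
  expect_true(all(db12$accessions %in% db123$accessions))

  bait <- toy_run(toy_record("X", 100, 50, c(1, 2)), bait = "X")
  expect_error(build_false_positive_db(list(c1, bait)),
               class = "coprecip_contract_error")
})

test_that("each of the four rules removes exactly the records it should", {
  db <- build_false_positive_db(list(control_with("E")))
  recs <- dplyr::bind_rows(
    toy_record("A", 120, 35, c(1, 2, 3, 4)),  # survives
    toy_record("B", 60, 10, c(1, 2, 3)),      # coverage < 20
    toy_record("C", 200, 40, c(9)),           # single peptide
    toy_record("D", 45, 50, c(1, 2, 3, 4, 5)),# score below cut-off
    toy_record("E", 80, 25, c(1, 2, 3))       # blacklisted
  )
  calls <- apply_stringent_filter(toy_run(recs), db)
  expect_equal(calls$accession, "A")
  audit <- attr(calls, "audit")
  expect_equal(nrow(audit), 5L)
  expect_equal(sum(audit$passed) + sum(!audit$passed), 5L)
  expect_false(audit$pass_coverage[audit$accession == "B"])
  expect_false(audit$pass_peptides[audit$accession == "C"])
  expect_false(audit$pass_score[audit$accession == "D"])
  expect_false(audit$pass_blacklist[audit$accession == "E"])
  # every rejected record fails at least one named rule
  rej <- audit[!audit$passed, ]
  expect_true(all(!rej$pass_peptides | !rej$pass_coverage |
                    !rej$pass_score | !rej$pass_blacklist))
})

test_that("a sub-cutoff score removes a record regardless of abundance", {
  # the Gem5 situation: detected with high-abundance peptides but a score
  # well below the cut-off
  recs <- toy_record("GEM5_LIKE", 30, 60, c(1e9, 1e9, 1e9))
  calls <- apply_stringent_filter(toy_run(recs),
                                  build_false_positive_db(list()))
  expect_equal(nrow(calls), 0L)
  expect_false(attr(calls, "audit")$pass_score)
})

test_that("an empty run filters to an empty call set", {
  empty <- toy_run(toy_record("Z", 1, 1, c(1))[0, ])
  calls <- apply_stringent_filter(empty, build_false_positive_db(list()))
  expect_equal(nrow(calls), 0L)
})

test_that("T3PQ is the mean of the top-3 present areas, degrading to the mean of what is available", {
  expect_equal(as.numeric(t3pq(c(5, 5, 5))), 5)
  expect_equal(as.numeric(t3pq(c(9, 3, 6, 1))), (9 + 6 + 3) / 3)
  v <- t3pq(c(8, 4))
  expect_equal(as.numeric(v), 6)
  expect_equal(attr(v, "n_used"), 2L)
  expect_equal(as.numeric(t3pq(c(NA, 7, NA))), 7)
  expect_error(t3pq(c(NA_real_, NA_real_)),
               class = "coprecip_undefined_quantity_error")
})

test_that("ranking is by descending T3PQ with score then accession tie-breaks", {
  recs <- dplyr::bind_rows(
    toy_record("A", 100, 50, c(10, 10, 10)),
    toy_record("B", 100, 50, c(30, 30, 30)),
    toy_record("C", 100, 50, c(20, 20, 20))
  )
  ranked <- call_interactors(toy_run(recs), list())
  expect_equal(ranked$accession, c("B", "C", "A"))
  expect_equal(ranked$rank, 1:3)

  # tie on T3PQ broken by descending score
  recs2 <- dplyr::bind_rows(
    toy_record("A", 50.5, 50, c(10, 10, 10)),
    toy_record("B", 70, 50, c(10, 10, 10))
  )
  ranked2 <- call_interactors(toy_run(recs2), list())
  expect_equal(ranked2$accession, c("B", "A"))

  # tie on T3PQ and score broken lexicographically
  recs3 <- dplyr::bind_rows(
    toy_record("ZZ", 70, 50, c(10, 10, 10)),
    toy_record("AA", 70, 50, c(10, 10, 10))
  )
  ranked3 <- call_interactors(toy_run(recs3), list())
  expect_equal(ranked3$accession, c("AA", "ZZ"))

  single <- call_interactors(toy_run(toy_record("S", 70, 50, c(1, 2))), list())
  expect_equal(single$rank, 1L)
})

test_that("verify_bait_top reports the bait rank and names the usurper", {
  recs <- dplyr::bind_rows(
    toy_record("BAIT", 100, 50, c(100, 100, 100)),
    toy_record("PREY", 100, 50, c(10, 10, 10))
  )
  ranked <- call_interactors(toy_run(recs, bait = "BAIT"), list())
  chk <- verify_bait_top(ranked, "BAIT")
  expect_true(chk$ok)
  expect_equal(chk$bait_rank, 1L)

  chk2 <- verify_bait_top(ranked, "PREY")
  expect_false(chk2$ok)
  expect_equal(chk2$top_accession, "BAIT")
  expect_error(verify_bait_top(ranked, "ABSENT"),
               class = "coprecip_absent_bait_error")
})

test_that("pipeline output equals an independent brute-force re-implementation", {
  set.seed(99)
  thresholds <- filter_thresholds()
  blacklist_pool <- sprintf("BL%03d", 1:20)
  db <- build_false_positive_db(list(control_with(blacklist_pool)))
  for (i in 1:25) {
    run <- random_run(sample(0:50, 1), blacklist_pool)
    got <- suppressWarnings(
      rank_interactors(apply_stringent_filter(run, db, thresholds))
    )
    want <- brute_force_pipeline(run, db$accessions, thresholds)
    expect_equal(got$accession, want$accession)
    expect_equal(got$t3pq_mean_area, want$t3pq, tolerance = 1e-12)
    expect_equal(got$rank, want$rank)
  }
})

test_that("raising any threshold never adds survivors (threshold monotonicity)", {
  set.seed(123)
  db <- build_false_positive_db(list(control_with(sprintf("BL%03d", 1:10))))
  run <- random_run(40, sprintf("BL%03d", 1:10))
  base <- apply_stringent_filter(run, db, filter_thresholds())
  for (t in list(filter_thresholds(min_distinct_peptides = 3),
                 filter_thresholds(min_coverage = 40),
                 filter_thresholds(min_score_exclusive = 120))) {
    tighter <- apply_stringent_filter(run, db, t)
    expect_true(all(tighter$accession %in% base$accession))
  }
})

test_that("adding a control run never enlarges the survivor set (blacklist monotonicity)", {
  set.seed(7)
  pool <- sprintf("BL%03d", 1:30)
  run <- random_run(40, pool)
  ctrls <- list(control_with(pool[1:10], "c1"), control_with(pool[11:20], "c2"))
  s2 <- apply_stringent_filter(run, build_false_positive_db(ctrls))
  s3 <- apply_stringent_filter(
    run, build_false_positive_db(c(ctrls, list(control_with(pool[21:30], "c3"))))
  )
  expect_true(all(s3$accession %in% s2$accession))
})

test_that("tidy and glance summarise a ranked call set", {
  sim <- generate_apms_experiment(apms_sim_config(
    n_true_interactors = 5, n_contaminants = 20, n_control_runs = 3, seed = 5
  ))
  ranked <- call_interactors(sim$bait_run, sim$controls)
  td <- tidy(ranked)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("rank", "accession", "description", "score", "coverage",
                     "n_peptides", "t3pq_mean_area", "t3pq_n_used", "is_bait"))
  gl <- glance(ranked)
  expect_equal(gl$n_survivors, nrow(ranked))
  expect_equal(gl$n_specific_interactors, sum(!ranked$is_bait))
  expect_equal(gl$bait_rank, 1L)
  expect_s3_class(autoplot(ranked), "ggplot")
})
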