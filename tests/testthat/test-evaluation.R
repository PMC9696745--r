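truth_for <- function(records, correct_ids) {
  tibble::tibble(local_code_id = records$local_code_id,
                 true_loinc = ifelse(records$local_code_id %in% correct_ids,
                                     records$mapped_loinc, "L-OTHER"))
}

test_that("precision counts accepted-and-correct mappings", {
  recs <- fake_records(c(-6, -6, -6, -6, -1, -1))
  truth <- truth_for(recs, recs$local_code_id[c(1, 2, 5)])
  p <- precision_at_cutoff(recs, truth, -5)
  expect_equal(p$n_accepted, 4)
  expect_equal(p$precision, 0.5)

  p_all <- precision_at_cutoff(recs, truth, Inf)
  expect_equal(p_all$n_accepted, 6)
  expect_equal(p_all$precision, 0.5)

  p_none <- precision_at_cutoff(recs, truth, -100)
  expect_equal(p_none$n_accepted, 0)
  expect_true(is.na(p_none$precision))

  all_correct <- truth_for(recs, recs$local_code_id)
  expect_equal(precision_at_cutoff(recs, all_correct, Inf)$precision, 1)

  expect_error(precision_at_cutoff(recs, truth[-1, ], -5),
               class = "loincmap_error_evaluation")
})

test_that("separation test detects perfectly split z-scores", {
  set.seed(61)
  recs <- fake_records(c(rnorm(8, -6, 0.2), rnorm(8, 0, 0.2)))
  truth <- truth_for(recs, recs$local_code_id[1:8])
  res <- zscore_separation_test(recs, truth)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$n_correct, 8)

  res_t <- zscore_separation_test(recs, truth, method = "t")
  expect_lt(res_t$p_value, 0.001)

  all_correct <- truth_for(recs, recs$local_code_id)
  expect_error(zscore_separation_test(recs, all_correct),
               class = "loincmap_error_evaluation")
})

test_that("repeated evaluation is reproducible and collapses correctly at n_runs = 1", {
  sc <- tiny_scenario(seed = 13)
  ev1 <- suppressMessages(run_repeated_evaluation(
    sc$query, sc$reference, sc$truth, cutoffs = c(-4, -2, 0),
    n_runs = 1, master_seed = 6, sample_size = 200))
  expect_equal(ev1$averaged$mean_precision,
               ev1$per_run$precision[match(ev1$averaged$cutoff, ev1$per_run$cutoff)])

  ev2 <- suppressMessages(run_repeated_evaluation(
    sc$query, sc$reference, sc$truth, cutoffs = c(-4, -2, 0),
    n_runs = 3, master_seed = 6, sample_size = 200))
  ev3 <- suppressMessages(run_repeated_evaluation(
    sc$query, sc$reference, sc$truth, cutoffs = c(-4, -2, 0),
    n_runs = 3, master_seed = 6, sample_size = 200))
  expect_identical(ev2$per_run, ev3$per_run)
  expect_identical(ev2$averaged, ev3$averaged)

  g <- glance(ev2)
  expect_equal(g$n_runs, 3)
  td <- tidy(ev2)
  expect_true(all(c("cutoff", "mean_precision", "mean_n_accepted") %in% names(td)))
})

test_that("evaluation and mapping plots build without error", {
  sc <- tiny_scenario(seed = 17)
  ev <- suppressMessages(run_repeated_evaluation(
    sc$query, sc$reference, sc$truth, cutoffs = c(-4, -2, 0),
    n_runs = 2, master_seed = 2, sample_size = 200))
  p1 <- autoplot(ev)
  expect_s3_class(p1, "ggplot")
  m <- suppressMessages(loinc_map(sc$query, sc$reference, sample_size = 200,
                                  master_seed = 2))
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(m, truth = sc$truth), "ggplot")
  expect_s3_class(plot_zscore_separation(m, sc$truth), "ggplot")
})
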