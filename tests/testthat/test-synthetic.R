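test_that("scenario generation is reproducible and truth covers every code once", {
  cfg <- make_confusable_panel(5, overlap = 0.5, seed = 3,
                               n_reference = 150, n_query = 120)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$query, b$query)
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth, b$truth)

  expect_equal(sort(a$truth$local_code_id), sort(unique(a$query$code_id)))
  expect_false(anyDuplicated(a$truth$local_code_id) > 0)
  expect_equal(sum(a$query$code_id == a$truth$local_code_id[1]), 120)
  expect_equal(sum(a$reference$code_id == a$truth$true_loinc[1]), 150)
})

test_that("unmapped_fraction withholds exactly the stated share of LOINCs", {
  cfg <- make_confusable_panel(10, overlap = 0, seed = 5,
                               n_reference = 80, n_query = 80,
                               unmapped_fraction = 0.3)
  sc <- generate_scenario(cfg)
  missing_loincs <- setdiff(sc$truth$true_loinc, unique(sc$reference$code_id))
  expect_length(missing_loincs, 3)
  expect_setequal(missing_loincs, sc$withheld)
  # withheld codes still have query observations and truth entries
  withheld_local <- sc$truth$local_code_id[sc$truth$true_loinc %in% sc$withheld]
  expect_true(all(withheld_local %in% sc$query$code_id))
})

test_that("confusable panels hit their limit cases", {
  cfg1 <- make_confusable_panel(4, overlap = 1, seed = 1)
  expect_true(all(purrr::map_dbl(cfg1$specs$params, "mean") == 0))
  cfg2 <- make_confusable_panel(2, overlap = 0.4, seed = 1)
  expect_equal(nrow(cfg2$specs), 2)
  expect_error(make_confusable_panel(1, overlap = 0),
               class = "loincmap_error_config")

  # overlap 0: reference eCDFs essentially disjoint
  sc <- generate_scenario(make_confusable_panel(6, overlap = 0, seed = 2,
                                                n_reference = 1000,
                                                n_query = 1000))
  re <- build_ecdf_set(sc$reference, sample_size = 1000, master_seed = 1)
  D <- build_distance_matrix(re, re)
  off_diag <- D[upper.tri(D)]
  expect_gt(mean(off_diag), 0.9)
})

test_that("all distribution families draw valid values", {
  specs <- dplyr::bind_rows(
    code_spec("L-norm", "normal", list(mean = 140, sd = 4), 200, 200),
    code_spec("L-lnorm", "lognormal", list(meanlog = 3, sdlog = 0.4), 200, 200),
    code_spec("L-gamma", "gamma", list(shape = 2, rate = 0.5), 200, 200),
    code_spec("L-unif", "uniform", list(min = 0, max = 10), 200, 200),
    code_spec("L-pois", "discrete", list(lambda = 6), 200, 200))
  sc <- generate_scenario(scenario_config(specs, seed = 8))
  expect_true(all(is.finite(sc$reference$value)))
  pois_vals <- sc$reference$value[sc$reference$code_id == "L-pois"]
  expect_true(all(pois_vals == round(pois_vals)))
  gamma_vals <- sc$reference$value[sc$reference$code_id == "L-gamma"]
  expect_true(all(gamma_vals > 0))

  expect_error(code_spec("bad", "normal", list(mean = 0, sd = -1)),
               class = "loincmap_error_config")
  expect_error(code_spec("bad", "uniform", list(min = 2, max = 1)),
               class = "loincmap_error_config")
  expect_error(code_spec("bad", "gamma", list(shape = 1)),
               class = "loincmap_error_config")
})

test_that("query shift preserves the family center and discrete ties", {
  specs <- code_spec("L-pois", "discrete", list(lambda = 20), 3000, 3000)
  sc <- generate_scenario(scenario_config(
    specs, query_shift = list(location_sd = 0.03, scale = 1.02), seed = 4))
  expect_true(all(sc$query$value == round(sc$query$value)))
  expect_lt(abs(mean(sc$query$value) - 20), 1)
})

test_that("confuser pairs force near-identical parameters", {
  specs <- dplyr::bind_rows(
    code_spec("LA", "normal", list(mean = 10, sd = 2), 300, 300),
    code_spec("LB", "normal", list(mean = 50, sd = 1), 300, 300))
  cfg <- scenario_config(specs, confuser_pairs = tibble::tibble(
    loinc_a = "LA", loinc_b = "LB"), seed = 6)
  sc <- generate_scenario(cfg)
  mb <- mean(sc$reference$value[sc$reference$code_id == "LB"])
  expect_lt(abs(mb - 10), 1)  # LB moved next to LA
})

test_that("generator is self-consistent: query matches reference per code", {
  sc <- generate_scenario(make_confusable_panel(20, overlap = 0, seed = 9,
                                                n_reference = 1000,
                                                n_query = 1000))
  pvals <- purrr::map_dbl(seq_len(nrow(sc$truth)), function(i) {
    q <- sc$query$value[sc$query$code_id == sc$truth$local_code_id[i]]
    r <- sc$reference$value[sc$reference$code_id == sc$truth$true_loinc[i]]
    suppressWarnings(stats::ks.test(q, r))$p.value
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("YAML scenario configs round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 12",
    "unmapped_fraction: 0.0",
    "query_shift:",
    "  location_sd: 0.01",
    "  scale: 1.0",
    "specs:",
    "  - loinc: 'L1'",
    "    family: normal",
    "    params: {mean: 0, sd: 1}",
    "    n_reference: 100",
    "    n_query: 100",
    "  - loinc: 'L2'",
    "    family: discrete",
    "    params: {lambda: 4}",
    "    n_reference: 100",
    "    n_query: 100"), f)
  cfg <- read_scenario_config(f)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$specs$loinc, c("L1", "L2"))
  expect_equal(cfg$query_shift$location_sd, 0.01)
  sc <- generate_scenario(cfg)
  expect_equal(nrow(sc$truth), 2)
})
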