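test_that("zscore_row standardizes exactly and respects the divisor choice", {
  expect_equal(zscore_row(c(0.1, 0.5, 0.9)), c(-1, 0, 1))

  set.seed(21)
  for (i in 1:20) {
    row <- runif(sample(2:40, 1))
    z <- zscore_row(row)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
    # affine invariance: shift and positive rescale leave z untouched
    expect_equal(zscore_row(3.7 * row + 0.2), z, tolerance = 1e-12)
  }

  # population divisor shrinks the sd by sqrt((n-1)/n)
  row <- c(0.1, 0.5, 0.9)
  expect_equal(zscore_row(row, sd_divisor = "n"),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  expect_error(zscore_row(c(0.3, 0.3, 0.3)), class = "loincmap_error_degenerate")
  expect_error(zscore_row(0.3), class = "loincmap_error_contract")
})

test_that("map_and_score picks the argmin and applies the strict cutoff", {
  D <- matrix(c(0.05, 0.60, 0.62, 0.61), nrow = 1,
              dimnames = list("C1", c("L1", "L2", "L3", "L4")))
  rec <- map_and_score(D, cutoff = -1)
  expect_equal(rec$mapped_loinc, "L1")
  expect_equal(rec$ks_distance, 0.05)
  expect_lt(rec$z_score, -1)
  expect_true(rec$accepted)

  # argmin property against brute force on random matrices
  set.seed(7)
  Dr <- matrix(runif(60, 0.1, 1), nrow = 6,
               dimnames = list(sprintf("C%d", 1:6), sprintf("L%02d", 1:10)))
  recs <- map_and_score(Dr)
  for (i in 1:6) {
    expect_equal(recs$ks_distance[i], min(Dr[i, ]))
    expect_true(all(Dr[i, recs$mapped_loinc[i]] <= Dr[i, ]))
    expect_equal(recs$z_score[i], zscore_row(Dr[i, ])[[recs$mapped_loinc[i]]])
  }

  expect_error(map_and_score(Dr[, 1, drop = FALSE]),
               class = "loincmap_error_contract")
})

test_that("tied minima break toward the lexicographically smaller LOINC", {
  D <- matrix(c(0.5, 0.2, 0.9, 0.2, 0.8), nrow = 1,
              dimnames = list("C1", c("L9", "L5", "L2", "L3", "L1")))
  expect_message(rec <- map_and_score(D), class = "loincmap_msg_ties")
  expect_equal(rec$mapped_loinc, "L3")
  expect_true(rec$tie)
})

test_that("constant rows are unmappable but never crash", {
  D <- matrix(c(0.3, 0.3, 0.3, 0.1, 0.5, 0.9), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "ok"), c("L1", "L2", "L3")))
  recs <- map_and_score(D, cutoff = -0.5)
  expect_true(is.na(recs$z_score[recs$local_code_id == "flat"]))
  expect_false(recs$accepted[recs$local_code_id == "flat"])
  expect_true(recs$accepted[recs$local_code_id == "ok"])
})

test_that("a +Inf cutoff accepts every mapping with a defined z-score", {
  set.seed(3)
  D <- matrix(runif(30, 0.1, 1), nrow = 3,
              dimnames = list(sprintf("C%d", 1:3), sprintf("L%02d", 1:10)))
  recs <- map_and_score(D, cutoff = Inf)
  expect_true(all(recs$accepted))
})

test_that("acceptance is monotone along the cutoff grid", {
  set.seed(14)
  recs <- fake_records(rnorm(40, -3, 2))
  grid <- c(-6, -3, 0)
  curve <- acceptance_curve(recs, grid)
  expect_true(all(diff(curve$n_accepted) >= 0))
  expect_equal(acceptance_curve(recs, -100)$n_accepted, 0L)
  expect_equal(acceptance_curve(recs, 100)$n_accepted, 40L)

  # accepted sets are nested, not merely growing in count
  sets <- lapply(grid, function(co) {
    r <- apply_cutoff(recs, co)
    r$local_code_id[r$accepted]
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))

  expect_error(acceptance_curve(recs, c(0, -1)),
               class = "loincmap_error_contract")
})

test_that("glance() summarises a mapping run", {
  recs <- fake_records(c(-6, -2, NA))
  g <- glance(recs)
  expect_equal(g$n_query, 3)
  expect_equal(g$n_accepted, 1)
  expect_equal(g$n_degenerate, 1)
})
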