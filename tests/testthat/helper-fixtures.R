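# Shared fixture builders; everything is generated in code at test time.

write_temp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A small mapping-record tibble with chosen z-scores and truth labels.
fake_records <- function(z, mapped = NULL, ids = NULL) {
  n <- length(z)
  ids <- ids %||% sprintf("C%02d", seq_len(n))
  mapped <- mapped %||% sprintf("L%02d", seq_len(n))
  out <- tibble::tibble(local_code_id = ids, mapped_loinc = mapped,
                        ks_distance = rep(0.1, n), z_score = z,
                        accepted = !is.na(z) & z < -5, tie = FALSE)
  attr(out, "cutoff") <- -5
  attr(out, "n_reference") <- 10L
  class(out) <- c("loinc_mapping", class(out))
  out
}

# Independent dense-grid oracle for the KS statistic: evaluate both eCDFs on
# a fine grid spanning the supports (plus the support points themselves) and
# take the max absolute difference.
ks_grid_oracle <- function(x, y, n_grid = 20000) {
  fa <- stats::ecdf(x)
  fb <- stats::ecdf(y)
  lo <- min(x, y) - 1
  hi <- max(x, y) + 1
  g <- sort(c(seq(lo, hi, length.out = n_grid), x, y))
  max(abs(fa(g) - fb(g)))
}

# A tiny two-site scenario for fast pipeline tests.
tiny_scenario <- function(seed = 42, k = 6, n = 400) {
  generate_scenario(make_confusable_panel(k, overlap = 0, seed = seed,
                                          n_reference = n, n_query = n))
}
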