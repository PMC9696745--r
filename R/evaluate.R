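# Evaluation at desk scale: precision against a truth table along a cutoff
# grid, repeated-run averaged curves (sampling is stochastic, so single runs
# are noisy), and the correct-vs-incorrect z-score separation test.

#' Precision of accepted mappings at a cutoff
#'
#' Accepted means `z_score < cutoff` (strict); precision is the fraction of
#' accepted mappings whose LOINC equals the truth entry. With zero accepted
#' mappings the ratio is undefined and reported as `NA`, never 0 or 1.
#'
#' @param records A `loinc_mapping` tibble.
#' @param truth Truth tibble (`local_code_id`, `true_loinc`).
#' @param cutoff Z-score cutoff; `Inf` accepts every mapping.
#' @return A one-row tibble: `cutoff`, `n_accepted`, `n_correct`,
#'   `precision`.
#' @export
precision_at_cutoff <- function(records, truth, cutoff) {
  missing_codes <- setdiff(records$local_code_id, truth$local_code_id)
  if (length(missing_codes) > 0) {
    stop_evaluation(paste0("local code(s) absent from truth table: ",
                           paste(head(missing_codes, 5), collapse = ", ")))
  }
  joined <- dplyr::left_join(records, truth, by = "local_code_id")
  acc <- !is.na(joined$z_score) & joined$z_score < cutoff
  if (is.infinite(cutoff) && cutoff > 0) acc <- rep(TRUE, nrow(joined))
  n_acc <- sum(acc)
  n_cor <- sum(acc & joined$mapped_loinc == joined$true_loinc)
  tibble::tibble(cutoff = as.numeric(cutoff), n_accepted = n_acc,
                 n_correct = n_cor,
                 precision = if (n_acc > 0) n_cor / n_acc else NA_real_)
}

#' One-sided separation test of correct vs incorrect mapping z-scores
#'
#' Tests whether the z-scores of correct mappings are located below those of
#' incorrect mappings (a correct best match should be an outlier among its
#' candidates). Default is the one-sided Wilcoxon rank-sum test; a Welch
#' t-test variant is available.
#'
#' @param records A `loinc_mapping` tibble.
#' @param truth Truth tibble (`local_code_id`, `true_loinc`).
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return A one-row tibble: `statistic`, `p_value`, `n_correct`,
#'   `n_incorrect`, `method`.
#' @export
zscore_separation_test <- function(records, truth,
                                   method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  joined <- dplyr::left_join(records, truth, by = "local_code_id")
  joined <- joined[!is.na(joined$z_score) & !is.na(joined$true_loinc), ]
  correct <- joined$mapped_loinc == joined$true_loinc
  z_cor <- joined$z_score[correct]
  z_inc <- joined$z_score[!correct]
  if (length(z_cor) == 0 || length(z_inc) == 0) {
    stop_evaluation("separation undefined: need at least one correct and one incorrect mapping")
  }
  if (method == "wilcoxon") {
    ht <- suppressWarnings(wilcox.test(z_cor, z_inc, alternative = "less"))
  } else {
    ht <- t.test(z_cor, z_inc, alternative = "less")
  }
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_correct = length(z_cor), n_incorrect = length(z_inc),
                 method = method)
}

#' Repeated-run precision-vs-cutoff evaluation
#'
#' Runs the full pipeline `n_runs` times on fixed query/reference tables;
#' run `r` resamples every code on a sub-seed derived from
#' `(master_seed, r)`, so the report is reproducible from `master_seed`
#' alone. Precision and acceptance counts are evaluated along `cutoffs`
#' (with `Inf` appended, the accept-everything regime), and the averaged
#' curve is the arithmetic mean over runs — precision averages over the
#' runs where it is defined.
#'
#' @param query,reference Lab-event tibbles.
#' @param truth Truth tibble covering every query code.
#' @param cutoffs Strictly increasing z-score grid (default `-8 ... 0` by
#'   0.5).
#' @param n_runs Number of repeated runs (default 30).
#' @param master_seed Master seed.
#' @param sample_size Readings per code and run (default 1000).
#' @param sd_divisor Passed to [map_and_score()].
#' @param separation_method Passed to [zscore_separation_test()].
#' @return A `loinc_eval` object: list with `per_run` (run, cutoff,
#'   n_accepted, n_correct, precision), `averaged` (cutoff, mean_precision,
#'   mean_n_accepted), `separation` (per-run test results), `n_runs`,
#'   `cutoffs`.
#' @export
run_repeated_evaluation <- function(query, reference, truth,
                                    cutoffs = seq(-8, 0, by = 0.5),
                                    n_runs = 30, master_seed = 1,
                                    sample_size = 1000,
                                    sd_divisor = "n_minus_1",
                                    separation_method = "wilcoxon") {
  if (n_runs < 1) stop_contract("n_runs must be >= 1")
  if (any(diff(cutoffs) <= 0)) stop_contract("cutoff grid must be strictly increasing")
  grid <- c(cutoffs, Inf)
  runs <- purrr::map(seq_len(n_runs), function(r) {
    seed_r <- run_seed(master_seed, r)
    recs <- suppressWarnings(loinc_map(query, reference,
                                       sample_size = sample_size,
                                       master_seed = seed_r,
                                       sd_divisor = sd_divisor))
    prec <- dplyr::bind_rows(purrr::map(grid, ~ precision_at_cutoff(recs, truth, .x)))
    prec$run <- r
    sep <- tryCatch(zscore_separation_test(recs, truth, method = separation_method),
                    loincmap_error_evaluation = function(e) {
                      tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                                     n_correct = NA_integer_,
                                     n_incorrect = NA_integer_,
                                     method = separation_method)
                    })
    sep$run <- r
    list(prec = prec, sep = sep)
  })
  per_run <- dplyr::relocate(dplyr::bind_rows(purrr::map(runs, "prec")), "run")
  averaged <- dplyr::summarise(
    dplyr::group_by(per_run, .data$cutoff),
    mean_precision = if (all(is.na(.data$precision))) NA_real_
                     else mean(.data$precision, na.rm = TRUE),
    mean_n_accepted = mean(.data$n_accepted),
    n_runs_defined = sum(!is.na(.data$precision)),
    .groups = "drop")
  structure(list(per_run = per_run, averaged = averaged,
                 separation = dplyr::relocate(dplyr::bind_rows(purrr::map(runs, "sep")), "run"),
                 n_runs = n_runs, cutoffs = grid,
                 master_seed = master_seed, sample_size = sample_size),
            class = "loinc_eval")
}

#' @export
print.loinc_eval <- function(x, ...) {
  cat("<loinc_eval> ", x$n_runs, " run(s), ", length(x$cutoffs),
      " cutoff(s)\n", sep = "")
  print(x$averaged)
  invisible(x)
}

#' Tidy the averaged precision curve of an evaluation
#'
#' @param x A `loinc_eval` object.
#' @param ... Unused.
#' @return The averaged tibble (`cutoff`, `mean_precision`,
#'   `mean_n_accepted`, `n_runs_defined`).
#' @method tidy loinc_eval
#' @export
tidy.loinc_eval <- function(x, ...) x$averaged

#' One-row summary of an evaluation
#'
#' @param x A `loinc_eval` object.
#' @param ... Unused.
#' @return A one-row tibble: run count, the accept-everything precision,
#'   the best mean precision on the finite grid and its cutoff, and the
#'   median separation p-value.
#' @method glance loinc_eval
#' @export
glance.loinc_eval <- function(x, ...) {
  av <- x$averaged
  fin <- av[is.finite(av$cutoff) & !is.na(av$mean_precision), ]
  best <- if (nrow(fin) > 0) fin[which.max(fin$mean_precision), ] else NULL
  tibble::tibble(
    n_runs = x$n_runs,
    precision_all_accepted = av$mean_precision[is.infinite(av$cutoff)],
    best_mean_precision = if (!is.null(best)) best$mean_precision else NA_real_,
    best_cutoff = if (!is.null(best)) best$cutoff else NA_real_,
    median_separation_p = stats::median(x$separation$p_value, na.rm = TRUE)
  )
}
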