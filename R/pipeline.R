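# End-to-end convenience: lab-event tables in, mapping records out.

#' Map local codes to LOINC by distributional similarity
#'
#' Runs the full pipeline: sample up to `sample_size` readings per code from
#' each table (Step I), build the per-code eCDFs and the query-by-reference
#' KS distance matrix (Step II), then assign each local code to its
#' minimum-distance LOINC and accept the mapping when the row z-score at the
#' minimum falls below `cutoff` (Step III).
#'
#' @param query,reference Lab-event tibbles (`code_id`, `value`); the
#'   reference may instead be a precomputed eCDF set from
#'   [build_ecdf_set()] or [read_reference_ecdfs()].
#' @param sample_size Readings drawn per code (default 1000).
#' @param cutoff Acceptance cutoff on the z-score (default -5).
#' @param master_seed Master seed driving all per-code sampling streams.
#' @param sd_divisor Passed to [zscore_row()].
#' @return A `loinc_mapping` tibble; see [map_and_score()].
#' @export
#' @examples
#' sc <- generate_scenario(make_confusable_panel(4, overlap = 0, seed = 7,
#'                                               n_reference = 300, n_query = 300))
#' loinc_map(sc$query, sc$reference, sample_size = 200, master_seed = 7)
loinc_map <- function(query, reference, sample_size = 1000, cutoff = -5,
                      master_seed = 0, sd_divisor = "n_minus_1") {
  qe <- build_ecdf_set(query, sample_size = sample_size,
                       master_seed = master_seed, stream = "query")
  re <- if (is.data.frame(reference) && "ecdf" %in% names(reference)) {
    reference
  } else {
    build_ecdf_set(reference, sample_size = sample_size,
                   master_seed = master_seed, stream = "reference")
  }
  D <- build_distance_matrix(qe, re)
  map_and_score(D, cutoff = cutoff, sd_divisor = sd_divisor)
}
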