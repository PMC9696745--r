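# Ensemble rule combining the distribution-based mapping with an external
# text-based mapper's candidates: trust the distribution-based candidate B
# when the external candidate R agrees with it, or when B's z-score is
# confidently low; otherwise defer to R.

#' Combine distribution-based and external candidate mappings
#'
#' Per local code, with distribution-based candidate `B` (and its z-score)
#' and external candidate `R`:
#' \itemize{
#'   \item `B == R` — choose `B`, branch `agree`;
#'   \item otherwise, if `z(B) < z_cutoff` — choose `B`, branch
#'     `bglm_confident`;
#'   \item otherwise — choose `R`, branch `external_default`.
#' }
#' A code present in only one source keeps that source's candidate, branch
#' `bglm_only` or `external_only`: a practical mapper always emits its best
#' available answer, and the branch label preserves auditability. A missing
#' z-score (degenerate row) never counts as confident.
#'
#' @param bglm A `loinc_mapping` tibble ([map_and_score()]).
#' @param external A candidate tibble with columns `local_code_id`,
#'   `candidate_loinc` ([read_candidate_mappings()]).
#' @param z_cutoff Confidence cutoff on the z-score of `B` (default -3.80;
#'   an operating point fitted to one dataset pair, so expect to re-tune).
#' @return A tibble with columns `local_code_id`, `bglm_candidate`,
#'   `external_candidate`, `z_score`, `chosen`, `branch`.
#' @export
#' @examples
#' b <- tibble::tibble(local_code_id = c("C1", "C2"),
#'                     mapped_loinc = c("L1", "L2"),
#'                     ks_distance = c(0.05, 0.07),
#'                     z_score = c(-4.1, -2.0), accepted = c(TRUE, FALSE))
#' r <- tibble::tibble(local_code_id = c("C1", "C2"),
#'                     candidate_loinc = c("L9", "L9"))
#' ensemble_combine(b, r)
ensemble_combine <- function(bglm, external, z_cutoff = -3.80) {
  b <- tibble::tibble(local_code_id = bglm$local_code_id,
                      bglm_candidate = bglm$mapped_loinc,
                      z_score = bglm$z_score)
  r <- tibble::tibble(local_code_id = external$local_code_id,
                      external_candidate = external$candidate_loinc)
  both <- dplyr::full_join(b, r, by = "local_code_id")
  decide <- function(bc, ec, z) {
    if (is.na(bc)) return(c(ec, "external_only"))
    if (is.na(ec)) return(c(bc, "bglm_only"))
    if (bc == ec) return(c(bc, "agree"))
    if (!is.na(z) && z < z_cutoff) return(c(bc, "bglm_confident"))
    c(ec, "external_default")
  }
  dec <- purrr::pmap(list(both$bglm_candidate, both$external_candidate,
                          both$z_score), decide)
  both$chosen <- purrr::map_chr(dec, 1)
  both$branch <- factor(purrr::map_chr(dec, 2),
                        levels = c("agree", "bglm_confident",
                                   "external_default", "bglm_only",
                                   "external_only"))
  dplyr::select(both, "local_code_id", "bglm_candidate",
                "external_candidate", "z_score", "chosen", "branch")
}

#' Write ensemble decisions to CSV
#'
#' @param decisions Tibble from [ensemble_combine()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_results <- function(decisions, path) {
  if (is.null(decisions) || nrow(decisions) == 0) {
    stop_contract("write_ensemble_results: empty decision list")
  }
  out <- dplyr::arrange(decisions, .data$local_code_id)
  out$branch <- as.character(out$branch)
  tryCatch(readr::write_csv(out, path, progress = FALSE),
           error = function(e) stop_io(paste0("cannot write ", path, ": ",
                                              conditionMessage(e))))
  invisible(path)
}
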