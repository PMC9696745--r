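# Steps II-III: argmin mapping per local code, row-wise z-score
# standardization, and cutoff-based acceptance. The cutoff on the z-score of
# the chosen (minimum-distance) candidate is the method's false-discovery
# control: a strongly negative z-score marks a best match that is an outlier
# among the candidates, i.e. a confident mapping.

#' Standardize a distance-matrix row to z-scores
#'
#' Centers and scales a row so the output has mean 0 and standard deviation
#' 1. The divisor is the sample one (`n - 1`, the default of mainstream
#' statistical environments); the population divisor `n` is available for
#' reproducing that variant.
#'
#' @param row Numeric vector, length at least 2, not constant.
#' @param sd_divisor `"n_minus_1"` (default) or `"n"`.
#' @return Numeric vector of z-scores, same length and order as `row`.
#' @export
#' @examples
#' zscore_row(c(0.1, 0.5, 0.9))  # -1 0 1
zscore_row <- function(row, sd_divisor = c("n_minus_1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  if (length(row) < 2) stop_contract("zscore_row: need at least 2 entries")
  if (!all(is.finite(row))) stop_contract("zscore_row: non-finite entries")
  centered <- row - mean(row)
  s <- sd(row)
  if (sd_divisor == "n") s <- s * sqrt((length(row) - 1) / length(row))
  if (!is.finite(s) || s == 0) {
    stop_degenerate("zscore_row: constant row, z-scores undefined")
  }
  centered / s
}

#' Map every query code to its nearest reference LOINC and score it
#'
#' For each row of the distance matrix the mapped LOINC is the argmin column;
#' the row is standardized with [zscore_row()] and the mapping is accepted
#' when the z-score at the argmin is strictly below `cutoff`. Ties at the
#' minimum are broken toward the lexicographically smallest LOINC code (and
#' counted in a message); a constant row — every reference equally distant —
#' is unmappable and yields `z_score = NA`, `accepted = FALSE`.
#'
#' @param D A `ks_dist` matrix from [build_distance_matrix()]; needs at
#'   least 2 reference columns (the z-score is undefined for a single
#'   reference).
#' @param cutoff Acceptance cutoff on the z-score (default -5).
#' @param sd_divisor Passed to [zscore_row()].
#' @return A tibble of class `loinc_mapping`, one row per query code:
#'   `local_code_id`, `mapped_loinc`, `ks_distance`, `z_score`, `accepted`,
#'   `tie`. Attributes `cutoff`, `sd_divisor` and `n_reference` record the
#'   run configuration.
#' @export
map_and_score <- function(D, cutoff = -5, sd_divisor = c("n_minus_1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  if (!inherits(D, "ks_dist") && !is.matrix(D)) {
    stop_contract("map_and_score: D must be a distance matrix")
  }
  if (ncol(D) < 2) {
    stop_contract("map_and_score: need at least 2 reference LOINCs (K >= 2)")
  }
  lo <- colnames(D)
  n_ties <- 0L
  recs <- purrr::map(seq_len(nrow(D)), function(i) {
    row <- as.numeric(D[i, ])
    m <- min(row)
    at_min <- which(row == m)
    if (length(at_min) > 1) n_ties <<- n_ties + 1L
    pick <- at_min[order(lo[at_min])[1]]
    z <- tryCatch(zscore_row(row, sd_divisor)[pick],
                  loincmap_error_degenerate = function(e) NA_real_)
    tibble::tibble(local_code_id = rownames(D)[i],
                   mapped_loinc = lo[pick],
                   ks_distance = m,
                   z_score = z,
                   accepted = !is.na(z) && z < cutoff,
                   tie = length(at_min) > 1)
  })
  if (n_ties > 0) {
    inform(paste0("map_and_score: ", n_ties,
                  " row(s) had tied minima; lexicographically smallest LOINC chosen"),
           class = "loincmap_msg_ties")
  }
  out <- dplyr::bind_rows(recs)
  attr(out, "cutoff") <- cutoff
  attr(out, "sd_divisor") <- sd_divisor
  attr(out, "n_reference") <- ncol(D)
  class(out) <- c("loinc_mapping", class(out))
  out
}

#' Re-apply an acceptance cutoff to mapping records
#'
#' @param records A `loinc_mapping` tibble.
#' @param cutoff New z-score cutoff.
#' @return The records with `accepted` recomputed and the `cutoff`
#'   attribute updated.
#' @export
apply_cutoff <- function(records, cutoff) {
  records$accepted <- !is.na(records$z_score) & records$z_score < cutoff
  attr(records, "cutoff") <- cutoff
  records
}

#' Accepted-mapping counts along a cutoff grid
#'
#' @param records A `loinc_mapping` tibble.
#' @param cutoffs Strictly increasing numeric grid of z-score cutoffs.
#' @return A tibble `(cutoff, n_accepted)`; `n_accepted` is non-decreasing
#'   in `cutoff`.
#' @export
acceptance_curve <- function(records, cutoffs) {
  if (length(cutoffs) == 0 || any(diff(cutoffs) <= 0)) {
    stop_contract("acceptance_curve: cutoff grid must be strictly increasing")
  }
  tibble::tibble(
    cutoff = as.numeric(cutoffs),
    n_accepted = purrr::map_int(cutoffs,
      ~ sum(records$z_score < .x, na.rm = TRUE))
  )
}

#' @export
print.loinc_mapping <- function(x, ...) {
  cat("<loinc_mapping> ", nrow(x), " local code(s) vs ",
      attr(x, "n_reference"), " reference LOINC(s); cutoff ",
      attr(x, "cutoff"), ", ", sum(x$accepted), " accepted\n", sep = "")
  NextMethod()
}

#' One-row summary of a mapping run
#'
#' @param x A `loinc_mapping` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_query`, `n_reference`, `cutoff`,
#'   `n_accepted`, `n_ties`, `n_degenerate`, `median_z`.
#' @method glance loinc_mapping
#' @export
glance.loinc_mapping <- function(x, ...) {
  tibble::tibble(
    n_query = nrow(x),
    n_reference = attr(x, "n_reference"),
    cutoff = attr(x, "cutoff"),
    n_accepted = sum(x$accepted),
    n_ties = sum(x$tie),
    n_degenerate = sum(is.na(x$z_score)),
    median_z = stats::median(x$z_score, na.rm = TRUE)
  )
}
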