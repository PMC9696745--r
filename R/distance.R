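# Step II: the N x K Kolmogorov-Smirnov distance matrix between query-code
# and reference-code eCDFs.

#' Two-sample Kolmogorov-Smirnov statistic between two eCDFs
#'
#' Computes `sup_x |F_a(x) - F_b(x)|` exactly by scanning the union of the
#' two supports: both eCDFs are step functions, constant between support
#' points and right-continuous, so the supremum of their absolute difference
#' is attained at a support point. Evaluating at every union point also
#' covers all left limits (the value just left of any point equals the value
#' at the preceding union point, or 0), so ties across the two samples —
#' common for discrete, integer-valued analytes — are handled exactly.
#'
#' The statistic is a metric on eCDFs, lies in `[0, 1]`, and is 0 exactly
#' when the two step functions coincide.
#'
#' @param a,b `ecdf_step` objects from [build_ecdf()].
#' @return The KS statistic, a double in `[0, 1]`.
#' @export
#' @examples
#' ks_statistic(build_ecdf(c(1, 2)), build_ecdf(c(1, 3)))  # 0.5
ks_statistic <- function(a, b) {
  if (!inherits(a, "ecdf_step") || !inherits(b, "ecdf_step")) {
    stop_contract("ks_statistic: both arguments must be ecdf_step objects")
  }
  if (length(a$support) == 0 || length(b$support) == 0) {
    stop_contract("ks_statistic: empty eCDF")
  }
  u <- sort(unique(c(a$support, b$support)))
  fa <- c(0, a$cum_prob)[findInterval(u, a$support) + 1L]
  fb <- c(0, b$cum_prob)[findInterval(u, b$support) + 1L]
  max(abs(fa - fb))
}

#' Build the query-by-reference KS distance matrix
#'
#' Entry `[i, j]` is [ks_statistic()] between query code `i` and reference
#' LOINC `j`; row and column order follow the input order of the two eCDF
#' sets.
#'
#' @param query_ecdfs,reference_ecdfs eCDF sets from [build_ecdf_set()] (or
#'   named lists of `ecdf_step`).
#' @return A numeric matrix of class `ks_dist` with query ids as rownames
#'   and LOINC codes as colnames.
#' @export
build_distance_matrix <- function(query_ecdfs, reference_ecdfs) {
  q <- as_ecdf_list(query_ecdfs)
  r <- as_ecdf_list(reference_ecdfs)
  if (length(q) == 0 || length(r) == 0) {
    stop_contract("build_distance_matrix: empty eCDF set")
  }
  D <- matrix(NA_real_, nrow = length(q), ncol = length(r),
              dimnames = list(names(q), names(r)))
  for (i in seq_along(q)) {
    for (j in seq_along(r)) D[i, j] <- ks_statistic(q[[i]], r[[j]])
  }
  structure(D, class = c("ks_dist", class(D)))
}

as_ecdf_list <- function(x) {
  if (is.data.frame(x)) {
    out <- x$ecdf
    names(out) <- x$code_id
    return(out)
  }
  if (is.list(x) && all(purrr::map_lgl(x, inherits, "ecdf_step"))) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop_contract("eCDF list must be fully named by code id")
    }
    return(x)
  }
  stop_contract("expected an eCDF set tibble or a named list of ecdf_step")
}

#' @export
print.ks_dist <- function(x, ...) {
  cat("<ks_dist> ", nrow(x), " query code(s) x ", ncol(x),
      " reference LOINC(s)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Tidy a KS distance matrix into long format
#'
#' @param x A `ks_dist` matrix.
#' @param ... Unused.
#' @return A tibble with columns `local_code_id`, `loinc`, `ks_distance`.
#' @method tidy ks_dist
#' @export
tidy.ks_dist <- function(x, ...) {
  tibble::tibble(
    local_code_id = rep(rownames(x), times = ncol(x)),
    loinc = rep(colnames(x), each = nrow(x)),
    ks_distance = as.vector(unclass(x))
  )
}
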