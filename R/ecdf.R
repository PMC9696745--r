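# Step I: per-code value sampling and empirical CDF construction.

new_ecdf_step <- function(support, cum_prob, n) {
  structure(list(support = as.numeric(support),
                 cum_prob = as.numeric(cum_prob),
                 n = as.integer(n)),
            class = "ecdf_step")
}

#' Draw a per-code value sample from a lab-event table
#'
#' Draws `n` reading values for one code, uniformly without replacement. A
#' code with fewer than `n` observations contributes all of them, with a
#' warning: the method degrades gracefully rather than excluding the code.
#' Reproducible for a fixed `seed`.
#'
#' @param events Lab-event tibble with columns `code_id`, `value`.
#' @param code_id Code to sample.
#' @param n Sample size requested (default 1000 readings).
#' @param seed Integer seed for this draw.
#' @return A `value_sample`: list with `code_id`, `values`,
#'   `sample_size_requested`, `seed`.
#' @export
#' @examples
#' ev <- tibble::tibble(code_id = "K", value = rnorm(50, 4.2, 0.4))
#' s <- draw_sample(ev, "K", n = 20, seed = 1)
#' length(s$values)
draw_sample <- function(events, code_id, n = 1000, seed = 0) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  vals <- events$value[events$code_id == code_id]
  if (length(vals) == 0) {
    stop_lookup(paste0("code '", code_id, "' absent from lab-event table"))
  }
  if (length(vals) > n) {
    vals <- withr::with_seed(seed, sample(vals, size = n, replace = FALSE))
  } else if (length(vals) < n) {
    warn(paste0("code '", code_id, "' has only ", length(vals),
                " observation(s); requested ", n, "; using all"),
         class = "loincmap_warning_undersized_code")
  }
  structure(list(code_id = code_id, values = vals,
                 sample_size_requested = as.integer(n),
                 seed = as.integer(seed)),
            class = "value_sample")
}

#' Build an empirical cumulative distribution function
#'
#' The eCDF is stored as a right-continuous step function: a strictly
#' increasing support (the distinct sample values) and the cumulative
#' probability at each support point. Tied values collapse into one support
#' point carrying the pooled probability; the last cumulative probability is
#' exactly 1.
#'
#' @param sample A `value_sample` from [draw_sample()], or a bare numeric
#'   vector of finite values.
#' @return An `ecdf_step` object.
#' @export
#' @examples
#' e <- build_ecdf(c(2, 2, 5))
#' e$support   # 2 5
#' e$cum_prob  # 2/3 1
build_ecdf <- function(sample) {
  values <- if (inherits(sample, "value_sample")) sample$values else as.numeric(sample)
  if (length(values) == 0) stop_contract("build_ecdf: empty sample")
  if (!all(is.finite(values))) stop_contract("build_ecdf: non-finite values")
  r <- rle(sort(values))
  new_ecdf_step(r$values, cumsum(r$lengths) / length(values), length(values))
}

#' Evaluate an eCDF at arbitrary points
#'
#' Right-continuous step-function evaluation: `F(x)` is the cumulative
#' probability at the largest support point not exceeding `x`, and 0 below
#' the whole support.
#'
#' @param ecdf An `ecdf_step` object.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
ecdf_eval <- function(ecdf, x) {
  stopifnot(inherits(ecdf, "ecdf_step"))
  c(0, ecdf$cum_prob)[findInterval(x, ecdf$support) + 1L]
}

#' @export
print.ecdf_step <- function(x, ...) {
  cat("<ecdf_step> ", length(x$support), " support points from sample of n = ",
      x$n, "\n", sep = "")
  cat("  range [", format(x$support[1]), ", ",
      format(x$support[length(x$support)]), "]\n", sep = "")
  invisible(x)
}

#' Build eCDFs for every code of a lab-event table
#'
#' Samples each code (default 1000 readings, without replacement) and builds
#' its eCDF. Each code draws from its own deterministic random stream derived
#' from `(master_seed, stream, code_id)`, so adding or removing a code never
#' perturbs the samples of the others.
#'
#' @param events Lab-event tibble with columns `code_id`, `value`.
#' @param sample_size Readings drawn per code (default 1000).
#' @param master_seed Master seed for the per-code streams.
#' @param codes Optional character vector restricting and ordering the codes;
#'   default: first-appearance order of `events$code_id`.
#' @param stream Label mixed into the per-code seeds, so e.g. query and
#'   reference tables sharing a code id still sample independently.
#' @return An eCDF set: tibble with columns `code_id`, `n_obs`, `n_sampled`,
#'   `ecdf` (list column of `ecdf_step`).
#' @export
build_ecdf_set <- function(events, sample_size = 1000, master_seed = 0,
                           codes = NULL, stream = "") {
  stopifnot(sample_size >= 1)
  codes <- codes %||% unique(events$code_id)
  if (length(codes) == 0) stop_contract("build_ecdf_set: no codes")
  absent <- setdiff(codes, events$code_id)
  if (length(absent) > 0) {
    stop_lookup(paste0("code(s) absent from lab-event table: ",
                       paste(head(absent, 5), collapse = ", ")))
  }
  rows <- purrr::map(codes, function(cid) {
    s <- draw_sample(events, cid, n = sample_size,
                     seed = code_seed(master_seed, paste0(stream, ":", cid)))
    tibble::tibble(code_id = cid,
                   n_obs = sum(events$code_id == cid),
                   n_sampled = length(s$values),
                   ecdf = list(build_ecdf(s)))
  })
  dplyr::bind_rows(rows)
}
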