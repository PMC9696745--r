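# Synthetic lab-event generator with known ground truth. Emulates the
# statistical structure the mapper assumes: reference codes distinguishable
# by value distribution, query observations mildly shifted/rescaled relative
# to the reference site, and a controllable fraction of query codes whose
# true LOINC is withheld from the reference panel (the necessarily-wrong
# mappings the z-score cutoff must reject).

FAMILIES <- c("normal", "lognormal", "gamma", "uniform", "discrete")

family_param_names <- list(
  normal = c("mean", "sd"),
  lognormal = c("meanlog", "sdlog"),
  gamma = c("shape", "rate"),
  uniform = c("min", "max"),
  discrete = "lambda"
)

validate_params <- function(family, params) {
  need <- family_param_names[[family]]
  if (is.null(need)) stop_config(paste0("unknown family: ", family))
  if (!all(need %in% names(params))) {
    stop_config(paste0("family '", family, "' needs params ",
                       paste(need, collapse = ", ")))
  }
  p <- params[need]
  if (!all(purrr::map_lgl(p, ~ is.numeric(.x) && is.finite(.x)))) {
    stop_config(paste0("non-numeric params for family '", family, "'"))
  }
  bad <- switch(family,
    normal = params$sd <= 0,
    lognormal = params$sdlog <= 0,
    gamma = params$shape <= 0 || params$rate <= 0,
    uniform = params$max <= params$min,
    discrete = params$lambda <= 0)
  if (bad) stop_config(paste0("invalid params for family '", family, "'"))
  invisible(TRUE)
}

family_draw <- function(family, params, n) {
  switch(family,
    normal = rnorm(n, params$mean, params$sd),
    lognormal = rlnorm(n, params$meanlog, params$sdlog),
    gamma = rgamma(n, shape = params$shape, rate = params$rate),
    uniform = runif(n, params$min, params$max),
    discrete = as.numeric(rpois(n, params$lambda)))
}

# Analytic mean of a family; the query scale perturbation acts on the
# spread around this center, not on raw magnitudes, so far-from-zero
# analytes are not dislocated.
family_mean <- function(family, params) {
  switch(family,
    normal = params$mean,
    lognormal = exp(params$meanlog + params$sdlog^2 / 2),
    gamma = params$shape / params$rate,
    uniform = (params$min + params$max) / 2,
    discrete = params$lambda)
}

# Analytic sd of a family, used to express the query location shift in
# units of the reference spread.
family_sd <- function(family, params) {
  switch(family,
    normal = params$sd,
    lognormal = sqrt((exp(params$sdlog^2) - 1) * exp(2 * params$meanlog + params$sdlog^2)),
    gamma = sqrt(params$shape) / params$rate,
    uniform = (params$max - params$min) / sqrt(12),
    discrete = sqrt(params$lambda))
}

#' Specify one synthetic lab code
#'
#' @param loinc Reference LOINC code string.
#' @param family Distribution family: `"normal"`, `"lognormal"`, `"gamma"`,
#'   `"uniform"` or `"discrete"` (Poisson; integer-valued, so it exercises
#'   tied values in the KS scan). The families mimic common analyte shapes:
#'   electrolytes (normal), enzymes (lognormal), skewed counts (gamma),
#'   integer panels (discrete).
#' @param params Named list of family parameters (`mean`/`sd`,
#'   `meanlog`/`sdlog`, `shape`/`rate`, `min`/`max`, `lambda`).
#' @param n_reference,n_query Observations stored per code at the reference
#'   and query sites. `n_query = 0` makes a reference-only "distractor"
#'   code, enlarging the candidate panel the way a hospital-wide reference
#'   vocabulary dwarfs any one site's query list.
#' @return A one-row tibble (a code spec).
#' @export
code_spec <- function(loinc, family, params, n_reference = 2000,
                      n_query = 2000) {
  family <- match.arg(family, FAMILIES)
  validate_params(family, params)
  if (n_reference < 1) stop_config("n_reference must be positive")
  if (n_query < 0) stop_config("n_query must be >= 0")
  tibble::tibble(loinc = as.character(loinc), family = family,
                 params = list(params),
                 n_reference = as.integer(n_reference),
                 n_query = as.integer(n_query))
}

#' Assemble a synthetic-scenario configuration
#'
#' @param specs Tibble of code specs ([code_spec()] rows).
#' @param query_shift List with `location_sd` (additive location shift in
#'   units of each code's reference sd) and `scale` (multiplicative spread
#'   change); models mild cross-site assay differences. Default: none.
#' @param confuser_pairs Optional tibble `(loinc_a, loinc_b)`; each pair
#'   forces `loinc_b` to near-identical parameters as `loinc_a` (location
#'   nudged by 1% of the sd), creating deliberately hard candidates.
#' @param unmapped_fraction Fraction of query codes whose true LOINC is
#'   withheld from the reference panel, in `[0, 1)`.
#' @param seed Integer master seed; the scenario is fully reproducible
#'   from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(specs, query_shift = list(location_sd = 0, scale = 1),
                            confuser_pairs = NULL, unmapped_fraction = 0,
                            seed = 1) {
  if (is.null(specs) || nrow(specs) == 0) stop_config("specs must be non-empty")
  if (anyDuplicated(specs$loinc)) stop_config("duplicate LOINC in specs")
  if (unmapped_fraction < 0 || unmapped_fraction >= 1) {
    stop_config("unmapped_fraction must be in [0, 1)")
  }
  purrr::walk2(specs$family, specs$params, validate_params)
  structure(list(specs = specs,
                 query_shift = utils::modifyList(list(location_sd = 0, scale = 1),
                                                 as.list(query_shift)),
                 confuser_pairs = confuser_pairs,
                 unmapped_fraction = unmapped_fraction,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a synthetic query/reference/truth triplet
#'
#' Reference draws come straight from each code's family; query draws are
#' taken from the same family and then perturbed by the configured shift
#' (`mu + (value - mu) * scale + location_sd * sd_family`, with `mu` the
#' family mean, re-rounded for the discrete family so integer ties
#' survive). Local code ids (`LC_0001`, ...) are
#' linked to LOINCs only through the truth table. Codes selected by
#' `unmapped_fraction` keep their query observations and truth entry but
#' their LOINC is withheld from the reference table. Every draw runs on a
#' per-code stream derived from the master seed, so the tables are
#' byte-stable under code addition/removal.
#'
#' @param config A `scenario_config`.
#' @return A list of class `loinc_scenario`: `query` and `reference`
#'   lab-event tibbles (`code_id`, `value`), `truth`
#'   (`local_code_id`, `true_loinc`), `withheld` (character vector of
#'   withheld LOINCs) and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  specs <- config$specs
  if (!is.null(config$confuser_pairs) && nrow(config$confuser_pairs) > 0) {
    for (k in seq_len(nrow(config$confuser_pairs))) {
      a <- config$confuser_pairs$loinc_a[k]
      b <- config$confuser_pairs$loinc_b[k]
      ia <- match(a, specs$loinc); ib <- match(b, specs$loinc)
      if (is.na(ia) || is.na(ib)) stop_config("confuser pair names unknown LOINC")
      pa <- specs$params[[ia]]
      nudged <- pa
      loc_name <- switch(specs$family[ia], normal = "mean",
                         lognormal = "meanlog", gamma = NULL,
                         uniform = "min", discrete = "lambda")
      if (!is.null(loc_name)) {
        nudged[[loc_name]] <- pa[[loc_name]] +
          0.01 * family_sd(specs$family[ia], pa)
      } else {
        nudged$shape <- pa$shape * 1.01
      }
      specs$family[ib] <- specs$family[ia]
      specs$params[[ib]] <- nudged
    }
  }

  query_specs <- specs[specs$n_query > 0, ]
  n_unmapped <- floor(config$unmapped_fraction * nrow(query_specs) + 0.5)
  withheld <- character(0)
  if (n_unmapped > 0) {
    withheld <- withr::with_seed(
      code_seed(config$seed, "unmapped"),
      sample(query_specs$loinc, n_unmapped))
  }

  ref_rows <- purrr::pmap(specs[specs$loinc %in% setdiff(specs$loinc, withheld), ],
    function(loinc, family, params, n_reference, n_query) {
      vals <- withr::with_seed(code_seed(config$seed, paste0("ref:", loinc)),
                               family_draw(family, params, n_reference))
      tibble::tibble(code_id = loinc, value = vals)
    })

  shift <- config$query_shift
  local_ids <- sprintf("LC_%04d", seq_len(nrow(query_specs)))
  qry_rows <- purrr::pmap(
    c(query_specs, list(.lid = local_ids)),
    function(loinc, family, params, n_reference, n_query, .lid) {
      vals <- withr::with_seed(code_seed(config$seed, paste0("qry:", loinc)),
                               family_draw(family, params, n_query))
      mu <- family_mean(family, params)
      vals <- mu + (vals - mu) * shift$scale +
        shift$location_sd * family_sd(family, params)
      if (family == "discrete") vals <- round(vals)
      tibble::tibble(code_id = .lid, value = vals)
    })

  structure(list(
    query = dplyr::bind_rows(qry_rows),
    reference = dplyr::bind_rows(ref_rows),
    truth = tibble::tibble(local_code_id = local_ids,
                           true_loinc = query_specs$loinc),
    withheld = withheld,
    config = config
  ), class = "loinc_scenario")
}

#' @export
print.loinc_scenario <- function(x, ...) {
  cat("<loinc_scenario> ", nrow(x$truth), " query code(s), ",
      length(unique(x$reference$code_id)), " reference LOINC(s), ",
      length(x$withheld), " withheld\n", sep = "")
  invisible(x)
}

#' Panel of codes with controlled pairwise overlap
#'
#' Builds a panel of unit-sd normal codes on an evenly spaced location grid
#' whose spacing shrinks as `overlap` grows: means `10 * (1 - overlap)`
#' apart. At `overlap = 0` the codes are essentially disjoint (pairwise KS
#' near 1); at `overlap = 1` all codes share identical parameters. When
#' reference-only distractors are requested the `k` query codes are
#' interleaved evenly among them, so no two query codes are grid
#' neighbours and every withheld code keeps its nearest reference at
#' exactly one grid step. Useful for difficulty sweeps.
#'
#' @param k Number of query codes (>= 2).
#' @param overlap Overlap level in `[0, 1]`.
#' @param seed Master seed for the resulting config.
#' @param n_reference,n_query Observations per code at each site.
#' @param n_distractors Extra reference-only codes appended beyond the
#'   query grid.
#' @param unmapped_fraction Passed to [scenario_config()].
#' @param query_shift Passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
make_confusable_panel <- function(k, overlap, seed = 1, n_reference = 2000,
                                  n_query = 2000, n_distractors = 0,
                                  unmapped_fraction = 0,
                                  query_shift = list(location_sd = 0, scale = 1)) {
  if (k < 2) stop_config("k must be >= 2")
  if (overlap < 0 || overlap > 1) stop_config("overlap must be in [0, 1]")
  total <- k + n_distractors
  means <- (seq_len(total) - 1) * 10 * (1 - overlap)
  query_pos <- if (n_distractors >= 2) {
    # interior, evenly interleaved: every query code keeps a two-sided
    # neighbourhood and no two query codes are grid-adjacent
    round(seq(2, total - 1, length.out = k))
  } else {
    seq_len(k)
  }
  specs <- dplyr::bind_rows(purrr::map(seq_len(total), function(i) {
    code_spec(sprintf("LOINC-%04d-1", i), "normal",
              list(mean = means[i], sd = 1),
              n_reference = n_reference,
              n_query = if (i %in% query_pos) n_query else 0L)
  }))
  scenario_config(specs, query_shift = query_shift,
                  unmapped_fraction = unmapped_fraction, seed = seed)
}

#' Packaged study scenarios
#'
#' Two reference conditions used throughout the package's own evaluation:
#'
#' `scenario_well_separated()` — 20 essentially disjoint codes (grid
#' spacing 10 sd, pairwise reference KS near 1), no query shift, full
#' reference coverage. The mapper should recover every code in every run;
#' any miss is a defect, not noise.
#'
#' `scenario_partial_reference()` — 30 query codes interleaved among 60
#' reference-only distractors on a 0.75-sd grid (neighbouring codes overlap
#' substantially, the hard regime), mild cross-site shift (3% of sd on
#' location, 2% on scale), and 30% of query codes with their true LOINC
#' withheld from the reference panel. The withheld codes are the
#' necessarily-wrong mappings the z-score cutoff must reject; their
#' nearest wrong reference sits exactly one grid step away, so their
#' z-scores concentrate just above the -5 operating point while correct
#' codes concentrate below it.
#'
#' @param seed Master seed for the scenario.
#' @return A `scenario_config`.
#' @export
scenario_well_separated <- function(seed = 1) {
  make_confusable_panel(20, overlap = 0, seed = seed,
                        n_reference = 2000, n_query = 2000)
}

#' @rdname scenario_well_separated
#' @export
scenario_partial_reference <- function(seed = 1) {
  make_confusable_panel(30, overlap = 0.925, seed = seed,
                        n_distractors = 60, unmapped_fraction = 0.3,
                        query_shift = list(location_sd = 0.03, scale = 1.02),
                        n_reference = 2000, n_query = 2000)
}

#' Write a scenario's tables to a directory
#'
#' Writes `query.csv`, `reference.csv` and `truth.csv`.
#'
#' @param scenario A `loinc_scenario` from [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "loinc_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(scenario$query, file.path(dir, "query.csv"), progress = FALSE)
  readr::write_csv(scenario$reference, file.path(dir, "reference.csv"), progress = FALSE)
  readr::write_csv(scenario$truth, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}

#' Build a scenario configuration from a YAML file
#'
#' Schema: top-level keys `seed`, `unmapped_fraction`, `query_shift`
#' (`location_sd`, `scale`) and `specs`, a list of entries with `loinc`,
#' `family`, `params` (named), `n_reference`, `n_query`.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_io(paste0("scenario config not found: ", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$specs) || length(y$specs) == 0) stop_config("no specs in YAML")
  specs <- dplyr::bind_rows(purrr::map(y$specs, function(s) {
    code_spec(s$loinc, s$family, s$params,
              n_reference = s$n_reference %||% 2000,
              n_query = s$n_query %||% 2000)
  }))
  scenario_config(specs,
                  query_shift = y$query_shift %||% list(location_sd = 0, scale = 1),
                  unmapped_fraction = y$unmapped_fraction %||% 0,
                  seed = y$seed %||% 1)
}
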