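# Tabular I/O: lab-event tables, candidate mappings, truth tables, mapping
# results and serialized reference eCDF panels. All CSV, UTF-8, header row.

#' Read a long-format lab-event table
#'
#' Reads one observation per row from a CSV extract (the shape of a
#' MIMIC-III-style `LABEVENTS` dump: a code column and a numeric value
#' column). Non-numeric and non-finite values are dropped — the method is
#' defined only for quantitative tests — and the number of dropped rows is
#' reported as a message.
#'
#' @param path Path to a CSV file with a header row.
#' @param code_column,value_column Names of the code and value columns.
#'   Defaults `"code_id"` and `"value"`; configurable because local EHR
#'   extracts vary.
#' @param source_label Optional label (e.g. `"query"` or `"reference"`)
#'   attached as the `source_label` attribute.
#'
#' @return A tibble with columns `code_id` (character) and `value` (double),
#'   one row per retained observation.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("code_id,value", "A,1.0", "A,2.0", "B,NA"), f)
#' read_lab_events(f)
read_lab_events <- function(path, code_column = "code_id",
                            value_column = "value", source_label = NULL) {
  if (!file.exists(path)) stop_io(paste0("lab-event file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(c(code_column, value_column), names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("column(s) absent from ", path, ": ",
                       paste(missing_cols, collapse = ", ")))
  }
  tab <- tibble::tibble(
    code_id = as.character(raw[[code_column]]),
    value = suppressWarnings(as.numeric(raw[[value_column]]))
  )
  keep <- !is.na(tab$code_id) & nzchar(tab$code_id) & is.finite(tab$value)
  n_dropped <- sum(!keep)
  tab <- tab[keep, ]
  if (n_dropped > 0) {
    inform(paste0("read_lab_events: dropped ", n_dropped,
                  " row(s) with non-numeric values or empty codes"),
           class = "loincmap_msg_dropped_rows")
  }
  if (nrow(tab) == 0) {
    stop_empty_input(paste0("no parseable numeric lab values in ", path))
  }
  attr(tab, "source_label") <- source_label
  tab
}

#' Read an external mapper's candidate file
#'
#' Reads the candidate mapping emitted by a text-based mapper (e.g. a RELMA
#' export): one local code, one proposed LOINC. When a local code appears more
#' than once — ranked candidate lists are common — the first-listed candidate
#' wins and a warning is raised.
#'
#' @param path CSV file with a header row.
#' @param code_column,loinc_column Column names; defaults `"local_code_id"`
#'   and `"candidate_loinc"`.
#' @return A tibble with columns `local_code_id`, `candidate_loinc`.
#' @export
read_candidate_mappings <- function(path, code_column = "local_code_id",
                                    loinc_column = "candidate_loinc") {
  if (!file.exists(path)) stop_io(paste0("candidate file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(c(code_column, loinc_column), names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("column(s) absent from ", path, ": ",
                       paste(missing_cols, collapse = ", ")))
  }
  tab <- tibble::tibble(
    local_code_id = as.character(raw[[code_column]]),
    candidate_loinc = as.character(raw[[loinc_column]])
  )
  dup <- duplicated(tab$local_code_id)
  if (any(dup)) {
    warn(paste0("read_candidate_mappings: ", sum(dup),
                " duplicate candidate(s); keeping the first per local code"),
         class = "loincmap_warning_duplicate_candidates")
    tab <- tab[!dup, ]
  }
  tab
}

#' Read a truth table of manually curated mappings
#'
#' @param path CSV file with a header row.
#' @param code_column,loinc_column Column names; defaults `"local_code_id"`
#'   and `"true_loinc"`.
#' @return A tibble with columns `local_code_id`, `true_loinc`, exactly one
#'   row per local code.
#' @export
read_truth_table <- function(path, code_column = "local_code_id",
                             loinc_column = "true_loinc") {
  if (!file.exists(path)) stop_io(paste0("truth file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(c(code_column, loinc_column), names(raw))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("column(s) absent from ", path, ": ",
                       paste(missing_cols, collapse = ", ")))
  }
  tab <- tibble::tibble(
    local_code_id = as.character(raw[[code_column]]),
    true_loinc = as.character(raw[[loinc_column]])
  )
  if (anyDuplicated(tab$local_code_id)) {
    stop_schema("truth table has more than one entry for some local code(s)")
  }
  tab
}

#' Write mapping results to CSV
#'
#' Writes the columns `local_code_id`, `mapped_loinc`, `ks_distance`,
#' `z_score`, `accepted`, sorted by `local_code_id` so output is
#' deterministic regardless of input order.
#'
#' @param records A mapping tibble as returned by [map_and_score()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mapping_results <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    stop_contract("write_mapping_results: empty record list")
  }
  needed <- c("local_code_id", "mapped_loinc", "ks_distance", "z_score", "accepted")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop_contract(paste0("records lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::arrange(dplyr::select(records, dplyr::all_of(needed)),
                        .data$local_code_id)
  tryCatch(readr::write_csv(out, path, progress = FALSE),
           error = function(e) stop_io(paste0("cannot write ", path, ": ",
                                              conditionMessage(e))))
  invisible(path)
}

#' Read mapping results written by [write_mapping_results()]
#'
#' @param path CSV path.
#' @return A tibble with the mapping-result columns; `accepted` is logical.
#' @export
read_mapping_results <- function(path) {
  if (!file.exists(path)) stop_io(paste0("mapping-result file not found: ", path))
  readr::read_csv(path, col_types = readr::cols(
    local_code_id = readr::col_character(),
    mapped_loinc = readr::col_character(),
    ks_distance = readr::col_double(),
    z_score = readr::col_double(),
    accepted = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE)
}

#' Serialize a reference eCDF panel to CSV
#'
#' Long format with columns `code_id`, `n_sampled`, `support`, `cum_prob`.
#' Doubles are written in shortest round-trippable decimal form, so a panel
#' survives a write/read cycle exactly. Sharing a panel of eCDFs instead of
#' raw lab values is the privacy-preserving deployment mode this supports:
#' no patient-level observation leaves the reference site.
#'
#' @param ecdfs An eCDF set tibble from [build_ecdf_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_ecdfs <- function(ecdfs, path) {
  if (is.null(ecdfs) || nrow(ecdfs) == 0) {
    stop_contract("write_reference_ecdfs: empty eCDF set")
  }
  long <- tidyr::unnest(
    dplyr::transmute(ecdfs, code_id = .data$code_id, n_sampled = .data$n_sampled,
                     pts = purrr::map(.data$ecdf, ~ tibble::tibble(
                       # 17 significant digits: lossless double round trip
                       support = sprintf("%.17g", .x$support),
                       cum_prob = sprintf("%.17g", .x$cum_prob)))),
    "pts")
  tryCatch(readr::write_csv(long, path, progress = FALSE),
           error = function(e) stop_io(paste0("cannot write ", path, ": ",
                                              conditionMessage(e))))
  invisible(path)
}

#' Read a reference eCDF panel written by [write_reference_ecdfs()]
#'
#' @param path CSV path.
#' @return An eCDF set tibble (columns `code_id`, `n_obs`, `n_sampled`,
#'   `ecdf`), in first-appearance code order.
#' @export
read_reference_ecdfs <- function(path) {
  if (!file.exists(path)) stop_io(paste0("eCDF panel file not found: ", path))
  long <- readr::read_csv(path, col_types = readr::cols(
    code_id = readr::col_character(),
    n_sampled = readr::col_integer(),
    # parsed via base strtod below: exact to the last bit
    support = readr::col_character(),
    cum_prob = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  long$support <- as.numeric(long$support)
  long$cum_prob <- as.numeric(long$cum_prob)
  if (nrow(long) == 0) stop_empty_input(paste0("no eCDF points in ", path))
  long$code_id <- factor(long$code_id, levels = unique(long$code_id))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$code_id),
    n_sampled = .data$n_sampled[1],
    ecdf = list(new_ecdf_step(.data$support, .data$cum_prob, .data$n_sampled[1])),
    .groups = "drop")
  tibble::tibble(code_id = as.character(out$code_id),
                 n_obs = NA_integer_,
                 n_sampled = as.integer(out$n_sampled),
                 ecdf = out$ecdf)
}

#' Write a KS distance matrix to CSV
#'
#' Query codes as rows (first column `local_code_id`), reference LOINC codes
#' as columns.
#'
#' @param D A distance matrix from [build_distance_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  out <- tibble::as_tibble(unclass(D), rownames = "local_code_id")
  tryCatch(readr::write_csv(out, path, progress = FALSE),
           error = function(e) stop_io(paste0("cannot write ", path, ": ",
                                              conditionMessage(e))))
  invisible(path)
}
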