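# Internal helpers: deterministic seed streams and error constructors.

# Deterministic 31-bit sub-seed from a master seed and a string key.
# Polynomial string hash folded with the master seed; keeping every per-code
# draw on its own stream means adding or removing a code never perturbs the
# samples of the others.
code_seed <- function(master_seed, key) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% m
  base <- (abs(as.numeric(master_seed)) %% m) * 48271 %% m
  as.integer((h + base) %% m)
}

# Sub-seed for run r of a repeated evaluation.
run_seed <- function(master_seed, run) {
  code_seed(master_seed, paste0("run:", run))
}

stop_io <- function(msg) abort(msg, class = "loincmap_error_io")
stop_schema <- function(msg) abort(msg, class = "loincmap_error_schema")
stop_empty_input <- function(msg) abort(msg, class = "loincmap_error_empty_input")
stop_lookup <- function(msg) abort(msg, class = "loincmap_error_lookup")
stop_contract <- function(msg) abort(msg, class = "loincmap_error_contract")
stop_degenerate <- function(msg) abort(msg, class = "loincmap_error_degenerate")
stop_config <- function(msg) abort(msg, class = "loincmap_error_config")
stop_evaluation <- function(msg) abort(msg, class = "loincmap_error_evaluation")
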