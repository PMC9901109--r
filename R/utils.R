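# Input-contract violations get a dedicated condition class so callers (and the
# command-line wrapper) can distinguish bad data (exit 1) from internal errors
# (exit 2).
stop_validation <- function(msg) {
  stop(errorCondition(msg, class = "wce_validation_error",
                      call = sys.call(-1)))
}

# Deterministic sub-seed derivation; keeps everything well inside 32-bit range.
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(index) * 7919L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
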