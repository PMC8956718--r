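# internal helpers shared across modules

# integer coverage target: smallest integer count satisfying
# (cells killed) >= lb * m; the epsilon guards float artifacts (0.7 * 10)
coverage_target <- function(lb, m) {
  as.integer(ceiling(lb * m - 1e-9))
}

# integer kill allowance: largest count satisfying (cells killed) <= ub * q
kill_allowance <- function(ub, q) {
  as.integer(floor(ub * q + 1e-9))
}

# stable 31-bit hash of a string; platform-independent
stable_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  h
}

# derive a per-(patient, replicate) RNG seed from one base seed, so adding
# patients or replicates never perturbs other streams
derive_seed <- function(seed, patient_id, replicate_index = 0L) {
  (as.numeric(seed) * 7919 + stable_hash(patient_id) +
     as.numeric(replicate_index) * 104729) %% 2147483629 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gene <- function(msg) abort(msg, class = "oncohit_error_gene")
stop_format <- function(msg) abort(msg, class = "oncohit_error_format")
stop_config <- function(msg) abort(msg, class = "oncohit_error_config")
stop_mode <- function(msg) abort(msg, class = "oncohit_error_mode")
stop_empty_sample <- function(msg) abort(msg, class = "oncohit_error_empty_sample")
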