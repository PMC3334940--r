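# Internal helpers shared across modules.

GENOTYPE_CODES <- c("mm", "Mm", "MM")  # fixed item order within a SNP

# Round to nearest integer, ties away from zero (upward for positives).
# base::round() rounds half to even, which is not what target-count
# arithmetic in the generator wants.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic per-task seeds derived from a master seed.  Kept well
# below .Machine$integer.max so downstream set.seed() is safe.
derive_seed <- function(master_seed, index) {
  (as.integer(master_seed) %% 1000003L) * 2011L + 7919L * as.integer(index) %% 1000003L
}

# FNV-1a hash of a character scalar, reported as 8 hex digits.  Used for
# stable config/dataset digests in provenance headers; not cryptographic.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

config_digest <- function(cfg) {
  flat <- unlist(cfg, use.names = TRUE)
  fnv1a(paste(names(flat), vapply(flat, format, ""), sep = "=", collapse = ";"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(errorCondition(sprintf(...), class = c("snpcombine_data_error", "error")))
}

stop_budget <- function(...) {
  stop(errorCondition(sprintf(...), class = c("snpcombine_budget_error", "error")))
}
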