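# Internal helpers shared across the package.

# Validation failures get a dedicated condition class so callers (and the CLI)
# can distinguish bad input from internal errors.
stop_invalid <- function(msg, ..., call. = FALSE) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dcvkit_validation_error", "error", "condition")))
}

is_validation_error <- function(e) inherits(e, "dcvkit_validation_error")

# ";"-separated code list <-> character vector
split_codes <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_codes <- function(x) vapply(x, paste, character(1), collapse = ";")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash over a character scalar; used only to stamp run logs
# with a dependency-free fingerprint of the parameter set.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
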