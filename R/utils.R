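#' Derive a stage-specific sub-seed from a global seed
#'
#' Deterministically fans one global integer seed out to named pipeline
#' stages so each stage is independently reproducible. Uses a small
#' string-hash mixed with the global seed; the result always lies in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 31 + ch) %% 2147483647
  as.integer(((as.double(seed) %% 2147483647) * 48271 + h) %% 2147483646 + 1)
}

# FNV-1a-style hash of a deparsed R object, as provenance fingerprint for
# configs and cached stages.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
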