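# internal helpers shared across modules

# column-wise maxima of a numeric matrix without apply() overhead
col_maxs <- function(m) {
  tm <- t(m)
  tm[cbind(seq_len(nrow(tm)), max.col(tm, ties.method = "first"))]
}

# deterministic per-compound substream seeds; kept below 2^31 and never equal
# to the base seed itself, so user-level set.seed(seed) calls cannot collide
# with any substream
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * (as.numeric(i) + 1)) %% 2147483647L)
}

# tiny FNV-1a hash for provenance stamps (no cryptographic intent)
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
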