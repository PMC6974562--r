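# internal helpers shared across modules

# Stable 31-bit string hash (polynomial rolling hash modulo a Mersenne-ish
# prime).  Used to derive per-flask RNG sub-streams so that any subset of
# flasks is reproducible independently of generation order.  Must stay below
# 2^31 because set.seed() takes a 32-bit integer.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  p <- 2147483629
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% p
  as.integer(h)
}

substream_seed <- function(seed, id) {
  stable_hash(paste0(format(seed, scientific = FALSE), "::", id))
}

# 64-bit hex digest of a character scalar (two independent rolling hashes),
# used to fingerprint configurations in run manifests.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  p1 <- 2147483629; p2 <- 2147483587
  h1 <- 0; h2 <- 0
  for (b in utf8ToInt(x)) {
    h1 <- (h1 * 131 + b) %% p1
    h2 <- (h2 * 137 + b) %% p2
  }
  sprintf("%08x%08x", h1, h2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  invisible(x)
}
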