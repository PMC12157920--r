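# Internal helpers: reproducible substreams, significance stars, tiny hash.

# Deterministic 31-bit hash of a string (FNV-style). Used to derive
# per-component RNG substreams so that adding genes never perturbs the
# columns already generated, and to fingerprint run configs.
str_hash31 <- function(key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Substream seed for a (master seed, key) pair; always in [0, 2^31).
substream_seed <- function(seed, key) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + str_hash31(key)) %%
               2147483647)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Significance stars
#'
#' Map p-values to the conventional star labels: `***` for p < 0.001,
#' `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# Fingerprint an arbitrary config-like list (canonical JSON, order-stable).
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", str_hash31(as.character(js)))
}

# Hashed name -> column position map; plain named-vector lookup is O(m)
# per access, which is quadratic over a 1e5-gene generation loop.
col_index <- function(ids) {
  list2env(as.list(setNames(seq_along(ids), ids)), hash = TRUE)
}

stop_stage <- function(stage, msg, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(msg, ...)), call. = FALSE)
}
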