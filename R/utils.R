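# Internal helpers shared across modules.

# Error constructors carrying a condition class so callers (and the pipeline
# driver) can map failures to exit codes: config -> 2, data -> 3, internal -> 4.
morbStop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "morbError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

morbConfigStop <- function(msg, ...) morbStop(msg, "morbConfigError", ...)
morbDataStop <- function(msg, ...) morbStop(msg, "morbDataError", ...)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage substream seed from the run seed. Kept below 2^31 so the
# result is always a valid R integer.
stageSeed <- function(seed, stage_index) {
  as.integer((as.double(seed) * 131L + stage_index) %% .Machine$integer.max)
}

cosineSimilarity <- function(u, v) {
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

isPermutation <- function(x, n = length(x)) {
  length(x) == n && !anyNA(x) && all(sort(as.integer(x)) == seq_len(n))
}
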