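# internal helpers shared across modules

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stage offset, kept within the
# 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 101L + k * 7919) %% .Machine$integer.max)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
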