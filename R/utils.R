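# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream (the global .Random.seed is restored on exit).
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Canonical key for an undirected edge: endpoints sorted lexicographically.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Split canonical keys back into a two-column character matrix.
edge_key_split <- function(keys) {
  if (length(keys) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("nodeA", "nodeB"))))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  matrix(unlist(parts), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("nodeA", "nodeB")))
}

# Derive a per-stage seed from a global seed; stays within 32-bit range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (abs(as.integer(seed)) %% 20000003L) * 101L + as.integer(stage)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
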