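#' @keywords internal
"_PACKAGE"

# Deterministic substreams: every simulated actor (annotator, AUT, sampler)
# draws from its own stream derived from (root seed, actor id) by a stable
# string hash. Adding or removing one actor therefore never perturbs the
# draws of another -- the blinding property the round-1 tests assert.

hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible substream seed for a named actor
#'
#' Combines a root seed with an actor identifier into a deterministic
#' 32-bit seed. Used throughout the pipeline so that each annotator,
#' sampler and algorithm under test has its own independent random stream.
#'
#' @param root Integer root seed for the whole run.
#' @param actor_id Character identifier of the actor or stage.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(root, actor_id) {
  stopifnot(is.numeric(root), length(root) == 1L, !is.na(root))
  hash_string(paste0(format(root, scientific = FALSE), "/", actor_id))
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so package internals never disturb user code.
with_stream <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}
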