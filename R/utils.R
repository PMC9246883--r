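# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a deterministic RNG state without disturbing the caller's
# stream. Seeds must stay below 2^31 - 1 (R integers are 32-bit).
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stream index (Knuth-style
# multiplicative mix, kept in 32-bit range).
mix_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 2654435761 + as.double(stream) * 40503) %%
               .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

clamp01 <- function(x) pmin(pmax(x, 0), 1)
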