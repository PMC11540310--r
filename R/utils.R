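#' @keywords internal
"_PACKAGE"

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
# seed = NULL leaves the global stream untouched (caller controls RNG).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed below 2^31: adding a stage never perturbs others.
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.double(master) %% 2147483629 + h * 7919 + index * 104729) %%
               2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
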