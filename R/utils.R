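# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed
#'
#' Stable integer hash combining a base seed with stage labels or indices,
#' so that every stochastic stage of a run draws from an independent,
#' reproducible stream. Result is in `[1, 2^31 - 2]`.
#'
#' @param seed integer base seed.
#' @param ... further integers or strings identifying the stage.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(paste(p, collapse = ""))) else p <- as.double(p)
    for (v in p) h <- (h * 48271 + (as.double(v) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}
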