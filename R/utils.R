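## run expr under a temporary RNG state seeded with `seed` (NULL = leave RNG
## alone); restores the caller's stream afterwards so seeded analyses do not
## perturb the session
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## row-flatten a p x 2 configuration to (x1, y1, ..., xp, yp)
flatten_config <- function(m) as.vector(t(m))

## inverse of flatten_config
unflatten_config <- function(v) matrix(v, ncol = 2L, byrow = TRUE)
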