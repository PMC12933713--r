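# shared internal helpers

# keeps dim/dimnames of x (x is the first argument of pmax/pmin on purpose)
clip_unit <- function(x) pmin(pmax(x, -1), 1)

# local RNG scope: evaluate expr with a temporary seed, restoring global state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a distinct 31-bit sub-seed from a base seed and a stream tag
sub_seed <- function(seed, tag) {
  x <- as.numeric(seed)
  for (ch in utf8ToInt(as.character(tag))) x <- (x * 31 + ch) %% 2147483647
  as.integer(x)
}

stop_surfibs <- function(msg, class = "surfibs_error") {
  rlang::abort(msg, class = class)
}
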