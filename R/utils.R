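# evaluate code under a temporary RNG state; NULL seed = use the current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a distinct 32-bit sub-seed from a base seed and a stream label
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1013 + as.numeric(stream) * 7919) %% 2147483587)
}
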