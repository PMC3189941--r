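# Deterministic child-seed derivation: one master seed per run, every
# stochastic operation draws its own child seed from (master, tag) so that
# fixtures are bit-reproducible regardless of evaluation order.

#' Derive a child random seed from a master seed and a tag
#'
#' @param master Integer master seed.
#' @param tag Character tag naming the stochastic operation.
#' @return Integer in `[0, 2^31 - 2]`, a deterministic function of inputs.
#' @export
derive_seed <- function(master, tag) {
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# evaluate expr with a locally set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
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
  expr
}
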