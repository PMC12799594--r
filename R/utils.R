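# Seed handling: every generator uses a local RNG scope so that global
# random state is neither consumed nor disturbed, and identical (params,
# seed) yield bit-identical output.

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive independent child seeds from one root seed
#'
#' Stage-specific generators are given their own child streams so that
#' adding or reordering stages does not silently change the draws of the
#' others. Children are sampled uniformly below 2^31 from the root stream.
#'
#' @param seed root seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length \code{n}.
#' @examples
#' deriveSeeds(1, 3)
#' @export
deriveSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.stopParam <- function(...) stop(..., call. = FALSE)
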