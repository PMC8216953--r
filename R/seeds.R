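#' Deterministic seed splitting
#'
#' One global integer seed fans out to per-component seeds so that pipeline
#' stages draw from independent, reproducible streams. The rule is
#' `child = (seed * 48271 + 7919 * index) mod (2^31 - 1)`, with `index` the
#' position of `component` in the registered component list (an unknown
#' component hashes its name). 48271 is the classic Lehmer multiplier; the
#' modulus keeps every derived seed a valid 32-bit R integer.
#'
#' @param seed integer global seed.
#' @param component character scalar naming the consuming stage.
#' @return An integer seed.
#' @examples
#' splitSeed(1, "dispersal")
#' @export
splitSeed <- function(seed, component) {
  stopifnot(length(seed) == 1, is.finite(seed))
  registry <- c("field", "nodes", "metapop", "environment", "dispersal",
                "filtering", "popgen", "outliers", "ordination", "pipeline")
  idx <- match(component, registry)
  if (is.na(idx))
    idx <- sum(utf8ToInt(component)) %% 1000L + 100L
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + 7919 * idx) %% m)
}

# run expr with a temporary RNG state seeded from `seed`; restores the
# caller's RNG so library code never perturbs user-level randomness
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
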