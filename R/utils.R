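# Deterministic sub-seed derivation: every stage/record draws its randomness
# from a sub-seed obtained by hashing (seed, label) so partial regeneration
# (e.g. a single image) is stable no matter what was generated before it.
# FNV-1a over the label bytes, folded with the seed, reduced mod 2^31 - 1.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1 (exact in doubles)
  h <- 17
  for (b in utf8ToInt(label)) {
    h <- (h * 1313 + b) %% 2147483647
  }
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Evaluate expr with the RNG seeded from (seed, label), restoring the caller's
# RNG state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  expr
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (the convention used
#' for reported percentages), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# Cheap stable hash of an R object (serialized to JSON) used to fingerprint
# configurations in output bundles.
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
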