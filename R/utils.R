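#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state. Restores the caller's .Random.seed so
# seeded sampling inside the package never perturbs user-level randomness.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting scheme used throughout the pipeline: every stage
#' (geometry draw, flow noise, data-set split, network initialization, ...)
#' receives its own 31-bit seed derived from the single run seed and a stage
#' tag, so that regenerating any one stage reproduces it bit-for-bit.
#'
#' @param master integer master seed.
#' @param tag character stage tag, e.g. `"flow/preop/12"`.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  s <- (abs(master) %% 2147483647) * 48271 + h * 7919 + 12345
  as.integer(s %% 2147483646 + 1)
}

vec_norm <- function(m) {
  if (is.matrix(m)) sqrt(rowSums(m^2)) else sqrt(sum(m^2))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
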