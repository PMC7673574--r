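#' Round half away from zero
#'
#' Presentation-layer rounding used for printed percentages and ratios:
#' exact halves round up (`round_half_up(0.125, 2)` is `0.13`), unlike base
#' [round()], which rounds halves to even. Internal computations are never
#' rounded; this is applied only when a table-style value is reported.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(52.845, 1) # Ties go up
#' round(52.845, 1)         # Base R rounds to even
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  f <- 10^digits
  # tiny nudge absorbs binary representation error just below .5 boundaries
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# set.seed scoped to a block: global RNG state is saved and restored.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
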