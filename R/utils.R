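# shared internal helpers

DAYS_PER_MONTH <- 30.4375

#' Surface area of the sphere with a given volume
#'
#' Returns \eqn{A = \pi^{1/3} (6V)^{2/3}}, the surface area of a sphere of
#' volume `volume`. Units are consistent: volume in cm^3 (= mL) gives area
#' in cm^2. This is the denominator of the sphericity index.
#'
#' @param volume sphere volume (cm^3 / mL); must be > 0
#' @return surface area in cm^2
#' @export
#' @examples
#' sphere_area(4 / 3 * pi) # unit-radius sphere: 4*pi
sphere_area <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("sphere_area: volume must be positive and finite")
  }
  pi^(1 / 3) * (6 * volume)^(2 / 3)
}

# run code with a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a reproducible sub-seed from a master seed and a stage label
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_error <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
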