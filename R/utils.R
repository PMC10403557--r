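#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

## Run code with a temporary RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

## Half-away-from-zero rounding (base round() rounds half to even).
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

## Quantize a real-valued working image to stored 8-bit integers.
quantize8 <- function(x) {
  out <- round_half_away(clip255(x))
  storage.mode(out) <- "integer"
  out
}

## Validate a stored image: integer-valued matrix in [0, 255].
assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg),
         call. = FALSE)
  }
  if (anyNA(image) || any(!is.finite(image))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (any(image < 0) || any(image > 255)) {
    stop(sprintf("`%s` has values outside [0, 255]", arg), call. = FALSE)
  }
  if (any(image != floor(image))) {
    stop(sprintf("`%s` must hold integer gray levels (quantize first)", arg),
         call. = FALSE)
  }
  invisible(image)
}

assert_scalar_num <- function(x, arg, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", arg), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %s", arg, min), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %s", arg, min), call. = FALSE)
  }
  invisible(x)
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)
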