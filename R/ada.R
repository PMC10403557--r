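#' Describe an acquisition-dependent attribute (ADA) perturbation
#'
#' An ADA spec parameterizes one global, anatomy-independent image
#' perturbation of the kind introduced by imaging hardware and vendor
#' post-processing: a contrast change (power-law / gamma mapping) or a
#' sharpness change (Gaussian softening or unsharp-mask sharpening). These
#' are the perturbations injected into one class of a shortcut training set
#' and later hunted by a certified detective.
#'
#' @param attribute `"contrast"` or `"sharpness"`.
#' @param gamma Positive contrast exponent; 1 is the identity. Only
#'   meaningful for `attribute = "contrast"`.
#' @param blur_sigma Nonnegative Gaussian smoothing scale in pixels; 0 is
#'   none. Only for `attribute = "sharpness"`.
#' @param sharpen_amount Nonnegative unsharp-mask gain; 0 is none. Only for
#'   `attribute = "sharpness"`, and mutually exclusive with `blur_sigma`.
#' @return An object of class `ada_spec`.
#' @examples
#' ada_spec("contrast", gamma = 1.3)
#' ada_spec("sharpness", blur_sigma = 1.0)
#' @export
ada_spec <- function(attribute = c("contrast", "sharpness"),
                     gamma = 1, blur_sigma = 0, sharpen_amount = 0) {
  attribute <- match.arg(attribute)
  assert_scalar_num(gamma, "gamma", min = 0, strict_min = TRUE)
  assert_scalar_num(blur_sigma, "blur_sigma", min = 0)
  assert_scalar_num(sharpen_amount, "sharpen_amount", min = 0)
  if (attribute == "contrast" && (blur_sigma != 0 || sharpen_amount != 0)) {
    stop("a contrast spec must have blur_sigma = 0 and sharpen_amount = 0",
         call. = FALSE)
  }
  if (attribute == "sharpness" && gamma != 1) {
    stop("a sharpness spec must have gamma = 1", call. = FALSE)
  }
  if (blur_sigma > 0 && sharpen_amount > 0) {
    stop("at most one of blur_sigma and sharpen_amount may be nonzero",
         call. = FALSE)
  }
  structure(
    list(attribute = attribute, gamma = gamma, blur_sigma = blur_sigma,
         sharpen_amount = sharpen_amount),
    class = "ada_spec"
  )
}

assert_ada_spec <- function(spec) {
  if (!inherits(spec, "ada_spec")) {
    stop("`ada` must be an object created by ada_spec()", call. = FALSE)
  }
  ## re-validate: specs may have been deserialized
  do.call(ada_spec, unclass(spec))
}

#' @export
print.ada_spec <- function(x, ...) {
  if (x$attribute == "contrast") {
    cat(sprintf("ADA spec: contrast (gamma = %g)\n", x$gamma))
  } else {
    cat(sprintf("ADA spec: sharpness (blur_sigma = %g px, sharpen_amount = %g)\n",
                x$blur_sigma, x$sharpen_amount))
  }
  invisible(x)
}

#' Is an ADA spec the identity perturbation?
#' @param spec An [ada_spec()].
#' @return `TRUE` when applying the spec leaves every image bit-identical.
#' @export
is_identity_ada <- function(spec) {
  assert_ada_spec(spec)
  (spec$attribute == "contrast" && spec$gamma == 1) ||
    (spec$attribute == "sharpness" && spec$blur_sigma == 0 &&
       spec$sharpen_amount == 0)
}

## ---- gamma map ------------------------------------------------------------

## Real-valued power-law map on the [0, 255] working range (no quantization).
contrast_map <- function(x, gamma) 255 * (x / 255)^gamma

#' Apply a global contrast (gamma) perturbation
#'
#' Each pixel p is mapped to `255 * (p/255)^gamma` in real arithmetic and
#' rounded half-away-from-zero back to 8-bit. `gamma = 1` is a bit-exact
#' no-op; 0 and 255 are fixed points for every gamma; the map is monotone so
#' pixel ordering is preserved.
#'
#' @param image Integer-valued matrix in \[0, 255\].
#' @param gamma Positive exponent.
#' @return An 8-bit image of the same dimensions.
#' @export
apply_contrast <- function(image, gamma) {
  assert_image(image)
  assert_scalar_num(gamma, "gamma", min = 0, strict_min = TRUE)
  quantize8(contrast_map(image, gamma))
}

## ---- Gaussian smoothing ---------------------------------------------------

## Sampled, normalized 1-D Gaussian kernel; radius ceil(3*sigma).
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Dense n x n matrix applying the kernel along one axis with
## symmetric (half-sample) reflection at the boundary: ... c b a | a b c ...
conv_matrix_reflect <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (t in seq_along(kernel)) {
    src <- seq_len(n) + (t - r - 1L)
    m <- (src - 1L) %% (2L * n)
    m <- ifelse(m >= n, 2L * n - 1L - m, m)
    idx <- cbind(seq_len(n), m + 1L)
    M[idx] <- M[idx] + kernel[t]
  }
  M
}

## Separable 2-D Gaussian blur on a real-valued image; reflective boundary.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel(sigma)
  Br <- conv_matrix_reflect(nrow(x), k)
  Bc <- if (ncol(x) == nrow(x)) Br else conv_matrix_reflect(ncol(x), k)
  Br %*% x %*% t(Bc)
}

#' Apply a sharpness perturbation (Gaussian blur or unsharp mask)
#'
#' With `blur_sigma > 0` the image is convolved with a normalized Gaussian
#' kernel (symmetric-reflect boundary), softening it. With
#' `sharpen_amount > 0` an unsharp mask is applied:
#' `out = in + amount * (in - Gaussian(in, sharpen_sigma))`, amplifying
#' detail. The two directions are mutually exclusive; both zero is a
#' bit-exact no-op. Results are clipped to \[0, 255\] and quantized.
#'
#' @inheritParams apply_contrast
#' @param blur_sigma Nonnegative Gaussian sigma in pixels.
#' @param sharpen_amount Nonnegative unsharp-mask gain.
#' @param sharpen_sigma Internal smoothing scale of the unsharp mask
#'   (pixels); default 1.0.
#' @return An 8-bit image of the same dimensions.
#' @export
apply_sharpness <- function(image, blur_sigma = 0, sharpen_amount = 0,
                            sharpen_sigma = 1.0) {
  assert_image(image)
  assert_scalar_num(blur_sigma, "blur_sigma", min = 0)
  assert_scalar_num(sharpen_amount, "sharpen_amount", min = 0)
  assert_scalar_num(sharpen_sigma, "sharpen_sigma", min = 0, strict_min = TRUE)
  if (blur_sigma > 0 && sharpen_amount > 0) {
    stop("at most one of blur_sigma and sharpen_amount may be nonzero",
         call. = FALSE)
  }
  if (blur_sigma == 0 && sharpen_amount == 0) {
    return(quantize8(image))
  }
  out <- if (blur_sigma > 0) {
    gaussian_blur(image, blur_sigma)
  } else {
    image + sharpen_amount * (image - gaussian_blur(image, sharpen_sigma))
  }
  quantize8(out)
}

#' Apply an ADA perturbation described by a spec
#'
#' Dispatches to [apply_contrast()] or [apply_sharpness()] according to the
#' spec's attribute. A pure function of its inputs.
#'
#' @inheritParams apply_contrast
#' @param spec An [ada_spec()].
#' @return An 8-bit image of the same dimensions.
#' @export
apply_ada <- function(image, spec) {
  assert_ada_spec(spec)
  switch(spec$attribute,
    contrast  = apply_contrast(image, spec$gamma),
    sharpness = apply_sharpness(image, spec$blur_sigma, spec$sharpen_amount)
  )
}

#' Total squared-gradient energy of an image
#'
#' Mean of squared horizontal plus squared vertical forward differences; the
#' summary statistic used throughout to reason about sharpness: Gaussian blur
#' decreases it on any non-constant image, an unsharp mask increases it.
#'
#' @param image Numeric matrix.
#' @return A nonnegative scalar.
#' @export
gradient_energy <- function(image) {
  gx <- image[, -1L, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  gy <- image[-1L, , drop = FALSE] - image[-nrow(image), , drop = FALSE]
  mean(gx^2) + mean(gy^2)
}
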