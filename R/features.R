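## Global image features for the feature_linear backend.
##
## Contrast and sharpness shortcuts are global properties, so a compact set
## of whole-image summaries carries the whole signal: intensity quantiles
## (gamma maps move them monotonically), log-quantiles (approximately linear
## in the effective gamma), and gradient/Laplacian energy summaries
## (monotone in the effective smoothing scale).

feature_names <- function() {
  c(sprintf("q%02d", c(1, 5, 10, 25, 50, 75, 90, 95, 99)),
    "logq25", "logq50", "logq75",
    "mean", "sd",
    "log_grad_energy", "gmag_q50", "gmag_q90",
    "log_lap_energy", "log_lap_over_grad")
}

image_features <- function(image) {
  p <- as.numeric(image)
  q <- stats::quantile(p, probs = c(.01, .05, .10, .25, .50, .75, .90, .95, .99),
                       names = FALSE)
  lq <- log((q[c(4, 5, 6)] + 0.5) / 256)
  gx <- image[, -1L, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  gy <- image[-1L, , drop = FALSE] - image[-nrow(image), , drop = FALSE]
  ge <- mean(gx^2) + mean(gy^2)
  gmag <- abs(c(gx, gy))
  gq <- stats::quantile(gmag, c(.5, .9), names = FALSE)
  n <- nrow(image); m <- ncol(image)
  core <- image[2:(n - 1), 2:(m - 1), drop = FALSE]
  lap <- 4 * core -
    image[1:(n - 2), 2:(m - 1)] - image[3:n, 2:(m - 1)] -
    image[2:(n - 1), 1:(m - 2)] - image[2:(n - 1), 3:m]
  le <- mean(lap^2)
  out <- c(q, lq, mean(p), stats::sd(p),
           log(ge + 1e-8), gq, log(le + 1e-8),
           log((le + 1e-8) / (ge + 1e-8)))
  names(out) <- feature_names()
  out
}

## n x p feature matrix for a list of images.
feature_matrix <- function(images) {
  t(vapply(images, image_features, numeric(length(feature_names()))))
}
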