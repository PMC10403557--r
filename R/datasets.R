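#' Construct an in-memory labeled image dataset
#'
#' The container every pipeline stage works on: a list of same-size 8-bit
#' grayscale images, binary labels (1 = positive class), optional patient
#' IDs, and — when a perturbation has been injected — a provenance note
#' recording which [ada_spec()] was applied to which class.
#'
#' @param images List of integer-valued matrices in \[0, 255\], all the same
#'   size.
#' @param labels Vector of 0/1 labels, one per image.
#' @param patient_ids Optional character vector of opaque patient IDs.
#' @param name Free-text dataset name.
#' @param injected_ada Optional provenance: `list(spec = <ada_spec>,
#'   target_label = 0 or 1)`.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(images, labels, patient_ids = NULL,
                            name = "unnamed", injected_ada = NULL) {
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a nonempty list of image matrices", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != length(images)) {
    stop("`labels` must have one entry per image", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be exactly 0 or 1", call. = FALSE)
  }
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all images must have the same dimensions", call. = FALSE)
  }
  if (!is.null(patient_ids)) {
    patient_ids <- as.character(patient_ids)
    if (length(patient_ids) != length(images)) {
      stop("`patient_ids` must have one entry per image", call. = FALSE)
    }
  }
  if (!is.null(injected_ada)) {
    assert_ada_spec(injected_ada$spec)
    if (!injected_ada$target_label %in% c(0L, 1L)) {
      stop("injected_ada$target_label must be 0 or 1", call. = FALSE)
    }
  }
  structure(
    list(images = images, labels = labels, patient_ids = patient_ids,
         name = name, injected_ada = injected_ada),
    class = "labeled_dataset"
  )
}

assert_labeled_dataset <- function(x, arg = "dataset") {
  if (!inherits(x, "labeled_dataset")) {
    stop(sprintf("`%s` must be a labeled_dataset", arg), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("Labeled dataset '%s': %d images (%dx%d), %d positive / %d negative\n",
              x$name, length(x$images), d[1], d[2],
              sum(x$labels == 1L), sum(x$labels == 0L)))
  if (!is.null(x$patient_ids)) {
    cat(sprintf("  patients: %d unique\n", length(unique(x$patient_ids))))
  }
  if (!is.null(x$injected_ada)) {
    cat(sprintf("  injected: %s into label %d\n",
                x$injected_ada$spec$attribute, x$injected_ada$target_label))
  }
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$images)

## ---- preprocessing --------------------------------------------------------

#' Specify raw-raster preprocessing
#'
#' Window/level mapping and quantization used to convert raw detector
#' rasters (e.g. pixel arrays extracted from DICOM) to the canonical 8-bit
#' grid: a linear map through `(window_center, window_width)`, clipping,
#' 8-bit quantization, and area-weighted resize to a square output.
#'
#' @param window_center Window center in raw units.
#' @param window_width Positive window width in raw units.
#' @param out_size Output side length in pixels (>= 8). 224 matches common
#'   clinical preprocessing; 64 is the desk-scale default.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(window_center = 127.5, window_width = 255,
                            out_size = 64) {
  assert_scalar_num(window_center, "window_center")
  assert_scalar_num(window_width, "window_width", min = 0, strict_min = TRUE)
  assert_scalar_num(out_size, "out_size", min = 8)
  structure(list(window_center = window_center, window_width = window_width,
                 out_size = as.integer(out_size), bit_depth = 8L),
            class = "preprocess_spec")
}

## Exact area-weighted 1-D resampling matrix (n_out x n_in): each output
## cell averages the input cells its interval overlaps, weighted by overlap.
area_weights <- function(n_out, n_in) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

## Area-weighted resize of a matrix to nr x nc.
resize_area <- function(x, nr, nc) {
  if (nrow(x) == nr && ncol(x) == nc) return(x)
  Wr <- area_weights(nr, nrow(x))
  Wc <- area_weights(nc, ncol(x))
  Wr %*% x %*% t(Wc)
}

#' Window, quantize and resize a raw raster
#'
#' `out = round(255 * clip((raw - (center - width/2)) / width, 0, 1))` with
#' half-away-from-zero rounding, followed by area-weighted resize to
#' `out_size x out_size` and re-quantization. On an already-8-bit in-range
#' raster with the full-range window and matching size this is the identity.
#'
#' @param raw Numeric matrix of raw intensities.
#' @param spec A [preprocess_spec()].
#' @return An 8-bit image of size `out_size x out_size`.
#' @export
window_and_quantize <- function(raw, spec = preprocess_spec()) {
  if (!inherits(spec, "preprocess_spec")) {
    stop("`spec` must be a preprocess_spec", call. = FALSE)
  }
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix", call. = FALSE)
  }
  lo <- spec$window_center - spec$window_width / 2
  u <- clip01((raw - lo) / spec$window_width)
  img <- round_half_away(255 * u)
  quantize8(resize_area(img, spec$out_size, spec$out_size))
}

## ---- splitting and shortcut construction ----------------------------------

#' Randomly split indices into two equal groups
#'
#' Uniformly random, disjoint and exhaustive; group A receives
#' `ceiling(n/2)` indices and group B the rest. Deterministic given
#' `(n, seed)`. This is the split that turns a pool of disease-free images
#' into the two classes of a shortcut training set.
#'
#' @param n Number of items (>= 2).
#' @param seed Integer seed.
#' @return A list with sorted integer index vectors `A` and `B`.
#' @export
equal_random_split <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  perm <- with_seed(seed, sample.int(n))
  na <- as.integer(ceiling(n / 2))
  list(A = sort(perm[seq_len(na)]), B = sort(perm[-seq_len(na)]))
}

#' Build a shortcut training set from disease-free images
#'
#' Splits the pool into two equal groups by [equal_random_split()], labels
#' one group positive (1) and the other negative (0), applies the ADA
#' perturbation to every positive image, and records the injection
#' provenance. Because the pool contains no class-related content, the only
#' signal separating the classes is the injected perturbation.
#'
#' @param normals List of same-size 8-bit images (>= 2).
#' @param ada An [ada_spec()] to inject into the positive class.
#' @param seed Integer seed for the split.
#' @param patient_ids Optional patient IDs, one per image.
#' @param name Dataset name.
#' @return A [labeled_dataset()] with provenance set.
#' @export
build_detective_trainset <- function(normals, ada, seed, patient_ids = NULL,
                                     name = "detective-trainset") {
  if (!is.list(normals) || length(normals) < 2L) {
    stop("`normals` must be a list of at least 2 images", call. = FALSE)
  }
  assert_ada_spec(ada)
  dims <- vapply(normals, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all images must have the same dimensions", call. = FALSE)
  }
  split <- equal_random_split(length(normals), seed)
  labels <- integer(length(normals))
  labels[split$A] <- 1L
  images <- normals
  for (i in split$A) images[[i]] <- apply_ada(images[[i]], ada)
  labeled_dataset(images, labels, patient_ids = patient_ids, name = name,
                  injected_ada = list(spec = ada, target_label = 1L))
}

#' Inject an ADA perturbation into one class of a dataset
#'
#' Transforms every image of `target_label` exactly once; the other class
#' is untouched. Double injection is refused. Used to construct the known
#' shortcut-present exam datasets.
#'
#' @param dataset A [labeled_dataset()] with both classes and no prior
#'   injection.
#' @param ada An [ada_spec()].
#' @param target_label Class to perturb, 0 or 1.
#' @return A new [labeled_dataset()] with provenance set.
#' @export
inject_into_class <- function(dataset, ada, target_label) {
  assert_labeled_dataset(dataset)
  assert_ada_spec(ada)
  if (!length(target_label) == 1L || !target_label %in% c(0, 1)) {
    stop("`target_label` must be 0 or 1", call. = FALSE)
  }
  target_label <- as.integer(target_label)
  if (!is.null(dataset$injected_ada)) {
    stop("dataset already carries an injected perturbation; double injection is forbidden",
         call. = FALSE)
  }
  if (length(unique(dataset$labels)) < 2L) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  images <- dataset$images
  for (i in which(dataset$labels == target_label)) {
    images[[i]] <- apply_ada(images[[i]], ada)
  }
  labeled_dataset(images, dataset$labels, patient_ids = dataset$patient_ids,
                  name = dataset$name,
                  injected_ada = list(spec = ada, target_label = target_label))
}

## ---- manifest I/O ---------------------------------------------------------

#' Write a dataset to disk as PNGs plus a manifest CSV
#'
#' Images are written as 8-bit grayscale PNGs under `root/images/`; the
#' manifest CSV (`path,label,patient_id`) holds paths relative to `root`.
#' Injection provenance, if any, is written as `provenance.json`.
#'
#' @param dataset A [labeled_dataset()].
#' @param root Dataset root directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dataset, root) {
  assert_labeled_dataset(dataset)
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  rel <- sprintf("images/img%06d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(dataset$images[[i]] / 255, file.path(root, rel[i]))
  }
  df <- data.frame(
    path = rel,
    label = dataset$labels,
    patient_id = if (is.null(dataset$patient_ids)) "" else dataset$patient_ids,
    stringsAsFactors = FALSE
  )
  manifest <- file.path(root, "manifest.csv")
  utils::write.csv(df, manifest, row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$injected_ada)) {
    jsonlite::write_json(
      list(spec = unclass(dataset$injected_ada$spec),
           target_label = dataset$injected_ada$target_label),
      file.path(root, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

#' Read a dataset from a manifest CSV
#'
#' Expects a CSV with header `path,label,patient_id` (`patient_id` optional),
#' paths relative to the manifest's directory, images as 8-bit grayscale
#' PNG. Reads `provenance.json` next to the manifest when present.
#' Write-then-read reproduces records in order.
#'
#' @param path Path to the manifest CSV.
#' @param name Dataset name; defaults to the manifest directory name.
#' @return A [labeled_dataset()].
#' @export
read_manifest <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  root <- dirname(path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  if (!all(c("path", "label") %in% names(df))) {
    stop("manifest must have columns `path` and `label`", call. = FALSE)
  }
  bad <- which(!df$label %in% c("0", "1"))
  if (length(bad)) {
    stop(sprintf("unknown label values in manifest rows: %s (labels must be 0 or 1)",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  files <- file.path(root, df$path)
  missing <- df$path[!file.exists(files)]
  if (length(missing)) {
    stop(sprintf("missing image files: %s",
                 paste(utils::head(missing, 10), collapse = ", ")), call. = FALSE)
  }
  images <- lapply(files, read_png_gray)
  pids <- NULL
  if ("patient_id" %in% names(df)) {
    v <- as.character(df$patient_id)
    if (!anyNA(v) && all(nzchar(v))) pids <- v
  }
  prov <- NULL
  prov_path <- file.path(root, "provenance.json")
  if (file.exists(prov_path)) {
    p <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
    prov <- list(spec = do.call(ada_spec, p$spec),
                 target_label = as.integer(p$target_label))
  }
  labeled_dataset(images, as.integer(df$label), patient_ids = pids,
                  name = if (is.null(name)) basename(root) else name,
                  injected_ada = prov)
}

## Read a PNG as an 8-bit grayscale matrix (first channel of color files).
read_png_gray <- function(file) {
  x <- png::readPNG(file)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  quantize8(x * 255)
}
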