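## Shared, lazily built fixtures. Everything is generated in code from fixed
## seeds; the cache only avoids re-generating within one test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

default_spec <- function() phantom_spec()

small_spec <- function() phantom_spec(height = 32, width = 32)

## 600-image disease-free pool at 64x64: the detective training pool.
pool600 <- function() {
  fixture("pool600", function() generate_phantom_pool(600, default_spec(), seed = 101))
}

## Detectives at the default injection magnitudes, trained on pool600.
sharp_detective <- function() {
  fixture("sharp_detective", function() {
    ts <- build_detective_trainset(pool600(), ada_spec("sharpness", blur_sigma = 1.0),
                                   seed = 202)
    shortcut_detective(ts, detective_config(seed = 303))
  })
}

contrast_detective <- function() {
  fixture("contrast_detective", function() {
    ts <- build_detective_trainset(pool600(), ada_spec("contrast", gamma = 1.3),
                                   seed = 202)
    shortcut_detective(ts, detective_config(seed = 303))
  })
}

## Certified versions (certification on a fresh shortcut-free set, 2000-rep
## bootstrap as in the protocol default).
cert_free_set <- function() {
  fixture("cert_free_set", function() generate_labeled_dataset(1000, default_spec(), seed = 404))
}

certified_sharp <- function() {
  fixture("certified_sharp", function() certify(sharp_detective(), cert_free_set(), seed = 11))
}

certified_contrast <- function() {
  fixture("certified_contrast", function() certify(contrast_detective(), cert_free_set(), seed = 12))
}

## A detective whose scores are a fixed constant: feature_linear member with
## zero weights scores 0.5 everywhere.
constant_detective <- function(image_size = c(64L, 64L)) {
  member <- list(backend = "feature_linear",
                 fit = list(type = "feature_linear",
                            beta = rep(0, length(adadetect:::feature_names()) + 1),
                            features = adadetect:::feature_names()),
                 val_auc = NA_real_, fold = 1L)
  structure(
    list(members = list(member), ada = ada_spec("contrast", gamma = 1.3),
         config = detective_config(ensemble_size = 1),
         image_size = image_size, trainset_name = "stub",
         unknown_provenance = FALSE, certification = NULL),
    class = "shortcut_detective"
  )
}

## Exhaustive pair-counting AUC: the independent oracle for compute_auc.
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
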