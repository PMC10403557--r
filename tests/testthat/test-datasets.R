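test_that("windowing maps the window interval onto [0, 255] exactly", {
  spec <- preprocess_spec(window_center = 100, window_width = 50, out_size = 8)
  raw <- matrix(rep(c(75, 125, 100, 130, 60, 100.1, 90, 95), 8), 8, 8)
  out <- window_and_quantize(raw, spec)
  expect_equal(out[1, 1], 0L)    # center - width/2
  expect_equal(out[2, 1], 255L)  # >= center + width/2
  expect_equal(out[3, 1], 128L)  # center: 127.5 rounds half-away to 128
  expect_equal(out[5, 1], 0L)    # below window clips
  expect_error(preprocess_spec(window_width = 0), "window_width")
})

test_that("constant rasters stay constant under any output size", {
  raw <- matrix(100, 37, 37)
  for (sz in c(8, 24, 64)) {
    out <- window_and_quantize(raw, preprocess_spec(100, 50, out_size = sz))
    expect_equal(dim(out), c(sz, sz))
    expect_true(all(out == 128L))
  }
})

test_that("full-range preprocessing is idempotent on 8-bit input", {
  img <- generate_phantom(phantom_spec(), seed = 4)
  out <- window_and_quantize(matrix(as.numeric(img), 64, 64),
                             preprocess_spec(127.5, 255, out_size = 64))
  expect_identical(out, img)
})

test_that("equal_random_split is disjoint, exhaustive and balanced for all n", {
  for (n in c(2:12, 99, 100, 1000)) {
    s <- equal_random_split(n, seed = n)
    expect_length(intersect(s$A, s$B), 0)
    expect_setequal(c(s$A, s$B), seq_len(n))
    expect_length(s$A, ceiling(n / 2))
    expect_length(s$B, floor(n / 2))
  }
  expect_identical(equal_random_split(1000, 5), equal_random_split(1000, 5))
  expect_false(identical(equal_random_split(1000, 5), equal_random_split(1000, 6)))
  expect_error(equal_random_split(1, 1), ">= 2")
})

test_that("a 46,894-image pool splits into two groups of 23,447", {
  s <- equal_random_split(46894, seed = 1)
  expect_length(s$A, 23447)
  expect_length(s$B, 23447)
})

test_that("trainset construction perturbs exactly the positive half", {
  pool <- generate_phantom_pool(100, phantom_spec(height = 32, width = 32),
                                seed = 21)
  ada <- ada_spec("contrast", gamma = 1.3)
  ts <- build_detective_trainset(pool, ada, seed = 8)
  expect_equal(sum(ts$labels == 1L), 50)
  expect_equal(sum(ts$labels == 0L), 50)
  expect_equal(ts$injected_ada$target_label, 1L)
  for (i in which(ts$labels == 0L)) expect_identical(ts$images[[i]], pool[[i]])
  for (i in which(ts$labels == 1L)) {
    expect_identical(ts$images[[i]], apply_ada(pool[[i]], ada))
  }
  ## identity spec: positives bit-identical to their pre-injection versions
  ts0 <- build_detective_trainset(pool, ada_spec("contrast", gamma = 1), seed = 8)
  for (i in which(ts0$labels == 1L)) expect_identical(ts0$images[[i]], pool[[i]])
  expect_error(build_detective_trainset(list(pool[[1]], matrix(0L, 8, 8)),
                                        ada, 1), "same dimensions")
})

test_that("default-magnitude contrast injection separates class means clearly", {
  pool <- fixture("pool500", function()
    generate_phantom_pool(500, phantom_spec(), seed = 31))
  ts <- build_detective_trainset(pool, ada_spec("contrast", gamma = 1.3), seed = 8)
  m <- vapply(ts$images, mean, numeric(1))
  m1 <- m[ts$labels == 1]; m0 <- m[ts$labels == 0]
  se <- sqrt(var(m1) / length(m1) + var(m0) / length(m0))
  expect_gt(abs(mean(m1) - mean(m0)), 3 * se)
})

test_that("injection touches exactly the target class and refuses doubles", {
  ds <- generate_labeled_dataset(60, phantom_spec(height = 32, width = 32),
                                 seed = 17)
  ada <- ada_spec("sharpness", blur_sigma = 1)
  inj1 <- inject_into_class(ds, ada, 1)
  for (i in which(ds$labels == 0L)) expect_identical(inj1$images[[i]], ds$images[[i]])
  for (i in which(ds$labels == 1L)) {
    expect_identical(inj1$images[[i]], apply_ada(ds$images[[i]], ada))
  }
  expect_error(inject_into_class(inj1, ada, 0), "double injection")
  ## identity spec changes nothing but provenance
  inj_id <- inject_into_class(ds, ada_spec("contrast", gamma = 1), 1)
  expect_identical(inj_id$images, ds$images)
  expect_false(is.null(inj_id$injected_ada))
  ## blur into label 0 vs label 1: gradient-energy class gaps of opposite sign
  inj0 <- inject_into_class(ds, ada, 0)
  gap <- function(d) {
    ge <- vapply(d$images, gradient_energy, numeric(1))
    mean(ge[d$labels == 1]) - mean(ge[d$labels == 0])
  }
  expect_lt(gap(inj1), 0)
  expect_gt(gap(inj0), 0)
})

test_that("manifest write/read round-trips records in order", {
  root <- withr::local_tempdir()
  ds <- generate_labeled_dataset(12, phantom_spec(height = 16, width = 16),
                                 seed = 23)
  ds <- inject_into_class(ds, ada_spec("sharpness", blur_sigma = 1), 1)
  manifest <- write_manifest(ds, root)
  back <- read_manifest(manifest, name = ds$name)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$patient_ids, ds$patient_ids)
  expect_identical(back$images, ds$images)
  expect_equal(back$injected_ada$spec, ds$injected_ada$spec)
  expect_equal(back$injected_ada$target_label, 1L)
  ## write(read(m)) reproduces the manifest byte-for-byte
  root2 <- withr::local_tempdir()
  m2 <- write_manifest(back, root2)
  expect_identical(readLines(m2), readLines(manifest))
})

test_that("bad manifests are rejected with the offending rows named", {
  root <- withr::local_tempdir()
  ds <- generate_labeled_dataset(3, phantom_spec(height = 16, width = 16),
                                 seed = 2)
  manifest <- write_manifest(ds, root)
  lines <- readLines(manifest)
  lines[3] <- sub(",[01],", ",2,", lines[3])
  writeLines(lines, manifest)
  expect_error(read_manifest(manifest), "unknown label.*2")

  manifest2 <- write_manifest(ds, root)
  file.remove(file.path(root, "images", "img000002.png"))
  expect_error(read_manifest(manifest2), "missing image")
  expect_error(read_manifest(file.path(root, "nope.csv")), "not found")
})
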