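test_that("a constant scorer passes Exam 1 with AUC exactly 0.5", {
  d <- constant_detective()
  free <- cert_free_set()
  e1 <- run_exam1(d, free, replicates = 200, seed = 1)
  expect_equal(e1$auc$auc, 0.5)
  expect_equal(e1$auc$ci_low, 0.5)
  expect_equal(e1$auc$ci_high, 0.5)
  expect_true(e1$passed)
  ## tau1 = 0 still passes only because the AUC is exactly 0.5
  expect_true(run_exam1(d, free, tau1 = 0, replicates = 50, seed = 1)$passed)
})

test_that("Exam 1 refuses a dataset carrying injection provenance", {
  d <- constant_detective()
  injected <- inject_into_class(cert_free_set(), ada_spec("contrast", gamma = 1.3), 1)
  expect_error(run_exam1(d, injected, replicates = 50), "injection provenance")
})

test_that("Exam 2 refuses an already-injected base dataset", {
  d <- sharp_detective()
  injected <- inject_into_class(cert_free_set(), d$ada, 1)
  expect_error(run_exam2(d, injected, target_label = 1, replicates = 50),
               "double injection")
})

test_that("an identity-spec injection makes Exam 2 fail at chance level", {
  d <- constant_detective()
  d$ada <- ada_spec("contrast", gamma = 1)
  e2 <- run_exam2(d, cert_free_set(), target_label = 1, replicates = 200, seed = 2)
  expect_false(e2$passed)
  expect_lt(abs(e2$auc$auc - 0.5), 0.1)
})

test_that("certification passes default-magnitude detectives and stamps them", {
  for (d in list(certified_sharp(), certified_contrast())) {
    cert <- d$certification
    expect_true(cert$passed)
    expect_true(cert$exam1$passed)
    expect_true(cert$exam2a$passed)
    expect_true(cert$exam2b$passed)
    expect_gte(cert$exam2a$auc$auc, 0.99)
    expect_lte(cert$exam2b$auc$auc, 0.01)
    expect_lte(abs(cert$exam1$auc$auc - 0.5), 0.07)
    ## report invariant: stored flag equals the threshold conjunction
    expect_equal(cert$passed,
                 abs(cert$exam1$auc$auc - 0.5) <= cert$tau1 &&
                   cert$exam2a$auc$auc >= 1 - cert$tau2 &&
                   cert$exam2b$auc$auc <= cert$tau2)
    ## injected signal can only help: Exam 2a AUC >= Exam 1 AUC
    expect_gte(cert$exam2a$auc$auc, cert$exam1$auc$auc)
  }
})

test_that("certification fails a detective trained on identity-spec data", {
  pool <- pool600()[1:200]
  ts <- build_detective_trainset(pool, ada_spec("sharpness", blur_sigma = 0), seed = 3)
  d <- shortcut_detective(ts, detective_config(seed = 4))
  d <- certify(d, cert_free_set(), replicates = 200, seed = 5)
  expect_false(d$certification$passed)
  expect_false(d$certification$exam2a$passed)
})

test_that("certification is stable across training seeds", {
  for (s in c(7, 19)) {
    ts <- build_detective_trainset(pool600(), ada_spec("sharpness", blur_sigma = 1.0),
                                   seed = s)
    d <- shortcut_detective(ts, detective_config(seed = s + 1))
    d <- certify(d, cert_free_set(), replicates = 200, seed = s + 2)
    expect_true(d$certification$passed)
  }
})

test_that("scanning refuses uncertified detectives and writes nothing", {
  out <- file.path(withr::local_tempdir(), "report.json")
  ds <- cert_free_set()
  expect_error(scan_dataset(sharp_detective(), ds, out_path = out),
               "not certified")
  expect_false(file.exists(out))
  ## a failed certification is just as unacceptable
  ts <- build_detective_trainset(pool600()[1:200],
                                 ada_spec("sharpness", blur_sigma = 0), seed = 3)
  dfail <- shortcut_detective(ts, detective_config(seed = 4))
  dfail <- certify(dfail, ds, replicates = 100, seed = 5)
  expect_error(scan_dataset(dfail, ds, out_path = out), "not certified")
  expect_false(file.exists(out))
})

test_that("scans of shortcut-free data are clean; injected shortcuts are flagged", {
  dets <- list(certified_sharp(), certified_contrast())
  clean <- generate_labeled_dataset(400, phantom_spec(), seed = 901)
  rep_clean <- scan_dataset(dets, clean, replicates = 500, seed = 31)
  verdicts <- vapply(rep_clean$entries, `[[`, "", "verdict")
  expect_true(all(verdicts == "no_shortcut_detected"))
  expect_false(any_shortcut(rep_clean))

  dirty <- inject_into_class(clean, ada_spec("sharpness", blur_sigma = 1.0), 1)
  dirty$injected_ada <- NULL # scan treats it as an ordinary audited dataset
  out <- file.path(withr::local_tempdir(), "scan.json")
  rep_dirty <- scan_dataset(dets, dirty, replicates = 500, seed = 32,
                            out_path = out)
  expect_equal(rep_dirty$entries$sharpness$verdict, "shortcut_detected")
  expect_true(any_shortcut(rep_dirty))
  expect_true(file.exists(out))
  js <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(js$entries$sharpness$verdict, "shortcut_detected")
})

test_that("label flips mirror scan AUCs around 0.5 and preserve verdicts", {
  dets <- list(certified_sharp())
  clean <- generate_labeled_dataset(300, phantom_spec(), seed = 902)
  dirty <- inject_into_class(clean, ada_spec("sharpness", blur_sigma = 1.0), 1)
  dirty$injected_ada <- NULL
  flipped <- labeled_dataset(dirty$images, 1L - dirty$labels,
                             patient_ids = dirty$patient_ids, name = "flipped")
  r1 <- scan_dataset(dets, dirty, replicates = 300, seed = 41)
  r2 <- scan_dataset(dets, flipped, replicates = 300, seed = 41)
  expect_equal(r2$entries[[1]]$auc$auc, 1 - r1$entries[[1]]$auc$auc)
  expect_equal(r2$entries[[1]]$verdict, r1$entries[[1]]$verdict)
})
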