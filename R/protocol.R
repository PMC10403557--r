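#' Exam 1: chance-level performance on a shortcut-free dataset
#'
#' Scores a labeled dataset that is known to be free of the detective's
#' shortcut and checks that the detective cannot separate the classes: the
#' exam passes iff `|AUC - 0.5| <= tau1`. A dataset carrying injection
#' provenance is refused — that would be the wrong exam.
#'
#' @param detective A trained [shortcut_detective()].
#' @param dataset A shortcut-free [labeled_dataset()] with both classes.
#' @param tau1 Tolerance around 0.5 (default 0.07).
#' @param replicates,seed Bootstrap controls, see [bootstrap_auc_ci()].
#' @return A list with the [bootstrap_auc_ci()] result (`auc`), `passed`,
#'   and the tolerance used.
#' @export
run_exam1 <- function(detective, dataset, tau1 = 0.07,
                      replicates = 2000, seed = 1) {
  assert_labeled_dataset(dataset)
  assert_scalar_num(tau1, "tau1", min = 0)
  if (!is.null(dataset$injected_ada)) {
    stop("Exam 1 requires a shortcut-free dataset; this one carries injection provenance",
         call. = FALSE)
  }
  if (length(unique(dataset$labels)) < 2L) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  scores <- predict(detective, dataset)
  res <- bootstrap_auc_ci(scores, dataset$labels, replicates = replicates,
                          seed = seed)
  list(auc = res, passed = abs(res$auc - 0.5) <= tau1, tau1 = tau1,
       dataset = dataset$name)
}

#' Exam 2: extreme performance when the known shortcut is injected
#'
#' Injects the detective's own ADA spec into one class of a shortcut-free
#' base dataset and checks that the detective separates the classes almost
#' perfectly: with the injection in the positive class (Exam 2a) the exam
#' passes iff `AUC >= 1 - tau2`; in the negative class (Exam 2b) iff
#' `AUC <= tau2` (an AUC of 0 under flipped injection is perfect
#' classification, only the label assignment differs).
#'
#' @inheritParams run_exam1
#' @param base A shortcut-free [labeled_dataset()]; injection is performed
#'   here, so an already-injected dataset is refused.
#' @param target_label Class receiving the injection: 1 (Exam 2a) or 0
#'   (Exam 2b).
#' @param tau2 Tolerance from the extremes (default 0.01).
#' @return As [run_exam1()].
#' @export
run_exam2 <- function(detective, base, target_label, tau2 = 0.01,
                      replicates = 2000, seed = 1) {
  assert_scalar_num(tau2, "tau2", min = 0)
  injected <- inject_into_class(base, detective$ada, target_label)
  scores <- predict(detective, injected)
  res <- bootstrap_auc_ci(scores, injected$labels, replicates = replicates,
                          seed = seed)
  passed <- if (as.integer(target_label) == 1L) {
    res$auc >= 1 - tau2
  } else {
    res$auc <= tau2
  }
  list(auc = res, passed = passed, tau2 = tau2,
       target_label = as.integer(target_label), dataset = base$name)
}

#' Certify a shortcut detective
#'
#' Runs the full qualification protocol on one shortcut-free dataset: Exam 1
#' (chance-level AUC on the data as-is), Exam 2a (AUC near 1 with the
#' detective's ADA injected into the positive class) and Exam 2b (AUC near 0
#' with it injected into the negative class). All three exams always run.
#' The detective passes only the conjunction; the report is stamped onto the
#' detective, which [scan_dataset()] later requires.
#'
#' @inheritParams run_exam1
#' @param shortcut_free A shortcut-free [labeled_dataset()].
#' @param tau2 Exam-2 tolerance from the extremes (default 0.01).
#' @return The detective with its `certification` field set to a
#'   `certification_report`.
#' @export
certify <- function(detective, shortcut_free, tau1 = 0.07, tau2 = 0.01,
                    replicates = 2000, seed = 1) {
  if (!inherits(detective, "shortcut_detective")) {
    stop("`detective` must be a shortcut_detective", call. = FALSE)
  }
  e1 <- run_exam1(detective, shortcut_free, tau1 = tau1,
                  replicates = replicates, seed = seed)
  e2a <- run_exam2(detective, shortcut_free, target_label = 1L, tau2 = tau2,
                   replicates = replicates, seed = seed + 1L)
  e2b <- run_exam2(detective, shortcut_free, target_label = 0L, tau2 = tau2,
                   replicates = replicates, seed = seed + 2L)
  passed <- e1$passed && e2a$passed && e2b$passed
  report <- structure(
    list(exam1 = e1, exam2a = e2a, exam2b = e2b,
         tau1 = tau1, tau2 = tau2, passed = passed,
         dataset = shortcut_free$name,
         ada = detective$ada,
         fingerprint = certification_fingerprint(e1, e2a, e2b, tau1, tau2)),
    class = "certification_report"
  )
  detective$certification <- report
  detective
}

certification_fingerprint <- function(e1, e2a, e2b, tau1, tau2) {
  sprintf("auc:%.6f/%.6f/%.6f;tau:%g/%g",
          e1$auc$auc, e2a$auc$auc, e2b$auc$auc, tau1, tau2)
}

#' @export
print.certification_report <- function(x, ...) {
  cat(sprintf("Certification (%s detective) on '%s': %s\n",
              x$ada$attribute, x$dataset,
              if (x$passed) "PASSED" else "FAILED"))
  rows <- list(
    c(sprintf("Exam 1: shortcut-free (|AUC-0.5| <= %g)", x$tau1),
      format(x$exam1$auc), if (x$exam1$passed) "pass" else "FAIL"),
    c(sprintf("Exam 2a: injected into label 1 (AUC >= %g)", 1 - x$tau2),
      format(x$exam2a$auc), if (x$exam2a$passed) "pass" else "FAIL"),
    c(sprintf("Exam 2b: injected into label 0 (AUC <= %g)", x$tau2),
      format(x$exam2b$auc), if (x$exam2b$passed) "pass" else "FAIL")
  )
  for (r in rows) cat(sprintf("  %-52s %-20s %s\n", r[[1]], r[[2]], r[[3]]))
  invisible(x)
}

#' Scan a labeled dataset for acquisition-dependent shortcuts
#'
#' Deploys certified detectives on a binary-labeled dataset. For each
#' detective the dataset is scored, AUC and its stratified-bootstrap CI are
#' computed, and a verdict is issued: `shortcut_detected` iff
#' `|AUC - 0.5| > delta` AND the CI excludes 0.5 (an effect-size guard plus
#' a significance guard). Any uncertified detective makes the whole scan
#' refuse before any scoring or writing — the central safety contract: an
#' unqualified detective's verdict would be meaningless.
#'
#' @param detectives A certified [shortcut_detective()] or a list of them.
#' @param dataset A [labeled_dataset()] with both classes.
#' @param delta Minimum AUC deviation from 0.5 to call a shortcut
#'   (default 0.10).
#' @param replicates,seed Bootstrap controls.
#' @param out_path Optional path; the report is written there as JSON.
#' @return An object of class `scan_report`.
#' @export
scan_dataset <- function(detectives, dataset, delta = 0.10,
                         replicates = 2000, seed = 1, out_path = NULL) {
  if (inherits(detectives, "shortcut_detective")) detectives <- list(detectives)
  if (!is.list(detectives) || length(detectives) == 0L) {
    stop("`detectives` must be one or more shortcut_detective objects",
         call. = FALSE)
  }
  assert_labeled_dataset(dataset)
  assert_scalar_num(delta, "delta", min = 0)
  for (i in seq_along(detectives)) {
    d <- detectives[[i]]
    if (!inherits(d, "shortcut_detective")) {
      stop(sprintf("entry %d is not a shortcut_detective", i), call. = FALSE)
    }
    if (!is_certified(d)) {
      stop(sprintf("refusing to scan: detective %d (%s) is not certified",
                   i, d$ada$attribute), call. = FALSE)
    }
  }
  if (length(unique(dataset$labels)) < 2L) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  entries <- vector("list", length(detectives))
  for (i in seq_along(detectives)) {
    d <- detectives[[i]]
    scores <- predict(d, dataset)
    res <- bootstrap_auc_ci(scores, dataset$labels, replicates = replicates,
                            seed = seed + i - 1L)
    excl <- res$ci_low > 0.5 || res$ci_high < 0.5
    verdict <- if (abs(res$auc - 0.5) > delta && excl) {
      "shortcut_detected"
    } else {
      "no_shortcut_detected"
    }
    entries[[i]] <- list(ada = d$ada$attribute, spec = d$ada, auc = res,
                         verdict = verdict,
                         fingerprint = d$certification$fingerprint)
  }
  names(entries) <- make.unique(vapply(entries, `[[`, "", "ada"))
  report <- structure(
    list(dataset = dataset$name, delta = delta, entries = entries),
    class = "scan_report"
  )
  if (!is.null(out_path)) {
    jsonlite::write_json(scan_report_json(report), out_path,
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

scan_report_json <- function(report) {
  list(dataset = report$dataset, delta = report$delta,
       entries = lapply(report$entries, function(e) {
         list(ada = e$ada, spec = unclass(e$spec),
              auc = e$auc$auc, ci_low = e$auc$ci_low, ci_high = e$auc$ci_high,
              n_pos = e$auc$n_pos, n_neg = e$auc$n_neg,
              replicates = e$auc$replicates,
              verdict = e$verdict, certification = e$fingerprint)
       }))
}

#' Did a scan detect any shortcut?
#' @param report A `scan_report`.
#' @return `TRUE` if any entry's verdict is `shortcut_detected`.
#' @export
any_shortcut <- function(report) {
  stopifnot(inherits(report, "scan_report"))
  any(vapply(report$entries, `[[`, "", "verdict") == "shortcut_detected")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("Shortcut scan of '%s' (delta = %g):\n", x$dataset, x$delta))
  for (nm in names(x$entries)) {
    e <- x$entries[[nm]]
    cat(sprintf("  %-10s %-20s %s\n", nm, format(e$auc), e$verdict))
  }
  invisible(x)
}
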