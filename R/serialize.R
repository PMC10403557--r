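#' Save a shortcut detective to a directory
#'
#' Writes `detective.json` (config, ADA spec, certification block, member
#' metadata) and `members.json` (backend weights as plain numeric arrays)
#' under `dir`. Everything is text; [load_detective()] restores the object
#' and verifies integrity.
#'
#' @param detective A [shortcut_detective()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_detective <- function(detective, dir) {
  if (!inherits(detective, "shortcut_detective")) {
    stop("`detective` must be a shortcut_detective", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cert <- detective$certification
  meta <- list(
    config = unclass(detective$config),
    ada = unclass(detective$ada),
    image_size = detective$image_size,
    trainset_name = detective$trainset_name,
    unknown_provenance = detective$unknown_provenance,
    certification = if (is.null(cert)) NULL else serialize_certification(cert)
  )
  jsonlite::write_json(meta, file.path(dir, "detective.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  members <- lapply(detective$members, serialize_member)
  jsonlite::write_json(members, file.path(dir, "members.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

serialize_member <- function(m) {
  if (m$backend == "feature_linear") {
    list(backend = m$backend, val_auc = m$val_auc, fold = m$fold,
         beta = m$fit$beta, features = m$fit$features)
  } else {
    p <- m$fit$params
    list(backend = m$backend, val_auc = m$val_auc, fold = m$fold,
         H = m$fit$H, W = m$fit$W, best_epoch = m$fit$best_epoch,
         params = lapply(p, function(x) {
           if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
           else list(dim = NULL, data = as.numeric(x))
         }))
  }
}

serialize_auc <- function(a) {
  a[c("auc", "ci_low", "ci_high", "n_pos", "n_neg", "replicates", "level",
      "seed", "ci_flag")]
}

serialize_certification <- function(cert) {
  list(
    exam1 = list(auc = serialize_auc(cert$exam1$auc),
                 passed = cert$exam1$passed, dataset = cert$exam1$dataset),
    exam2a = list(auc = serialize_auc(cert$exam2a$auc),
                  passed = cert$exam2a$passed),
    exam2b = list(auc = serialize_auc(cert$exam2b$auc),
                  passed = cert$exam2b$passed),
    tau1 = cert$tau1, tau2 = cert$tau2, passed = cert$passed,
    dataset = cert$dataset, ada = unclass(cert$ada),
    fingerprint = cert$fingerprint
  )
}

#' Load a shortcut detective from a directory
#'
#' Restores a detective written by [save_detective()]. The ADA spec is
#' re-validated and the certification block is integrity-checked: the
#' stored pass flag must equal the threshold conjunction recomputed from the
#' stored exam AUCs, and the fingerprint must match.
#'
#' @param dir Directory written by [save_detective()].
#' @return A [shortcut_detective()].
#' @export
load_detective <- function(dir) {
  meta_path <- file.path(dir, "detective.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("no detective found at %s", dir), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  config <- do.call(detective_config, meta$config)
  ada <- do.call(ada_spec, meta$ada)
  members_raw <- jsonlite::read_json(file.path(dir, "members.json"),
                                     simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE)
  members <- lapply(members_raw, deserialize_member)
  cert <- NULL
  if (!is.null(meta$certification)) {
    cert <- deserialize_certification(meta$certification, ada)
  }
  structure(
    list(members = members, ada = ada, config = config,
         image_size = as.integer(meta$image_size),
         trainset_name = meta$trainset_name,
         unknown_provenance = isTRUE(meta$unknown_provenance),
         certification = cert),
    class = "shortcut_detective"
  )
}

deserialize_member <- function(m) {
  if (m$backend == "feature_linear") {
    fit <- list(type = "feature_linear",
                beta = as.numeric(unlist(m$beta)),
                features = as.character(unlist(m$features)))
  } else {
    params <- lapply(m$params, function(p) {
      x <- as.numeric(unlist(p$data))
      d <- as.integer(unlist(p$dim))
      if (length(d) == 2L) dim(x) <- d
      x
    })
    fit <- list(type = "reference_convnet", params = params,
                H = as.integer(m$H), W = as.integer(m$W),
                val_auc = m$val_auc, best_epoch = m$best_epoch)
  }
  list(backend = m$backend, fit = fit,
       val_auc = if (is.null(m$val_auc)) NA_real_ else as.numeric(m$val_auc),
       fold = m$fold)
}

deserialize_auc <- function(a) {
  structure(list(auc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high,
                 n_pos = a$n_pos, n_neg = a$n_neg, replicates = a$replicates,
                 level = a$level, seed = a$seed, ci_flag = isTRUE(a$ci_flag)),
            class = "auc_result")
}

deserialize_certification <- function(s, ada) {
  e1 <- list(auc = deserialize_auc(s$exam1$auc), passed = s$exam1$passed,
             tau1 = s$tau1, dataset = s$exam1$dataset)
  e2a <- list(auc = deserialize_auc(s$exam2a$auc), passed = s$exam2a$passed,
              tau2 = s$tau2, target_label = 1L)
  e2b <- list(auc = deserialize_auc(s$exam2b$auc), passed = s$exam2b$passed,
              tau2 = s$tau2, target_label = 0L)
  recomputed <- (abs(e1$auc$auc - 0.5) <= s$tau1) &&
    (e2a$auc$auc >= 1 - s$tau2) && (e2b$auc$auc <= s$tau2)
  if (!identical(recomputed, isTRUE(s$passed))) {
    stop("certification block corrupt: stored pass flag disagrees with stored AUCs and thresholds",
         call. = FALSE)
  }
  fp <- certification_fingerprint(e1, e2a, e2b, s$tau1, s$tau2)
  if (!identical(fp, s$fingerprint)) {
    stop("certification block corrupt: fingerprint mismatch", call. = FALSE)
  }
  structure(
    list(exam1 = e1, exam2a = e2a, exam2b = e2b, tau1 = s$tau1,
         tau2 = s$tau2, passed = isTRUE(s$passed), dataset = s$dataset,
         ada = ada, fingerprint = fp),
    class = "certification_report"
  )
}
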