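#' Training configuration for a shortcut detective
#'
#' @param backend `"feature_linear"` (global image features + ridge-penalized
#'   logistic scorer; seconds-scale) or `"reference_convnet"` (a small
#'   convolutional network trained end-to-end; see [reference_convnet]).
#'   The shortcut signal is global, so both backends detect it; the convnet
#'   matches the model class used for full-scale audits.
#' @param ensemble_size Number of ensemble members (default 5), each trained
#'   on a distinct training-validation partition.
#' @param seed Integer seed governing partitions, initialization and batch
#'   order.
#' @param lambda Ridge penalty of the feature_linear scorer.
#' @param max_epochs,patience,learning_rate,batch_size Convnet training
#'   controls: epoch cap, early-stopping patience on validation AUC, Adam
#'   step size, minibatch size.
#' @return An object of class `detective_config`.
#' @export
detective_config <- function(backend = c("feature_linear", "reference_convnet"),
                             ensemble_size = 5, seed = 1,
                             lambda = 1e-2,
                             max_epochs = 15, patience = 3,
                             learning_rate = 3e-3, batch_size = 32) {
  backend <- match.arg(backend)
  assert_scalar_num(ensemble_size, "ensemble_size", min = 1)
  assert_scalar_num(lambda, "lambda", min = 0, strict_min = TRUE)
  assert_scalar_num(max_epochs, "max_epochs", min = 1)
  assert_scalar_num(patience, "patience", min = 1)
  assert_scalar_num(learning_rate, "learning_rate", min = 0, strict_min = TRUE)
  assert_scalar_num(batch_size, "batch_size", min = 1)
  structure(
    list(backend = backend, ensemble_size = as.integer(ensemble_size),
         seed = as.integer(seed), lambda = lambda,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         learning_rate = learning_rate, batch_size = as.integer(batch_size)),
    class = "detective_config"
  )
}

## Disjoint validation folds; grouped by patient when IDs are available so
## no patient straddles a member's train/validation boundary.
make_folds <- function(n, k, patient_ids = NULL, seed = 1) {
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(n))
  units <- unique(patient_ids)
  ord <- with_seed(seed, sample(units))
  unit_fold <- rep(seq_len(k), length.out = length(ord))
  names(unit_fold) <- ord
  unname(unit_fold[patient_ids])
}

#' Train an ensemble shortcut detective
#'
#' Fits an ensemble of binary scorers on a shortcut training set — images
#' split into a perturbed positive class and an untouched negative class.
#' Each member trains on a distinct training-validation partition (disjoint
#' validation folds, grouped by patient when patient IDs exist); convnet
#' members keep the epoch with the best validation AUC (early stopping).
#' Deterministic given the config seed.
#'
#' @param trainset A [labeled_dataset()] with both classes. Normally built
#'   by [build_detective_trainset()] so injection provenance is present;
#'   training on data without provenance is allowed but flagged.
#' @param config A [detective_config()].
#' @param ada The [ada_spec()] the detective hunts; defaults to the
#'   trainset's injected spec.
#' @return An object of class `shortcut_detective`: ensemble members, the
#'   ADA spec, the config, per-member validation AUCs, and (after
#'   [certify()]) a certification report. Score new images with
#'   [predict.shortcut_detective()].
#' @seealso [certify()], [scan_dataset()]
#' @export
shortcut_detective <- function(trainset, config = detective_config(),
                               ada = NULL) {
  assert_labeled_dataset(trainset, "trainset")
  if (!inherits(config, "detective_config")) {
    stop("`config` must be a detective_config", call. = FALSE)
  }
  if (length(unique(trainset$labels)) < 2L) {
    stop("trainset must contain both classes", call. = FALSE)
  }
  unknown_provenance <- is.null(trainset$injected_ada)
  if (is.null(ada)) {
    if (unknown_provenance) {
      stop("trainset has no injection provenance; supply `ada` explicitly",
           call. = FALSE)
    }
    ada <- trainset$injected_ada$spec
  }
  assert_ada_spec(ada)
  if (unknown_provenance) {
    warning("training on a dataset without injection provenance; detective flagged",
            call. = FALSE)
  }

  n <- length(trainset$images)
  y <- trainset$labels
  k <- config$ensemble_size
  folds <- make_folds(n, k, trainset$patient_ids, seed = config$seed)

  X <- if (config$backend == "feature_linear") {
    feature_matrix(trainset$images)
  } else NULL

  members <- vector("list", k)
  for (m in seq_len(k)) {
    val <- folds == m
    if (k == 1L) val <- rep(FALSE, n) # single member: train on everything
    tr <- !val
    if (length(unique(y[tr])) < 2L) {
      stop("a training partition lost a class; use more data or fewer members",
           call. = FALSE)
    }
    member_seed <- config$seed + 1000L * m
    if (config$backend == "feature_linear") {
      fit <- fit_feature_linear(X[tr, , drop = FALSE], y[tr],
                                lambda = config$lambda)
      val_auc <- if (any(val) && length(unique(y[val])) == 2L) {
        compute_auc(score_feature_linear(fit, X[val, , drop = FALSE]), y[val])
      } else NA_real_
    } else {
      fit <- fit_convnet(trainset$images[tr], y[tr],
                         val_images = trainset$images[val], val_y = y[val],
                         max_epochs = config$max_epochs,
                         patience = config$patience,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size,
                         seed = member_seed)
      val_auc <- fit$val_auc
    }
    members[[m]] <- list(backend = config$backend, fit = fit,
                         val_auc = val_auc, fold = m)
  }

  structure(
    list(members = members, ada = ada, config = config,
         image_size = dim(trainset$images[[1]]),
         trainset_name = trainset$name,
         unknown_provenance = unknown_provenance,
         certification = NULL),
    class = "shortcut_detective"
  )
}

## ---- feature_linear backend -----------------------------------------------

fit_feature_linear <- function(X, y, lambda) {
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(stats::coef(fit, s = lambda))
  list(type = "feature_linear", beta = beta, features = colnames(X))
}

score_feature_linear <- function(fit, X) {
  as.numeric(stats::plogis(fit$beta[1] + X %*% fit$beta[-1]))
}

score_member <- function(member, images, X = NULL) {
  if (member$backend == "feature_linear") {
    if (is.null(X)) X <- feature_matrix(images)
    score_feature_linear(member$fit, X)
  } else {
    predict_convnet(member$fit, images)
  }
}

## ---- methods --------------------------------------------------------------

#' Score images with a shortcut detective
#'
#' Ensemble score: the per-image arithmetic mean of the member
#' probabilities, each in \[0, 1\]. Inference is pure — identical inputs
#' give identical scores.
#'
#' @param object A [shortcut_detective()].
#' @param newdata A list of images or a [labeled_dataset()]; image size must
#'   match the training size.
#' @param ... Unused.
#' @return A numeric vector of probabilities, one per image, in input order.
#' @export
predict.shortcut_detective <- function(object, newdata, ...) {
  images <- if (inherits(newdata, "labeled_dataset")) newdata$images else newdata
  if (!is.list(images) || length(images) == 0L) {
    stop("`newdata` must be a nonempty list of images or a labeled_dataset",
         call. = FALSE)
  }
  sz <- dim(images[[1]])
  if (!all(vapply(images, function(im) all(dim(im) == sz), logical(1)))) {
    stop("images must all have the same dimensions", call. = FALSE)
  }
  if (!all(sz == object$image_size)) {
    stop(sprintf("image size %dx%d does not match the detective's training size %dx%d",
                 sz[1], sz[2], object$image_size[1], object$image_size[2]),
         call. = FALSE)
  }
  X <- if (object$config$backend == "feature_linear") feature_matrix(images) else NULL
  scores <- vapply(object$members,
                   function(m) score_member(m, images, X = X),
                   numeric(length(images)))
  if (length(images) == 1L) scores <- matrix(scores, nrow = 1L)
  rowMeans(scores)
}

#' @export
print.shortcut_detective <- function(x, ...) {
  cat(sprintf("Shortcut detective (%s): %d members, %s attribute, trained on '%s'\n",
              x$config$backend, length(x$members), x$ada$attribute,
              x$trainset_name))
  if (is.null(x$certification)) {
    cat("  certification: none\n")
  } else {
    cat(sprintf("  certification: %s\n",
                if (x$certification$passed) "PASSED" else "FAILED"))
  }
  invisible(x)
}

#' @export
summary.shortcut_detective <- function(object, ...) {
  vaucs <- vapply(object$members, function(m) m$val_auc, numeric(1))
  print(object)
  print(object$ada)
  cat(sprintf("  member validation AUCs: %s\n",
              paste(fmt_num(vaucs, 3), collapse = ", ")))
  if (object$unknown_provenance) {
    cat("  flag: trained on data without injection provenance\n")
  }
  if (!is.null(object$certification)) print(object$certification)
  invisible(object)
}

is_certified <- function(detective) {
  inherits(detective, "shortcut_detective") &&
    !is.null(detective$certification) &&
    isTRUE(detective$certification$passed)
}
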