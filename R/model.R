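## Diagnostic classifier: RBF-kernel SVM with grid search, recursive
## feature elimination by the kernel margin criterion, data-driven
## feature-count selection, and a decision threshold calibrated at fixed
## training specificity.

Y_LEVELS <- c("control", "case")

as_class_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (!all(y %in% Y_LEVELS))
    stop("class labels must be 'case'/'control'")
  factor(y, levels = Y_LEVELS)
}

#' Model configuration
#'
#' @param grid data.frame of candidate `(C, gamma)` pairs; default a
#'   powers-of-two lattice with C in 2^-5..2^15 and gamma in 2^-15..2^3
#'   (step 2 in the exponent, the usual coarse grid).
#' @param cv_folds number of stratified cross-validation folds
#'   (default 4).
#' @param target_specificity training specificity at which the decision
#'   threshold is set (default 0.90).
#' @param seed RNG seed governing fold assignment.
#' @return list of class `model_config`.
#' @export
model_config <- function(grid = default_svm_grid(), cv_folds = 4L,
                         target_specificity = 0.90, seed = 1L) {
  stopifnot(all(grid$C > 0), all(grid$gamma > 0), cv_folds >= 2L,
            target_specificity > 0, target_specificity < 1)
  structure(list(grid = grid, cv_folds = as.integer(cv_folds),
                 target_specificity = target_specificity,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Default coarse powers-of-two grid for (C, gamma)
#' @return data.frame with columns `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  expand.grid(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' Split a cohort into training and test sets
#'
#' Uniform random split without replacement; the remaining samples form
#' the test set. The partition is disjoint and exhaustive.
#'
#' @param case_ids,control_ids sample identifiers.
#' @param n_case_train,n_control_train training sizes.
#' @param seed RNG seed.
#' @return list with `train` and `test`, each holding `cases` and
#'   `controls`.
#' @export
split_cohort <- function(case_ids, control_ids, n_case_train,
                         n_control_train, seed = 1L) {
  if (n_case_train > length(case_ids) || n_control_train > length(control_ids))
    stop("requested training sizes exceed available samples")
  with_seed(seed, {
    tr_ca <- sort(sample(case_ids, n_case_train))
    tr_co <- sort(sample(control_ids, n_control_train))
    out <- list(train = list(cases = tr_ca, controls = tr_co),
                test = list(cases = setdiff(case_ids, tr_ca),
                            controls = setdiff(control_ids, tr_co)))
    if (length(out$test$cases) + length(out$test$controls) == 0L)
      warning("test set is empty: training sizes equal the totals")
    out
  })
}

# Stratified fold assignment, balanced within each class.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("need at least ", k, " samples per class for ", k, "-fold CV")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_rbf_svm <- function(x, y, C, gamma) {
  if (nlevels(droplevels(y)) < 2L)
    stop("degenerate single-class training data")
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

# libsvm orients the decision value toward the class that appears first
# in the training data, so the sign must be read off the model.
svm_orientation <- function(model) {
  if (startsWith(colnames(model$decision.values)[1], "case")) 1 else -1
}

# Decision scores oriented so that larger means more case-like.
svm_scores <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1]
  if (!startsWith(colnames(dv)[1], "case")) s <- -s
  unname(s)
}

auc_of_scores <- function(scores, y) {
  roc_auc(scores[y == "case"], scores[y == "control"])$auc
}

# Mean per-fold out-of-fold AUROC plus the pooled out-of-fold scores.
cv_scores <- function(x, y, C, gamma, fold) {
  k <- max(fold)
  scores <- numeric(length(y))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- fit_rbf_svm(x[tr, , drop = FALSE], y[tr], C, gamma)
    scores[!tr] <- svm_scores(m, x[!tr, , drop = FALSE])
    fold_auc[f] <- auc_of_scores(scores[!tr], y[!tr])
  }
  list(scores = scores, fold_auc = fold_auc,
       mean_auc = mean(fold_auc),
       pooled_auc = auc_of_scores(scores, y))
}

#' Grid search for the RBF-SVM hyperparameters
#'
#' Maximises the mean out-of-fold AUROC over stratified folds. Ties are
#' broken toward smaller C, then smaller gamma.
#'
#' @param x training feature matrix (samples x features).
#' @param y class labels ("case"/"control").
#' @param grid data.frame of `(C, gamma)` candidates.
#' @param cv_folds number of stratified folds.
#' @param fold optional precomputed fold assignment (overrides
#'   `cv_folds`).
#' @return list with `C`, `gamma`, `cv_auc` and the full `path`.
#' @export
svm_grid_search <- function(x, y, grid = default_svm_grid(), cv_folds = 4L,
                            fold = NULL) {
  y <- as_class_factor(y)
  if (is.null(fold)) fold <- stratified_folds(y, cv_folds)
  grid <- grid[order(grid$C, grid$gamma), , drop = FALSE]
  auc <- vapply(seq_len(nrow(grid)), function(i)
    cv_scores(x, y, grid$C[i], grid$gamma[i], fold)$mean_auc, numeric(1))
  best <- which.max(auc)  # first max; grid sorted by (C, gamma)
  list(C = grid$C[best], gamma = grid$gamma[best], cv_auc = auc[best],
       path = cbind(grid, cv_auc = auc))
}

# Margin criterion J = 1/2 sum_ij alpha_i alpha_j y_i y_j K(x_i, x_j),
# evaluated on the support vectors (coefs = alpha_i * y_i).
svm_J <- function(K, coefs) 0.5 * drop(crossprod(coefs, K %*% coefs))

#' Rank features by kernel recursive feature elimination
#'
#' At each round an RBF SVM is fitted on the surviving features and the
#' margin criterion `J = 1/2 sum alpha_i alpha_j y_i y_j K(x_i, x_j)` is
#' computed. For every feature, `J` is recomputed with that feature's
#' column removed from the kernel while the dual coefficients are held
#' fixed; the feature with the smallest `|J - J(-f)|` is eliminated
#' (ties to the lowest column index), the SVM is refitted, and the
#' process repeats until one feature remains.
#'
#' @param x standardized training feature matrix with column names.
#' @param y class labels ("case"/"control").
#' @param C,gamma SVM hyperparameters.
#' @return character vector of feature names in elimination order
#'   (first eliminated = least important; the last element survives
#'   longest).
#' @export
rfe_rank <- function(x, y, C, gamma) {
  y <- as_class_factor(y)
  feats <- colnames(x)
  if (is.null(feats)) stop("feature matrix must have column names")
  surviving <- feats
  order_out <- character(0)
  round <- 0L
  while (length(surviving) > 1L) {
    round <- round + 1L
    m <- tryCatch(fit_rbf_svm(x[, surviving, drop = FALSE], y, C, gamma),
                  error = function(e)
                    stop("SVM solver failed at RFE round ", round, ": ",
                         conditionMessage(e)))
    sv <- m$SV
    coefs <- m$coefs[, 1]
    D <- as.matrix(stats::dist(sv))^2
    K <- exp(-gamma * D)
    J <- svm_J(K, coefs)
    dJ <- vapply(seq_along(surviving), function(f) {
      df <- outer(sv[, f], sv[, f], "-")^2
      abs(J - svm_J(K * exp(gamma * df), coefs))
    }, numeric(1))
    drop_f <- which.min(dJ)  # ties resolve to the lowest index
    order_out <- c(order_out, surviving[drop_f])
    surviving <- surviving[-drop_f]
  }
  c(order_out, surviving)
}

#' Choose the feature count along the elimination path
#'
#' For each k along the path, the last k surviving features are
#' evaluated by mean out-of-fold AUROC over stratified folds; k is the
#' argmax, with ties broken toward the smallest k.
#'
#' @param x standardized training feature matrix.
#' @param y class labels.
#' @param elimination_order feature names from [rfe_rank()].
#' @param C,gamma SVM hyperparameters.
#' @param cv_folds number of folds.
#' @param fold optional precomputed fold assignment.
#' @return list with `k`, `features`, and the evaluation `path`.
#' @export
select_feature_count <- function(x, y, elimination_order, C, gamma,
                                 cv_folds = 4L, fold = NULL) {
  y <- as_class_factor(y)
  if (is.null(fold)) fold <- stratified_folds(y, cv_folds)
  p <- length(elimination_order)
  auc <- vapply(seq_len(p), function(k) {
    feats <- elimination_order[(p - k + 1L):p]
    cv_scores(x[, feats, drop = FALSE], y, C, gamma, fold)$mean_auc
  }, numeric(1))
  k <- which.max(auc)  # which.max takes the smallest index on ties
  list(k = k, features = elimination_order[(p - k + 1L):p],
       path = data.frame(k = seq_len(p), cv_auc = auc))
}

#' Calibrate the decision threshold at a target training specificity
#'
#' The threshold is the smallest out-of-fold score value achieving
#' specificity at or above `target_specificity` among training controls
#' (prediction is "case" when a score strictly exceeds the threshold).
#'
#' @param scores out-of-fold decision scores for every training sample.
#' @param y class labels.
#' @param target_specificity target (default 0.90).
#' @return list with `threshold`, `cv_specificity`, `cv_sensitivity`.
#' @export
calibrate_threshold <- function(scores, y, target_specificity = 0.90) {
  y <- as_class_factor(y)
  ctrl <- sort(scores[y == "control"])
  case <- scores[y == "case"]
  if (length(ctrl) == 0L || length(case) == 0L)
    stop("need scores for both classes")
  if (min(ctrl) > max(case)) {
    warning("target specificity unreachable: all controls score above all cases")
    thr <- max(scores) + 1e-8
  } else {
    m <- ceiling(target_specificity * length(ctrl))
    cand <- ctrl[m:length(ctrl)]
    ok <- vapply(cand, function(t) mean(ctrl <= t) >= target_specificity,
                 logical(1))
    thr <- cand[which(ok)[1]]
  }
  list(threshold = thr,
       cv_specificity = mean(scores[y == "control"] <= thr),
       cv_sensitivity = mean(case > thr))
}

#' Train the full diagnostic classifier
#'
#' Standardizes features on training statistics, grid-searches
#' `(C, gamma)`, ranks features by kernel RFE, chooses the feature count
#' by out-of-fold AUROC, fits the final SVM on the selected features,
#' and calibrates the decision threshold at the target training
#' specificity from out-of-fold scores. All data-dependent choices use
#' training data only.
#'
#' @param x training feature matrix (samples x features, column names
#'   required).
#' @param y class labels ("case"/"control").
#' @param config a [model_config()].
#' @return An object of class `ra_model`.
#' @export
train_ra_model <- function(x, y, config = model_config()) {
  y <- as_class_factor(y)
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  with_seed(config$seed, {
    center <- colMeans(x)
    scale_sd <- apply(x, 2L, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    z <- sweep(sweep(x, 2L, center), 2L, scale_sd, "/")
    fold <- stratified_folds(y, config$cv_folds)
    gs <- svm_grid_search(z, y, config$grid, fold = fold)
    elim <- rfe_rank(z, y, gs$C, gs$gamma)
    sel <- select_feature_count(z, y, elim, gs$C, gs$gamma, fold = fold)
    cv <- cv_scores(z[, sel$features, drop = FALSE], y, gs$C, gs$gamma, fold)
    cal <- calibrate_threshold(cv$scores, y, config$target_specificity)
    final <- fit_rbf_svm(z[, sel$features, drop = FALSE], y, gs$C, gs$gamma)
    structure(list(features = sel$features,
                   center = center[sel$features],
                   scale = scale_sd[sel$features],
                   C = gs$C, gamma = gs$gamma,
                   sv = unname(final$SV), coefs = unname(final$coefs[, 1]),
                   rho = final$rho, orientation = svm_orientation(final),
                   threshold = cal$threshold,
                   cv = list(auc_pooled = cv$pooled_auc,
                             auc_fold_mean = cv$mean_auc,
                             sensitivity = cal$cv_sensitivity,
                             specificity = cal$cv_specificity),
                   grid_cv_auc = gs$cv_auc,
                   elimination_order = elim,
                   k_path = sel$path,
                   target_specificity = config$target_specificity,
                   seed = config$seed),
              class = "ra_model")
  })
}

#' @export
print.ra_model <- function(x, ...) {
  cat(sprintf("ra_model: %d features, C=%g gamma=%g, threshold %.4f\n",
              length(x$features), x$C, x$gamma, x$threshold))
  cat(sprintf("  CV: pooled AUROC %.3f, fold-mean %.3f, sens %.3f at spec %.3f\n",
              x$cv$auc_pooled, x$cv$auc_fold_mean, x$cv$sensitivity,
              x$cv$specificity))
  invisible(x)
}

#' Decision scores of a trained model
#'
#' Computes the RBF decision function explicitly from the stored support
#' vectors and dual coefficients, after standardizing with the training
#' statistics. Larger scores are more case-like.
#'
#' @param model an `ra_model`.
#' @param x feature matrix containing at least the model's features.
#' @return numeric score vector.
#' @export
model_scores <- function(model, x) {
  miss <- setdiff(model$features, colnames(x))
  if (length(miss))
    stop("test data lacks model feature(s): ", paste(miss, collapse = ", "))
  z <- sweep(sweep(x[, model$features, drop = FALSE], 2L, model$center),
             2L, model$scale, "/")
  d2 <- outer(rowSums(z^2), rowSums(model$sv^2), "+") -
    2 * z %*% t(model$sv)
  k <- exp(-model$gamma * pmax(d2, 0))
  raw <- drop(k %*% model$coefs) - model$rho
  model$orientation * raw
}

#' Evaluate a trained model on a held-out test set
#'
#' @param model an `ra_model`.
#' @param x_test test feature matrix.
#' @param y_test test labels ("case"/"control").
#' @param acpa_status optional per-sample ACPA status
#'   ("positive"/"negative"/"unknown") used to stratify case
#'   sensitivity.
#' @return An object of class `eval_report`: list with `auroc`,
#'   `sensitivity`, `specificity`, subgroup sensitivities, counts and
#'   the scores.
#' @export
evaluate_model <- function(model, x_test, y_test, acpa_status = NULL) {
  y <- as_class_factor(y_test)
  s <- model_scores(model, x_test)
  pred_pos <- s > model$threshold
  is_case <- y == "case"
  rep <- list(auroc = roc_auc(s[is_case], s[!is_case])$auc,
              sensitivity = mean(pred_pos[is_case]),
              specificity = mean(!pred_pos[!is_case]),
              n_case = sum(is_case), n_control = sum(!is_case),
              threshold = model$threshold, scores = s, y = y)
  if (!is.null(acpa_status)) {
    pos <- is_case & acpa_status == "positive"
    neg <- is_case & acpa_status == "negative"
    rep$sensitivity_acpa_pos <- if (any(pos)) mean(pred_pos[pos]) else NA_real_
    rep$sensitivity_acpa_neg <- if (any(neg)) mean(pred_pos[neg]) else NA_real_
    rep$n_acpa_pos <- sum(pos); rep$n_acpa_neg <- sum(neg)
  }
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUROC %.3f, sens %.3f / spec %.3f at threshold %.4f (%d cases, %d controls)\n",
              x$auroc, x$sensitivity, x$specificity, x$threshold,
              x$n_case, x$n_control))
  if (!is.null(x$sensitivity_acpa_pos))
    cat(sprintf("  ACPA+ sens %.3f (n=%d), ACPA- sens %.3f (n=%d)\n",
                x$sensitivity_acpa_pos, x$n_acpa_pos,
                x$sensitivity_acpa_neg, x$n_acpa_neg))
  invisible(x)
}

#' Compare single markers with the model at matched specificity
#'
#' Each marker is dichotomized at the cutoff giving the smallest
#' training-control value whose specificity reaches
#' `target_specificity`; marker combinations are positive when any
#' member is positive. Samples missing a marker value are excluded and
#' counted.
#'
#' @param markers_train data.frame/matrix of marker values for training
#'   controls (one column per marker).
#' @param markers_test marker values for test samples.
#' @param y_test test labels.
#' @param model optional `ra_model` whose test sensitivity (on
#'   `x_test`) is reported alongside.
#' @param x_test test features for the model row.
#' @param target_specificity matched specificity target.
#' @param combine include an any-positive combination row over all
#'   markers (default TRUE).
#' @return data.frame with columns `marker`, `cutoff`, `sensitivity`,
#'   `specificity`, `n_missing`.
#' @export
compare_single_markers <- function(markers_train, markers_test, y_test,
                                   model = NULL, x_test = NULL,
                                   target_specificity = 0.90,
                                   combine = TRUE) {
  y <- as_class_factor(y_test)
  markers_train <- as.data.frame(markers_train)
  markers_test <- as.data.frame(markers_test)
  stopifnot(identical(names(markers_train), names(markers_test)))
  marker_cutoff <- function(v) {
    v <- sort(v[!is.na(v)])
    m <- ceiling(target_specificity * length(v))
    v[m]
  }
  cuts <- vapply(markers_train, marker_cutoff, numeric(1))
  pos <- sweep(as.matrix(markers_test), 2L, cuts, ">")
  one <- function(p, name, n_missing) {
    ok <- !is.na(p)
    data.frame(marker = name,
               cutoff = if (name %in% names(cuts)) cuts[[name]] else NA_real_,
               sensitivity = mean(p[ok & y == "case"]),
               specificity = mean(!p[ok & y == "control"]),
               n_missing = n_missing, stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, lapply(names(markers_test), function(nm)
    one(pos[, nm], nm, sum(is.na(markers_test[[nm]])))))
  if (combine && ncol(pos) > 1L) {
    any_pos <- rowSums(pos, na.rm = TRUE) > 0
    any_pos[apply(is.na(pos), 1L, all)] <- NA
    out <- rbind(out, one(any_pos, paste(names(markers_test), collapse = "+"),
                          sum(is.na(any_pos))))
  }
  if (!is.null(model) && !is.null(x_test)) {
    s <- model_scores(model, x_test)
    p <- s > model$threshold
    out <- rbind(one(p, "model", 0L), out)
  }
  rownames(out) <- NULL
  out
}

#' Serialize a trained model to a versioned JSON artifact
#' @param model an `ra_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(format = "seroscreen-model", version = 1L,
                  features = model$features,
                  center = model$center, scale = model$scale,
                  C = model$C, gamma = model$gamma,
                  sv = model$sv, coefs = model$coefs, rho = model$rho,
                  orientation = model$orientation,
                  threshold = model$threshold, cv = model$cv,
                  target_specificity = model$target_specificity,
                  seed = model$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#' @param path path written by [write_model()].
#' @return an `ra_model` (scoring-capable).
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "seroscreen-model"))
    stop("not a seroscreen model artifact: ", path)
  m <- p[c("features", "center", "scale", "C", "gamma", "sv", "coefs",
           "rho", "orientation", "threshold", "cv", "target_specificity",
           "seed")]
  m$center <- stats::setNames(as.numeric(m$center), m$features)
  m$scale <- stats::setNames(as.numeric(m$scale), m$features)
  m$sv <- as.matrix(m$sv)
  class(m) <- "ra_model"
  m
}
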