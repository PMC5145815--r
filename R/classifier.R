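## Reproducible, order-independent fold assignment: units (samples, or
## whole donors within a cell type when donor annotation is present) are
## ordered by a hash of their id and the run seed, then greedily assigned
## to the currently smallest fold, stratified by class.
make_folds <- function(ids, labels, k, seed, donors = NULL) {
  labels <- as.character(labels)
  unit <- if (is.null(donors)) ids else paste(labels, donors, sep = "|")
  fold_of_unit <- new.env(parent = emptyenv())
  load <- numeric(k)
  for (cl in sort(unique(labels))) {
    units <- unique(unit[labels == cl])
    units <- units[order(str_hash(paste0(seed, "#", units)), units)]
    used <- integer(0)
    for (u in units) {
      ## prefer folds this class has not used yet, then smallest load
      cand <- setdiff(seq_len(k), used)
      if (!length(cand)) cand <- seq_len(k)
      f <- cand[order(load[cand], cand)][1L]
      assign(u, f, envir = fold_of_unit)
      used <- c(used, f)
      load[f] <- load[f] + sum(unit == u)
    }
  }
  vapply(unit, function(u) get(u, envir = fold_of_unit), integer(1),
         USE.NAMES = FALSE)
}

#' Train a multinomial elastic-net cell-type classifier
#'
#' Multinomial logistic regression with the elastic-net penalty
#' lambda * \[(1 - alpha)/2 * ||W||_2^2 + alpha * ||W||_1\], fitted on the
#' region methylation matrix. Features are standardized internally and
#' coefficients are reported on the original scale. The penalty weight is
#' chosen by internal cross-validation as the largest lambda within one
#' standard error of the minimum multinomial deviance (the one-SE rule).
#'
#' @param mat a `meth_matrix` or a plain samples x regions matrix.
#' @param labels cell-type label per sample.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (default 0.5).
#' @param lambda optional lambda grid (default: glmnet's automatic path).
#' @param nfolds internal CV folds for lambda selection (default 10).
#' @param seed run seed; folds are derived from sample ids and this seed,
#'   so sample order does not matter.
#' @param donors optional donor annotation; samples of one donor within a
#'   class are kept in the same fold.
#' @return object of class `celltype_model`.
#' @export
train_celltype <- function(mat, labels, alpha = 0.5, lambda = NULL,
                           nfolds = 10L, seed = 1L, donors = NULL) {
  x <- if (inherits(mat, "meth_matrix")) mat$beta else as.matrix(mat)
  if (anyNA(x)) stop_ml("matrix contains missing values; impute first")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop_ml("need at least 2 classes")
  sizes <- table(labels)
  if (any(sizes < nfolds))
    stop_ml("class '%s' has %d samples, fewer than %d CV folds",
            names(sizes)[sizes < nfolds][1], min(sizes), nfolds)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  foldid <- make_folds(ids, labels, nfolds, seed, donors)
  ## glmnet warns about small per-fold class counts on every desk-scale
  ## fit; the fold construction already guarantees every class is present
  fit <- withCallingHandlers(
    glmnet::cv.glmnet(x, labels, family = "multinomial",
                      alpha = alpha, lambda = lambda, foldid = foldid,
                      type.measure = "deviance", standardize = TRUE),
    warning = function(w) {
      if (grepl("dangerous ground|fewer than", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, classes = levels(labels), alpha = alpha,
                 lambda = fit$lambda.1se, lambda_min = fit$lambda.min,
                 features = colnames(x), seed = seed, n = nrow(x)),
            class = "celltype_model")
}

#' @export
print.celltype_model <- function(x, ...) {
  W <- coef(x)
  cat(sprintf(
    "Elastic-net cell-type classifier: %d classes, %d regions (alpha = %.2f)\n",
    length(x$classes), length(x$features), x$alpha))
  cat(sprintf("  lambda (one-SE rule): %.4g; nonzero regions: %d\n",
              x$lambda, sum(rowSums(abs(W)) > 0)))
  invisible(x)
}

#' @export
coef.celltype_model <- function(object, ...) {
  cf <- glmnet::coef.glmnet(object$fit, s = object$lambda)
  W <- do.call(cbind, lapply(cf, function(m) as.numeric(m)[-1L]))
  dimnames(W) <- list(object$features, object$classes)
  attr(W, "intercepts") <- vapply(cf, function(m) as.numeric(m)[1L],
                                  numeric(1))
  W
}

#' Predict cell-type probabilities or classes
#'
#' @param object a `celltype_model`.
#' @param newdata `meth_matrix` or matrix over the training features.
#' @param type `"prob"` for the class-probability matrix (rows on the
#'   probability simplex) or `"class"` for argmax labels (ties broken
#'   towards the lexicographically first class).
#' @param ... unused.
#' @export
predict.celltype_model <- function(object, newdata, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "meth_matrix")) newdata$beta else
    as.matrix(newdata)
  pr <- stats::predict(object$fit, newx = x[, object$features, drop = FALSE],
                       s = object$lambda, type = "response")
  pr <- pr[, , 1L, drop = TRUE]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L,
                                     dimnames = list(rownames(x),
                                                     object$classes))
  if (type == "prob") return(pr)
  ord <- order(colnames(pr))
  apply(pr[, ord, drop = FALSE], 1L, function(p)
    colnames(pr)[ord][which.max(p)])
}

## one-vs-rest ROC AUC with midrank tie handling
auc_one_vs_rest <- function(is_pos, score) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated evaluation of the cell-type classifier
#'
#' Stratified k-fold cross-validation (folds derived from sample ids and
#' the seed; donors kept intact within folds when annotated). Each fold is
#' predicted by a model trained on the remaining folds with the same
#' alpha/lambda-selection rule. Reports the confusion matrix (argmax with
#' lexicographic tie-break), per-class one-vs-rest ROC AUC with midrank
#' tie handling, overall accuracy and macro accuracy (mean per-class
#' recall).
#'
#' @inheritParams train_celltype
#' @param folds outer CV folds (default 10); must not exceed the smallest
#'   class size.
#' @param nfolds_inner internal folds for lambda selection per fold model.
#' @return object of class `cv_report`: `probabilities`, `predicted`,
#'   `confusion`, `auc`, `accuracy`, `macro_accuracy`, `fold`.
#' @export
cross_validate <- function(mat, labels, folds = 10L, alpha = 0.5,
                           nfolds_inner = 10L, seed = 1L, donors = NULL) {
  x <- if (inherits(mat, "meth_matrix")) mat$beta else as.matrix(mat)
  labels <- factor(labels)
  sizes <- table(labels)
  if (folds > min(sizes))
    stop_ml("fold count %d exceeds smallest class size %d", folds,
            min(sizes))
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  fold <- make_folds(ids, labels, folds, seed, donors)
  prob <- matrix(NA_real_, nrow(x), nlevels(labels),
                 dimnames = list(ids, levels(labels)))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(labels[tr])) < nlevels(labels))
      stop_ml("fold %d removes a class entirely from training", f)
    model <- train_celltype(x[tr, , drop = FALSE], droplevels(labels[tr]),
                            alpha = alpha, nfolds = nfolds_inner,
                            seed = derive_seed(seed, paste0("fold", f)),
                            donors = if (is.null(donors)) NULL else donors[tr])
    prob[!tr, model$classes] <- predict(model, x[!tr, , drop = FALSE])
  }
  ord <- order(colnames(prob))
  predicted <- apply(prob[, ord, drop = FALSE], 1L, function(p)
    colnames(prob)[ord][which.max(p)])
  confusion <- table(true = labels,
                     predicted = factor(predicted, levels = levels(labels)))
  auc <- vapply(levels(labels), function(cl)
    auc_one_vs_rest(labels == cl, prob[, cl]), numeric(1))
  recall <- diag(confusion) / rowSums(confusion)
  structure(list(probabilities = prob, predicted = predicted,
                 confusion = confusion, auc = auc,
                 accuracy = mean(predicted == as.character(labels)),
                 macro_accuracy = mean(recall), fold = fold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: accuracy %.3f (macro %.3f); per-class AUC %.2f-%.2f\n",
              length(unique(x$fold)), x$accuracy, x$macro_accuracy,
              min(x$auc), max(x$auc)))
  print(x$confusion)
  invisible(x)
}

#' Extract signature regions from a fitted classifier
#'
#' The regularized classifier weighs every region by its discriminatory
#' power; the importance of region r is I(r) = sum over classes of
#' |W(c, r)| at the selected lambda. Signature regions are those with
#' I(r) > `min_importance` (i.e. a nonzero coefficient for at least one
#' class), sorted by decreasing importance, with the per-class coefficient
#' sign pattern.
#'
#' @param model a `celltype_model`.
#' @param min_importance importance cutoff (default 0).
#' @return data.frame with `region`, `importance` and one `sign_<class>`
#'   column per class.
#' @export
extract_signatures <- function(model, min_importance = 0) {
  if (!inherits(model, "celltype_model")) stop_ml("not a fitted model")
  W <- coef(model)
  imp <- rowSums(abs(W))
  keep <- which(imp > min_importance)
  signs <- sign(W[keep, , drop = FALSE])
  colnames(signs) <- paste0("sign_", colnames(signs))
  out <- data.frame(region = model$features[keep],
                    importance = unname(imp[keep]),
                    signs, check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
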