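#' Binary diagnostic labels from sample metadata
#'
#' Supported schemes:
#' * `benign_vs_malignant`: stage I/II samples are `benign`, stage III/IV
#'   `malignant`; controls and unstaged cancer samples are excluded (a
#'   message reports how many).
#' * `control_vs_cancer`: `control` versus `cancer` (early and late
#'   pooled).
#' * `early_vs_late`: the two cancer phases.
#'
#' @param metadata data.frame with `sample_id`, `phase`, optional
#'   `stage`.
#' @param scheme one of the three labelling schemes.
#' @return named factor (two levels, negative class first) over the
#'   retained samples.
#' @export
makeLabels <- function(metadata,
                       scheme = c("benign_vs_malignant",
                                  "control_vs_cancer", "early_vs_late")) {
  scheme <- match.arg(scheme)
  metadata <- as.data.frame(metadata)
  ph <- as.character(metadata$phase)
  st <- if ("stage" %in% colnames(metadata)) as.character(metadata$stage)
        else rep(NA_character_, nrow(metadata))
  lab <- switch(scheme,
    benign_vs_malignant = {
      cancer <- ph %in% c("early", "late")
      dropped <- sum(cancer & is.na(st))
      if (dropped)
        message(dropped, " unstaged cancer sample(s) excluded")
      out <- rep(NA_character_, nrow(metadata))
      out[cancer & st %in% c("I", "II")] <- "benign"
      out[cancer & st %in% c("III", "IV")] <- "malignant"
      factor(out, levels = c("benign", "malignant"))
    },
    control_vs_cancer = factor(ifelse(ph == "control", "control", "cancer"),
                               levels = c("control", "cancer")),
    early_vs_late = {
      out <- rep(NA_character_, nrow(metadata))
      out[ph == "early"] <- "early"
      out[ph == "late"] <- "late"
      factor(out, levels = c("early", "late"))
    })
  names(lab) <- metadata$sample_id
  lab <- lab[!is.na(lab)]
  if (any(table(lab) == 0L))
    stop("a class has zero samples under scheme ", scheme)
  lab
}

# stratified fold assignment: per class, shuffled samples are dealt
# round-robin so every fold holds both classes where sizes allow
.stratifiedFolds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (any(table(factor(fold, levels = seq_len(folds)), y) == 0L))
    stop("a class is absent from some fold; use fewer folds")
  fold
}

# mean stratified-CV accuracy of an SVM on the given feature columns
.cvAccuracy <- function(X, y, features, folds, seed, kernel = "radial",
                        cost = 1, gamma = NULL) {
  fold <- .stratifiedFolds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    args <- list(x = X[tr, features, drop = FALSE], y = y[tr],
                 kernel = kernel, cost = cost, scale = FALSE)
    if (!is.null(gamma)) args$gamma <- gamma
    fit <- do.call(e1071::svm, args)
    pred <- stats::predict(fit, X[!tr, features, drop = FALSE])
    mean(pred == y[!tr])
  }, 0)
  mean(acc)
}

# |weight| ranking of features from a linear-kernel SVM
.svmWeights <- function(X, y, features) {
  fit <- e1071::svm(X[, features, drop = FALSE], y, kernel = "linear",
                    cost = 1, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  abs(setNames(w, features))
}

#' Recursive feature elimination with SVM ranking
#'
#' Iteratively fits a linear-kernel SVM on the surviving features, ranks
#' them by absolute weight and eliminates the `step` lowest-ranked; at
#' each retained size the stratified `folds`-fold CV accuracy of an
#' RBF-kernel SVM on that feature set is recorded. The selected set is
#' the one at the accuracy-curve maximum (ties resolved toward fewer
#' features). `ranking` orders all features from first-eliminated
#' (least informative) to last-surviving.
#'
#' @param X samples-by-genes numeric matrix with column names.
#' @param y two-level factor aligned with the rows of `X`.
#' @param step features eliminated per iteration (default 1).
#' @param folds CV folds for the accuracy curve (default 5).
#' @param seed RNG seed (fold assignment).
#' @return list with `curve` (data.frame `n_features`, `cv_accuracy`),
#'   `ranking`, `selected`.
#' @export
rfeSelect <- function(X, y, step = 1L, folds = 5L, seed = 1L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)), step >= 1L)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("need exactly two classes")
  if (any(table(y) < 2L)) stop("need >= 2 samples per class")
  surviving <- colnames(X)
  eliminated <- character(0)
  curve <- list()
  repeat {
    acc <- .cvAccuracy(X, y, surviving, folds, seed, kernel = "radial")
    curve[[length(curve) + 1L]] <-
      data.frame(n_features = length(surviving), cv_accuracy = acc)
    if (length(surviving) == 1L) break
    w <- .svmWeights(X, y, surviving)
    drop_n <- min(step, length(surviving) - 1L)
    worst <- names(sort(w))[seq_len(drop_n)]
    eliminated <- c(eliminated, worst)
    surviving <- setdiff(surviving, worst)
  }
  curve <- do.call(rbind, curve)
  ranking <- c(eliminated, rev(surviving))  # only 1 survivor remains
  best <- max(curve$cv_accuracy)
  bestN <- min(curve$n_features[curve$cv_accuracy == best])
  selected <- tail(ranking, bestN)
  list(curve = curve, ranking = ranking, selected = selected)
}

#' Grid-searched SVM training
#'
#' Exhaustive search over the (cost, gamma) grid by stratified CV
#' accuracy, ties broken toward smaller cost then smaller gamma; the
#' winning cell is refit on all data. The default gamma grid is centred
#' on `1 / (n_features * mean feature variance)`.
#'
#' @param X samples-by-genes matrix.
#' @param y two-level factor.
#' @param features feature genes to use (default all columns).
#' @param grid list with numeric `cost` and `gamma` vectors; `NULL`
#'   gamma entries use the default centre.
#' @param folds,seed CV settings.
#' @return a [DiagnosticModel-class].
#' @export
trainSvm <- function(X, y, features = colnames(X), grid = NULL,
                     folds = 5L, seed = 1L) {
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("need exactly two classes")
  if (any(!is.finite(X[, features]))) stop("non-finite feature values")
  g0 <- 1 / (length(features) *
               mean(apply(X[, features, drop = FALSE], 2L, var)))
  if (is.null(grid))
    grid <- list(cost = c(0.1, 1, 10, 100), gamma = g0 * c(0.1, 1, 10))
  if (!length(grid$cost) || !length(grid$gamma)) stop("empty grid")
  cells <- expand.grid(cost = sort(grid$cost), gamma = sort(grid$gamma))
  cells <- cells[order(cells$cost, cells$gamma), ]
  acc <- mapply(function(cost, gamma)
    .cvAccuracy(X, y, features, folds, seed, "radial", cost, gamma),
    cells$cost, cells$gamma)
  best <- which.max(acc)  # first index at ties = smaller cost, gamma
  fit <- e1071::svm(X[, features, drop = FALSE], y, kernel = "radial",
                    cost = cells$cost[best], gamma = cells$gamma[best],
                    scale = FALSE)
  new("DiagnosticModel", features = features, kernel = "radial",
      cost = cells$cost[best], gamma = cells$gamma[best],
      levels = levels(y), fit = fit)
}

#' Cross-validated ROC evaluation of an SVM specification
#'
#' Stratified `folds`-fold cross-validation: in each fold an RBF SVM
#' with the given hyperparameters is trained on the remaining folds and
#' its decision scores on the held-out fold yield a ROC curve
#' (thresholding the scores) and a trapezoidal AUROC. Reported accuracy
#' is the mean of per-fold accuracies, AUROC the mean of per-fold AUCs.
#'
#' @param X samples-by-genes matrix.
#' @param y two-level factor (second level is the positive class).
#' @param features feature genes.
#' @param cost,gamma SVM hyperparameters (`NULL` gamma = e1071 default).
#' @param folds,seed CV settings.
#' @return list with `accuracy`, `auroc`, `fold_accuracy`, `fold_auroc`,
#'   `roc` (data.frame `fold`, `fpr`, `tpr`), `folds`, `seed`.
#' @export
evaluateCv <- function(X, y, features = colnames(X), cost = 1,
                       gamma = NULL, folds = 5L, seed = 1L) {
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("need exactly two classes")
  fold <- .stratifiedFolds(y, folds, seed)
  pos <- levels(y)[2L]
  per <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    args <- list(x = X[tr, features, drop = FALSE], y = y[tr],
                 kernel = "radial", cost = cost, scale = FALSE)
    if (!is.null(gamma)) args$gamma <- gamma
    fit <- do.call(e1071::svm, args)
    pred <- stats::predict(fit, X[!tr, features, drop = FALSE],
                           decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # decision values are signed toward the first class of the colname
    score <- if (strsplit(colnames(dv)[1L], "/")[[1L]][1L] == pos)
      dv[, 1L] else -dv[, 1L]
    truth <- y[!tr] == pos
    roc <- .rocCurve(score, truth)
    list(accuracy = mean(pred == y[!tr]), auroc = roc$auc,
         roc = data.frame(fold = f, fpr = roc$fpr, tpr = roc$tpr))
  })
  accs <- vapply(per, `[[`, 0, "accuracy")
  aucs <- vapply(per, `[[`, 0, "auroc")
  list(accuracy = mean(accs), auroc = mean(aucs),
       fold_accuracy = accs, fold_auroc = aucs,
       roc = do.call(rbind, lapply(per, `[[`, "roc")),
       folds = folds, seed = seed)
}

# ROC points and trapezoidal AUC from decision scores; ties handled by
# stepping through distinct thresholds in decreasing order
.rocCurve <- function(score, truth) {
  o <- order(score, decreasing = TRUE)
  truth <- truth[o]; score <- score[o]
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L) stop("need both classes in the fold")
  keep <- c(score[-1L] != score[-length(score)], TRUE)
  tpr <- c(0, cumsum(truth)[keep] / npos)
  fpr <- c(0, cumsum(!truth)[keep] / nneg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}
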