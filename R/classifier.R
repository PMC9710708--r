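# One-vs-rest SVM training with kernel grid search, stratified k-fold
# cross-validation and MCC-based model selection.
#
# The namespace-level import below also guarantees e1071 is loaded whenever
# this package is, so predict() dispatches on deserialized svm objects.
#' @importFrom e1071 svm
NULL
#
# Kernels (libsvm via e1071, with s = 1, c = 1 fixed for the polynomial):
#   K_poly(x, y) = (x . y + 1)^d
#   K_rbf(x, y)  = exp(-g * ||x - y||^2)

#' Configure the kernel parameter grid
#'
#' Defaults sweep the polynomial degree d over 1..9 with cost C over
#' 10^-7..10^13, and the RBF gamma g over 10^-15..10^3 with C over
#' 10^-5..10^15 — 189 polynomial + 399 RBF = 588 combinations per class.
#'
#' @param poly_d integer vector of polynomial degrees (empty to skip
#'   polynomial kernels).
#' @param poly_C_exponents integer exponents: C = 10^e for the polynomial.
#' @param rbf_g_exponents integer exponents: g = 10^e for the RBF (empty to
#'   skip RBF kernels).
#' @param rbf_C_exponents integer exponents: C = 10^e for the RBF.
#' @param folds number of cross-validation folds (>= 2, default 5).
#' @param seed integer seed for fold assignment.
#' @return object of class `grid_config`.
#' @export
grid_config <- function(poly_d = 1:9,
                        poly_C_exponents = -7:13,
                        rbf_g_exponents = -15:3,
                        rbf_C_exponents = -5:15,
                        folds = 5L,
                        seed = 1L) {
  stopifnot(folds >= 2L)
  if (!length(poly_d) && !length(rbf_g_exponents)) {
    stop("the grid must contain at least one kernel family")
  }
  cfg <- list(poly_d = as.integer(poly_d),
              poly_C_exponents = as.integer(poly_C_exponents),
              rbf_g_exponents = as.integer(rbf_g_exponents),
              rbf_C_exponents = as.integer(rbf_C_exponents),
              folds = as.integer(folds), seed = as.integer(seed))
  class(cfg) <- "grid_config"
  cfg
}

#' A reduced grid for quick runs and tests
#' @inheritParams grid_config
#' @return a [grid_config] with d in \{1,2\}, polynomial C exponents
#'   \{-1,0,1\}, RBF g exponents \{-3,-1\} and RBF C exponents \{0,1\}.
#' @export
reduced_grid <- function(folds = 5L, seed = 1L) {
  grid_config(poly_d = 1:2, poly_C_exponents = -1:1,
              rbf_g_exponents = c(-3L, -1L), rbf_C_exponents = 0:1,
              folds = folds, seed = seed)
}

#' Enumerate all kernel parameter combinations
#'
#' Polynomial pairs (d, C) in ascending lexicographic order, then RBF pairs
#' (g, C) likewise.
#' @param config a [grid_config].
#' @return data.frame with columns `kernel`, `d`, `C`, `g`.
#' @export
enumerate_grid <- function(config) {
  stopifnot(inherits(config, "grid_config"))
  rows <- list()
  if (length(config$poly_d) && length(config$poly_C_exponents)) {
    g <- expand.grid(C = 10^sort(config$poly_C_exponents),
                     d = sort(config$poly_d))
    rows$poly <- data.frame(kernel = "polynomial", d = g$d, C = g$C,
                            g = NA_real_)
  }
  if (length(config$rbf_g_exponents) && length(config$rbf_C_exponents)) {
    g <- expand.grid(C = 10^sort(config$rbf_C_exponents),
                     g = 10^sort(config$rbf_g_exponents))
    rows$rbf <- data.frame(kernel = "rbf", d = NA_integer_, C = g$C, g = g$g)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0 when
#' any marginal is zero.
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return real in \[-1, 1\].
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `folds` folds whose sizes differ by at most one,
#' with the positive:negative ratio of each fold within one item of the
#' global ratio. Deterministic for a fixed seed.
#' @param is_positive logical vector (the class indicator).
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..folds.
#' @export
stratified_kfold <- function(is_positive, folds, seed) {
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos < folds || n_neg < folds) {
    stop("each stratum needs at least ", folds, " samples (have ",
         n_pos, " positives, ", n_neg, " negatives)")
  }
  fold <- integer(length(is_positive))
  with_local_seed(seed, {
    fold[sample(which(is_positive))] <- rep_len(seq_len(folds), n_pos)
    fold[sample(which(!is_positive))] <- rep_len(seq_len(folds), n_neg)
  })
  fold
}

svm_args <- function(params) {
  if (params$kernel == "polynomial") {
    list(kernel = "polynomial", degree = params$d, gamma = 1, coef0 = 1,
         cost = params$C)
  } else {
    list(kernel = "radial", gamma = params$g, cost = params$C)
  }
}

# training representation: compositional vectors are >90% zeros, so libsvm
# runs much faster on a sparse matrix; rows without any nonzero entry cannot
# be represented in the csr format e1071 uses, so fall back to dense then
as_sparse <- function(x) {
  if (requireNamespace("SparseM", quietly = TRUE) && is.matrix(x) &&
      nrow(x) > 0L && all(rowSums(x != 0) > 0L)) {
    Matrix::Matrix(x, sparse = TRUE)
  } else {
    x
  }
}

#' Train one binary soft-margin SVM
#'
#' @param x numeric feature matrix (rows = samples).
#' @param is_positive logical class indicator for rows of `x`.
#' @param params one row of [enumerate_grid] (list or data.frame row) with
#'   fields `kernel`, `d`, `C`, `g`.
#' @return object of class `binary_svm` wrapping the fitted model; use
#'   [decision_values] to score new samples (positive value = positive class).
#' @export
train_binary <- function(x, is_positive, params) {
  if (!any(is_positive) || all(is_positive)) {
    stop("training requires both positive and negative samples")
  }
  y <- factor(ifelse(is_positive, "pos", "neg"), levels = c("pos", "neg"))
  args <- svm_args(as.list(params))
  fit <- tryCatch(
    do.call(e1071::svm, c(list(x = as_sparse(x), y = y, scale = FALSE,
                               tolerance = 1e-3), args)),
    error = function(e) {
      stop("SVM training failed for kernel=", params$kernel,
           " d=", params$d, " C=", params$C, " g=", params$g, ": ",
           conditionMessage(e))
    })
  structure(list(fit = fit, params = as.list(params)), class = "binary_svm")
}

#' Signed decision values of a binary SVM
#' @param model a `binary_svm` from [train_binary].
#' @param x numeric feature matrix.
#' @return numeric vector; > 0 predicts the positive class.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "binary_svm"))
  if (!is.matrix(x)) x <- as.matrix(x)
  pr <- predict(model$fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients the decision value toward the first label it saw; flip if
  # that was the negative class
  if (colnames(dv)[1] == "neg/pos") -as.numeric(dv) else as.numeric(dv)
}

#' Cross-validate one kernel parameter combination
#'
#' @inheritParams train_binary
#' @param folds,seed stratified fold assignment (see [stratified_kfold]).
#' @return list of class `cv_result`: `params`, `mean_mcc`, `mean_accuracy`,
#'   `confusions` (per-fold data.frame TP, FP, TN, FN).
#' @export
cross_validate <- function(x, is_positive, params, folds = 5L, seed = 1L) {
  fold <- stratified_kfold(is_positive, folds, seed)
  conf <- data.frame(TP = integer(folds), FP = integer(folds),
                     TN = integer(folds), FN = integer(folds))
  mccs <- accs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- train_binary(x[tr, , drop = FALSE], is_positive[tr], params)
    dv <- decision_values(m, x[!tr, , drop = FALSE])
    truth <- is_positive[!tr]
    pred <- dv > 0
    conf$TP[f] <- sum(pred & truth)
    conf$FP[f] <- sum(pred & !truth)
    conf$TN[f] <- sum(!pred & !truth)
    conf$FN[f] <- sum(!pred & truth)
    mccs[f] <- mcc(conf$TP[f], conf$FP[f], conf$TN[f], conf$FN[f])
    accs[f] <- (conf$TP[f] + conf$TN[f]) / sum(!tr)
  }
  structure(list(params = as.list(params), mean_mcc = mean(mccs),
                 mean_accuracy = mean(accs), confusions = conf),
            class = "cv_result")
}

#' Grid search over kernel parameters for one class
#'
#' Evaluates [cross_validate] at every grid point. The best point maximizes
#' mean MCC; ties go to higher mean accuracy, then polynomial before RBF,
#' then smaller d, then smaller C, then smaller g. The winning parameters are
#' refit on the full data.
#'
#' @inheritParams cross_validate
#' @param config a [grid_config].
#' @return list: `model` (a `binary_svm` refit on all data), `best`
#'   (the winning `cv_result`), `results` (data.frame: kernel, d, C, g,
#'   mean_mcc, mean_accuracy, rank).
#' @export
grid_search <- function(x, is_positive, config) {
  grid <- enumerate_grid(config)
  cvs <- vector("list", nrow(grid))
  failures <- character()
  for (i in seq_len(nrow(grid))) {
    cvs[[i]] <- tryCatch(
      cross_validate(x, is_positive, grid[i, ], config$folds, config$seed),
      error = function(e) conditionMessage(e))
    if (is.character(cvs[[i]])) failures <- c(failures, cvs[[i]])
  }
  ok <- vapply(cvs, inherits, logical(1), "cv_result")
  if (!any(ok)) {
    stop("every grid point failed; first error: ", failures[1])
  }
  res <- grid
  res$mean_mcc <- vapply(cvs, function(r) if (inherits(r, "cv_result")) r$mean_mcc else NA_real_, numeric(1))
  res$mean_accuracy <- vapply(cvs, function(r) if (inherits(r, "cv_result")) r$mean_accuracy else NA_real_, numeric(1))
  ord <- order(-res$mean_mcc, -res$mean_accuracy,
               res$kernel != "polynomial",           # polynomial first
               ifelse(is.na(res$d), Inf, res$d),
               res$C,
               ifelse(is.na(res$g), Inf, res$g),
               na.last = TRUE)
  res$rank <- NA_integer_
  res$rank[ord] <- seq_len(nrow(res))
  best_i <- ord[1]
  model <- train_binary(x, is_positive, grid[best_i, ])
  list(model = model, best = cvs[[best_i]], results = res)
}
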