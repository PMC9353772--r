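#' Random-forest classification under repeated stratified cross-validation
#'
#' Fits a random forest (default 100 trees) in every fold of a stratified
#' k-fold scheme, re-drawing the folds \code{nIterations} times, and pools
#' the out-of-fold predictions of each iteration into one accuracy. Feature
#' importances are the gini (mean decrease in impurity) importances averaged
#' over all fold models. All randomness derives from one master seed
#' (per-iteration and per-fold sub-seeds), so results are bit-reproducible.
#'
#' @param profile numeric matrix, samples x features.
#' @param labels class labels (every class needs at least \code{nFolds}
#'   members).
#' @param nFolds folds per iteration (default 3).
#' @param nIterations fold redraws (default 20).
#' @param nTrees trees per forest (default 100).
#' @param seed master seed.
#' @return a list of class \code{cv_result}: \code{accuracy_mean},
#'   \code{accuracy_sd}, \code{accuracies} (per iteration), \code{folds}
#'   (per-iteration assignments), \code{importance} (normalized mean gini).
#' @export
rfClassifyCV <- function(profile, labels, nFolds = 3, nIterations = 20,
                         nTrees = 100, seed = 1) {
    y <- factor(labels)
    accs <- numeric(nIterations)
    foldList <- vector("list", nIterations)
    impSum <- numeric(ncol(profile))
    nModels <- 0L
    for (it in seq_len(nIterations)) {
        folds <- stratifiedFolds(y, nFolds, .subSeed(seed, it, 0))
        foldList[[it]] <- folds
        pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
        for (f in seq_len(nFolds)) {
            tr <- folds != f
            fit <- withSeed(.subSeed(seed, it, f),
                randomForest::randomForest(x = profile[tr, , drop = FALSE],
                                           y = y[tr], ntree = nTrees))
            pred[!tr] <- stats::predict(fit, profile[!tr, , drop = FALSE])
            impSum <- impSum + fit$importance[, "MeanDecreaseGini"]
            nModels <- nModels + 1L
        }
        accs[it] <- mean(pred == y)
    }
    imp <- impSum / nModels
    if (sum(imp) > 0) imp <- imp / sum(imp)
    structure(list(accuracy_mean = mean(accs),
                   accuracy_sd = stats::sd(accs),
                   accuracies = accs, folds = foldList,
                   importance = stats::setNames(imp, colnames(profile))),
              class = "cv_result")
}

#' Two-block NIPALS partial least squares (PLS2)
#'
#' Classic NIPALS extraction of \code{ncomp} latent components relating a
#' predictor block X to a (possibly multi-column) response block Y. Both
#' blocks are mean-centered internally; any further scaling is the caller's
#' responsibility. The regression coefficient matrix
#' \code{B = W (P'W)^-1 C'} reproduces the standard PLS2 predictor.
#'
#' @param X numeric matrix, observations x predictors.
#' @param Y numeric matrix (or vector), observations x responses.
#' @param ncomp number of latent components; must not exceed the rank
#'   actually extractable from X.
#' @param tol convergence tolerance of the score iteration.
#' @return list of class \code{pls_nipals} with the centered-model pieces
#'   (\code{coefficients}, \code{xMeans}, \code{yMeans}, scores/loadings).
#' @export
plsNipals <- function(X, Y, ncomp, tol = 1e-10) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    xm <- colMeans(X); ym <- colMeans(Y)
    E <- sweep(X, 2, xm); F <- sweep(Y, 2, ym)
    n <- nrow(X); p <- ncol(X)
    if (ncomp > min(n - 1, p))
        stop("ncomp exceeds the maximal extractable rank")
    W <- P <- matrix(0, p, ncomp)
    C <- matrix(0, ncol(Y), ncomp)
    Tm <- matrix(0, n, ncomp)
    for (a in seq_len(ncomp)) {
        u <- F[, which.max(apply(F, 2, stats::var))]
        if (all(abs(u) < tol)) u <- E[, which.max(apply(E, 2, stats::var))]
        tOld <- rep(Inf, n)
        for (iter in seq_len(500)) {
            w <- crossprod(E, u)[, 1]
            nw <- sqrt(sum(w^2))
            if (nw < tol)
                stop("ncomp exceeds the rank of the predictor block")
            w <- w / nw
            tt <- E %*% w
            cc <- crossprod(F, tt)[, 1] / sum(tt^2)
            if (sum(cc^2) < tol^2) break
            u <- F %*% cc / sum(cc^2)
            if (sum((tt - tOld)^2) < tol * sum(tt^2)) break
            tOld <- tt
        }
        tt2 <- sum(tt^2)
        if (tt2 < tol)
            stop("ncomp exceeds the rank of the predictor block")
        pp <- crossprod(E, tt)[, 1] / tt2
        W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
        E <- E - tt %*% t(pp)
        F <- F - tt %*% t(cc)
    }
    B <- W %*% solve(crossprod(P, W), t(C))
    structure(list(coefficients = B, xMeans = xm, yMeans = ym,
                   scores = Tm, xLoadings = P, yLoadings = C, weights = W),
              class = "pls_nipals")
}

#' @rdname plsNipals
#' @param object a fitted \code{pls_nipals} model.
#' @param newdata matrix of new observations.
#' @param ... unused.
#' @export
predict.pls_nipals <- function(object, newdata, ...) {
    sweep(as.matrix(newdata), 2, object$xMeans) %*% object$coefficients +
        matrix(object$yMeans, nrow(as.matrix(newdata)),
               length(object$yMeans), byrow = TRUE)
}

.onehot <- function(y) {
    y <- factor(y)
    out <- matrix(0, length(y), nlevels(y),
                  dimnames = list(NULL, levels(y)))
    out[cbind(seq_along(y), as.integer(y))] <- 1
    out
}

.autoscaleFit <- function(X) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1   # constant columns pass through centered
    list(mu = mu, sd = sdv)
}
.autoscaleApply <- function(X, fit) sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")

## predicted class labels from a PLS response matrix, applying the
## discriminant decision rules: argmax of the one-hot response for
## multiclass (ties -> lowest class index), 0.5 threshold for two classes
.plsDecision <- function(Yhat, levels) {
    if (length(levels) == 2 && ncol(Yhat) == 1) {
        factor(ifelse(Yhat[, 1] >= 0.5, levels[2], levels[1]), levels = levels)
    } else {
        idx <- apply(Yhat, 1, which.max)   # which.max takes the first tie
        factor(levels[idx], levels = levels)
    }
}

## Q2-maximizing component count via internal stratified CV on the training
## data: Q2(a) = 1 - PRESS(a)/TSS, PRESS pooled over internal folds
.selectNcompQ2 <- function(X, y, maxComp, nFolds = 3, seed = 1) {
    y <- factor(y, levels = sort(unique(as.character(y))))
    Y <- if (nlevels(y) == 2) cbind(as.numeric(y) - 1) else .onehot(y)
    folds <- stratifiedFolds(y, nFolds, seed)
    maxComp <- min(maxComp, nrow(X) - max(table(folds)) - 1, ncol(X))
    press <- numeric(maxComp)
    for (f in seq_len(nFolds)) {
        tr <- folds != f
        sc <- .autoscaleFit(X[tr, , drop = FALSE])
        Xtr <- .autoscaleApply(X[tr, , drop = FALSE], sc)
        Xte <- .autoscaleApply(X[!tr, , drop = FALSE], sc)
        for (a in seq_len(maxComp)) {
            fit <- tryCatch(plsNipals(Xtr, Y[tr, , drop = FALSE], a),
                            error = function(e) NULL)
            if (is.null(fit)) { press[a] <- Inf; next }
            press[a] <- press[a] +
                sum((predict.pls_nipals(fit, Xte) - Y[!tr, , drop = FALSE])^2)
        }
    }
    tss <- sum(sweep(Y, 2, colMeans(Y))^2)
    q2 <- 1 - press / tss
    which.max(q2)
}

#' PLS-DA classification under repeated stratified cross-validation
#'
#' Partial least squares discriminant analysis with the PLS2-NIPALS engine
#' ([plsNipals()]): the class response is one-hot encoded (multiclass;
#' predicted class = argmax of the predicted response, ties to the lowest
#' class index) or 0/1 with a 0.5 decision threshold (two classes).
#' Predictors are autoscaled inside each training fold and the fold's
#' scaling applied to its test part. The component count may be fixed or
#' selected by maximizing Q2 (cross-validated predictive explained
#' variance) on the training data of each fold.
#'
#' @inheritParams rfClassifyCV
#' @param nComponents integer, or "auto" for Q2-based selection.
#' @param maxComponents search ceiling for "auto".
#' @param autoScale autoscale predictors within the fold (disable when the
#'   input matrix is already scaled).
#' @return a \code{cv_result} list as in [rfClassifyCV()]; \code{importance}
#'   holds the mean absolute PLS regression coefficient per feature
#'   (averaged over responses and folds, normalized to sum 1).
#' @export
plsdaClassifyCV <- function(profile, labels, nComponents = "auto",
                            nFolds = 3, nIterations = 20,
                            maxComponents = 8, autoScale = TRUE, seed = 1) {
    y <- factor(labels)
    lev <- levels(y)
    Yfull <- if (nlevels(y) == 2) cbind(as.numeric(y) - 1) else .onehot(y)
    accs <- numeric(nIterations)
    foldList <- vector("list", nIterations)
    coefSum <- numeric(ncol(profile))
    nModels <- 0L
    for (it in seq_len(nIterations)) {
        folds <- stratifiedFolds(y, nFolds, .subSeed(seed, it, 0))
        foldList[[it]] <- folds
        pred <- factor(rep(NA_character_, length(y)), levels = lev)
        for (f in seq_len(nFolds)) {
            tr <- folds != f
            Xtr <- profile[tr, , drop = FALSE]
            Xte <- profile[!tr, , drop = FALSE]
            if (autoScale) {
                sc <- .autoscaleFit(Xtr)
                Xtr <- .autoscaleApply(Xtr, sc)
                Xte <- .autoscaleApply(Xte, sc)
            }
            a <- if (identical(nComponents, "auto"))
                .selectNcompQ2(profile[tr, , drop = FALSE], y[tr],
                               maxComponents, seed = .subSeed(seed, it, f))
            else nComponents
            fit <- plsNipals(Xtr, Yfull[tr, , drop = FALSE], a)
            pred[!tr] <- .plsDecision(predict.pls_nipals(fit, Xte), lev)
            coefSum <- coefSum + rowMeans(abs(fit$coefficients))
            nModels <- nModels + 1L
        }
        accs[it] <- mean(pred == y)
    }
    imp <- coefSum / nModels
    if (sum(imp) > 0) imp <- imp / sum(imp)
    structure(list(accuracy_mean = mean(accs),
                   accuracy_sd = stats::sd(accs),
                   accuracies = accs, folds = foldList,
                   importance = stats::setNames(imp, colnames(profile))),
              class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
    cat(sprintf("cross-validated accuracy: %.3f +/- %.3f (%d iterations)\n",
                x$accuracy_mean, x$accuracy_sd, length(x$accuracies)))
    invisible(x)
}

#' Label-permutation significance test for a classifier
#'
#' Re-runs a cross-validated classifier on label permutations and reports
#' \code{p = (1 + #\{permuted accuracy >= observed\}) / (1 + nPerm)} — the
#' add-one estimator, which never returns 0 (the floor with 500 permutations
#' is 1/501).
#'
#' @param profile numeric matrix, samples x features.
#' @param labels class labels.
#' @param cvAccuracy function \code{(profile, labels, seed) -> accuracy};
#'   e.g. a wrapper around [rfClassifyCV()] or [plsdaClassifyCV()].
#' @param nPerm number of permutations (default 500).
#' @param seed master seed (observed run + permutation draws).
#' @return list with \code{p_value}, \code{observed}, \code{permuted}.
#' @export
permutationTest <- function(profile, labels, cvAccuracy, nPerm = 500,
                            seed = 1) {
    stopifnot(nPerm >= 1)
    observed <- cvAccuracy(profile, labels, .subSeed(seed, 0))
    permuted <- vapply(seq_len(nPerm), function(i) {
        shuffled <- withSeed(.subSeed(seed, i, 1), sample(labels))
        cvAccuracy(profile, shuffled, .subSeed(seed, i, 2))
    }, numeric(1))
    list(p_value = (1 + sum(permuted >= observed)) / (1 + nPerm),
         observed = observed, permuted = permuted)
}

#' Cross-validated ROC curve and AUC for a two-class problem
#'
#' Pools the out-of-fold class scores of a stratified k-fold run and
#' computes the ROC curve and its trapezoidal area. Scores are the
#' out-of-fold vote fraction (random forest) or the predicted response
#' (PLS-DA) for the second class level.
#'
#' @param profile numeric matrix, samples x features.
#' @param labels labels with exactly two classes.
#' @param classifier "rf" or "plsda".
#' @param nFolds folds (default 5).
#' @param nTrees forest size for "rf".
#' @param nComponents components for "plsda".
#' @param seed master seed.
#' @return list with \code{auc}, \code{roc} (a \code{pROC::roc} object),
#'   \code{scores} (pooled, in sample order).
#' @export
rocAucCV <- function(profile, labels, classifier = c("rf", "plsda"),
                     nFolds = 5, nTrees = 100, nComponents = 2, seed = 1) {
    classifier <- match.arg(classifier)
    y <- factor(labels)
    if (nlevels(y) != 2) stop("ROC analysis needs exactly two classes")
    folds <- stratifiedFolds(y, nFolds, .subSeed(seed, 1))
    scores <- numeric(length(y))
    for (f in seq_len(nFolds)) {
        tr <- folds != f
        if (classifier == "rf") {
            fit <- withSeed(.subSeed(seed, 2, f),
                randomForest::randomForest(x = profile[tr, , drop = FALSE],
                                           y = y[tr], ntree = nTrees))
            scores[!tr] <- stats::predict(fit, profile[!tr, , drop = FALSE],
                                          type = "prob")[, levels(y)[2]]
        } else {
            sc <- .autoscaleFit(profile[tr, , drop = FALSE])
            fit <- plsNipals(.autoscaleApply(profile[tr, , drop = FALSE], sc),
                             cbind(as.numeric(y[tr]) - 1), nComponents)
            scores[!tr] <- predict.pls_nipals(
                fit, .autoscaleApply(profile[!tr, , drop = FALSE], sc))[, 1]
        }
    }
    roc <- pROC::roc(response = y, predictor = scores,
                     levels = levels(y), direction = "<", quiet = TRUE)
    list(auc = as.numeric(pROC::auc(roc)), roc = roc, scores = scores)
}
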