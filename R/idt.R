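#' Intensity-based pretreatment (IDT)
#'
#' The conventional intensity-matrix pipeline used as the benchmark against
#' the network profiles: missing-value imputation (1/5 of the per-sample
#' minimum, or iterative random-forest imputation), normalization (reference
#' feature or probabilistic quotient), generalized log transform and Pareto
#' scaling. All steps operate on [MassFeatureSet-class] objects and return
#' new ones.
#'
#' @name idt
NULL

.replaceIntensity <- function(x, m) {
    assays(x)[["intensity"]] <- m
    x
}

#' @describeIn idt replace every missing cell by one-fifth of the minimum
#'   non-missing intensity of its sample (a detection-limit surrogate).
#' @param x a [MassFeatureSet-class].
#' @export
imputeFifthMin <- function(x) {
    m <- intensityMatrix(x)
    if (any(colSums(!is.na(m)) == 0)) stop("sample with no observed values")
    for (j in seq_len(ncol(m))) {
        miss <- is.na(m[, j])
        if (any(miss)) m[miss, j] <- min(m[, j], na.rm = TRUE) / 5
    }
    .replaceIntensity(x, m)
}

#' @describeIn idt iterative random-forest imputation in the missForest
#'   style: initialize with [imputeFifthMin()], then cycle over features with
#'   missing values (least missing first), regressing each on its
#'   \code{nPredictors} most correlated (absolute Pearson, on the current
#'   completed matrix) features with an \code{nTrees}-tree forest and
#'   refreshing the imputed cells, until the sum of squared changes stops
#'   decreasing or \code{maxIter} rounds. Deterministic under \code{seed}.
#' @param nTrees trees per forest (default 50).
#' @param nPredictors number of most-correlated predictor features
#'   (default 100; all if fewer are available).
#' @param maxIter iteration cap (default 10).
#' @param seed RNG seed.
#' @export
imputeRandomForest <- function(x, nTrees = 50, nPredictors = 100,
                               maxIter = 10, seed = 1) {
    m0 <- intensityMatrix(x)
    if (any(colSums(!is.na(m0)) == 0)) stop("sample with no observed values")
    missIdx <- which(is.na(m0))
    if (!length(missIdx)) return(x)
    cur <- intensityMatrix(imputeFifthMin(x))
    feats <- which(rowSums(is.na(m0)) > 0)
    feats <- feats[order(rowSums(is.na(m0))[feats])]
    lastSS <- Inf
    best <- cur
    withSeed(seed, {
        for (it in seq_len(maxIter)) {
            prev <- cur
            co <- abs(suppressWarnings(stats::cor(t(cur))))
            diag(co) <- 0
            co[is.na(co)] <- 0
            for (f in feats) {
                obs <- !is.na(m0[f, ])
                preds <- order(co[f, ], decreasing = TRUE)
                preds <- setdiff(preds, f)[seq_len(min(nPredictors, nrow(cur) - 1))]
                ## regression forests warn on few unique responses, which
                ## is routine for features observed in a handful of samples
                fit <- suppressWarnings(randomForest::randomForest(
                    x = t(cur[preds, obs, drop = FALSE]),
                    y = m0[f, obs], ntree = nTrees))
                cur[f, !obs] <- stats::predict(
                    fit, t(cur[preds, !obs, drop = FALSE]))
            }
            ss <- sum((cur[missIdx] - prev[missIdx])^2)
            if (ss >= lastSS) { cur <- best; break }
            lastSS <- ss
            best <- cur
        }
    })
    .replaceIntensity(x, cur)
}

#' @describeIn idt divide each sample by its intensity of a designated
#'   reference feature (e.g. a spiked lock-mass compound), then remove the
#'   reference feature. The feature is located by mass within
#'   \code{tolPpm}; no match or an ambiguous match is an error.
#' @param refMass neutral/ion mass of the reference feature (Da).
#' @param tolPpm match tolerance in ppm (default 1).
#' @export
normalizeReferenceFeature <- function(x, refMass, tolPpm = 1) {
    mass <- neutralMass(x)
    hits <- which(abs(mass - refMass) <= refMass * tolPpm * 1e-6)
    if (length(hits) == 0)
        stop(sprintf("no feature within %g ppm of %.6f", tolPpm, refMass))
    if (length(hits) > 1)
        stop("ambiguous reference feature, candidates: ",
             paste(sprintf("%s (%.6f)", names(mass)[hits], mass[hits]),
                   collapse = ", "))
    m <- intensityMatrix(x)
    ref <- m[hits, ]
    if (any(is.na(ref)))
        stop("reference feature missing in sample(s): ",
             paste(colnames(m)[is.na(ref)], collapse = ", "))
    out <- sweep(m[-hits, , drop = FALSE], 2, ref, "/")
    res <- MassFeatureSet(out, mass[-hits], classLabels(x))
    metadata(res) <- metadata(x)
    res
}

#' @describeIn idt probabilistic quotient normalization: spectra are first
#'   integral (total-intensity) normalized, the reference spectrum is the
#'   per-feature mean of the integral-normalized samples, and each sample is
#'   then divided by the median of its feature-wise quotients against that
#'   reference (features with positive reference only). The initial
#'   integral step follows the canonical quotient-normalization procedure
#'   and makes the result exactly invariant to per-sample dilution:
#'   multiplying any one sample by k > 0 yields identical output. Requires
#'   a complete (post-imputation) matrix.
#' @export
normalizePQN <- function(x) {
    m <- intensityMatrix(x)
    if (anyNA(m)) stop("PQN requires a complete matrix (impute first)")
    tot <- colSums(m)
    if (any(tot <= 0)) stop("sample(s) with nonpositive total intensity")
    rel <- sweep(m, 2, tot, "/")   # dilution-free relative spectra
    ref <- rowMeans(rel)
    use <- ref > 0
    if (!any(use)) stop("reference spectrum is zero everywhere")
    q <- apply(rel[use, , drop = FALSE], 2, function(col)
        stats::median(col / ref[use]))
    if (any(q == 0)) stop("zero quotient for sample(s): ",
                          paste(colnames(m)[q == 0], collapse = ", "))
    .replaceIntensity(x, sweep(rel, 2, q, "/"))
}

#' @describeIn idt generalized logarithm
#'   \code{g(x) = log2((x + sqrt(x^2 + lambda)) / 2)}, elementwise. At
#'   \code{lambda = 0} this is exactly \code{log2(x)} (so values must then be
#'   positive); positive lambda tames the variance of low intensities.
#' @param lambda nonnegative transform parameter.
#' @export
glogTransform <- function(x, lambda = 0) {
    stopifnot(lambda >= 0)
    m <- intensityMatrix(x)
    if (lambda == 0 && any(m[!is.na(m)] <= 0))
        stop("nonpositive intensities need lambda > 0")
    .replaceIntensity(x, log2((m + sqrt(m^2 + lambda)) / 2))
}

#' @describeIn idt Pareto scaling: per feature, subtract the mean and divide
#'   by the square root of the standard deviation (a compromise between no
#'   scaling and autoscaling that keeps large fold changes influential).
#'   Constant features become all-zero rows. \code{center}/\code{scale}
#'   override the fitted parameters, which is how train-fitted scaling is
#'   applied to a test set; the fitted values are attached as attributes
#'   \code{pareto_center} / \code{pareto_scale} of the returned assay.
#' @param center,scale optional per-feature centers / sqrt-SD divisors.
#' @export
paretoScale <- function(x, center = NULL, scale = NULL) {
    m <- intensityMatrix(x)
    if (ncol(m) < 2 && is.null(center)) stop("need >= 2 samples to fit scaling")
    if (is.null(center)) center <- rowMeans(m)
    if (is.null(scale)) scale <- sqrt(apply(m, 1, stats::sd))
    out <- m - center
    pos <- scale > 0
    out[pos, ] <- out[pos, , drop = FALSE] / scale[pos]
    out[!pos, ] <- 0
    attr(out, "pareto_center") <- center
    attr(out, "pareto_scale") <- scale
    .replaceIntensity(x, out)
}

#' Pretreatment configuration
#'
#' @param imputation "fifth_min" or "random_forest".
#' @param normalization "pqn" or "reference"; \code{refMass}/\code{refTolPpm}
#'   locate the reference feature in the latter case.
#' @param glogLambda lambda for [glogTransform()]; \code{NULL} (default)
#'   means the square of the smallest non-missing training intensity — a
#'   detection-limit-scale softening of the log.
#' @param rfTrees,rfPredictors random-forest imputation parameters.
#' @param seed RNG seed for the stochastic steps.
#' @return a list of class \code{idt_config}.
#' @export
idtConfig <- function(imputation = c("fifth_min", "random_forest"),
                      normalization = c("pqn", "reference"),
                      refMass = NULL, refTolPpm = 1, glogLambda = NULL,
                      rfTrees = 50, rfPredictors = 100, seed = 1) {
    imputation <- match.arg(imputation)
    normalization <- match.arg(normalization)
    if (normalization == "reference" && is.null(refMass))
        stop("reference normalization needs refMass")
    structure(list(imputation = imputation, normalization = normalization,
                   refMass = refMass, refTolPpm = refTolPpm,
                   glogLambda = glogLambda, rfTrees = rfTrees,
                   rfPredictors = rfPredictors, seed = seed),
              class = "idt_config")
}

.idtImpute <- function(x, cfg, forceFifthMin = FALSE) {
    if (cfg$imputation == "fifth_min" || forceFifthMin) imputeFifthMin(x)
    else imputeRandomForest(x, nTrees = cfg$rfTrees,
                            nPredictors = cfg$rfPredictors, seed = cfg$seed)
}

.idtNormalize <- function(x, cfg) {
    if (cfg$normalization == "pqn") normalizePQN(x)
    else normalizeReferenceFeature(x, cfg$refMass, cfg$refTolPpm)
}

#' Full pretreatment pipeline with train/test leakage guards
#'
#' Runs imputation, normalization, generalized log and Pareto scaling. When
#' a test set is supplied the two are treated independently by the same
#' pipeline with the standard leakage guards: the training set is first
#' filtered to features occurring in at least two training samples and the
#' test set restricted to that universe; test features occurring in a single
#' test sample are imputed by the 1/5-minimum rule rather than the random
#' forest; features entirely absent from the test set are filled with the
#' minimum intensity observed in the training set; the glog lambda and the
#' Pareto center/scale are fitted on the training set and reused on the test
#' set. No statistic of the test set enters the training transform.
#'
#' @param train a [MassFeatureSet-class].
#' @param test optional [MassFeatureSet-class] on the same feature universe.
#' @param cfg an [idtConfig()].
#' @return \code{test = NULL}: the treated training set. Otherwise a list
#'   \code{list(train =, test =)}.
#' @export
idtPipeline <- function(train, test = NULL, cfg = idtConfig()) {
    if (is.null(test)) {
        tr <- .idtImpute(train, cfg)
        tr <- .idtNormalize(tr, cfg)
        lam <- cfg$glogLambda %||% min(intensityMatrix(tr))^2
        tr <- glogTransform(tr, lam)
        return(paretoScale(tr))
    }
    if (!length(intersect(featureIds(train), featureIds(test))))
        stop("train and test share no features")
    train <- filterMinGlobalOccurrence(train, 2)
    keep <- featureIds(train)
    testM <- matrix(NA_real_, nrow = length(keep), ncol = ncol(test),
                    dimnames = list(keep, sampleIds(test)))
    common <- intersect(keep, featureIds(test))
    testM[common, ] <- intensityMatrix(test)[common, , drop = FALSE]
    trainMin <- min(intensityMatrix(train), na.rm = TRUE)
    absent <- rowSums(!is.na(testM)) == 0
    testM[absent, ] <- trainMin
    test <- MassFeatureSet(testM, neutralMass(train)[keep],
                           classLabels(test))
    ## features seen once in the test set never feed the RF regressor
    once <- rowSums(!is.na(testM)) == 1
    tr <- .idtImpute(train, cfg)
    te <- if (cfg$imputation == "random_forest" && any(once)) {
        fm <- intensityMatrix(imputeFifthMin(test))
        partial <- intensityMatrix(test)
        partial[once, ] <- fm[once, ]
        .idtImpute(.replaceIntensity(test, partial), cfg)
    } else .idtImpute(test, cfg)
    tr <- .idtNormalize(tr, cfg)
    te <- .idtNormalize(te, cfg)
    lam <- cfg$glogLambda %||% min(intensityMatrix(tr))^2
    tr <- glogTransform(tr, lam)
    te <- glogTransform(te, lam)
    tr <- paretoScale(tr)
    ctr <- attr(intensityMatrix(tr), "pareto_center")
    scl <- attr(intensityMatrix(tr), "pareto_scale")
    idx <- match(featureIds(te), featureIds(tr))
    te <- paretoScale(te, center = ctr[idx], scale = scl[idx])
    list(train = tr, test = te)
}
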