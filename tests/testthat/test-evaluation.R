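## tight, well-separated class clouds at mutually orthogonal centers
blobs <- function(nPerClass = 4, k = 2, sep = 10, seed = 1, p = 3) {
    stopifnot(p >= k)
    withSeed(seed, {
        x <- do.call(rbind, lapply(seq_len(k), function(ci) {
            center <- rep(0, p); center[ci] <- sep
            matrix(rnorm(nPerClass * p, sd = 0.3), nPerClass, p,
                   byrow = TRUE) + rep(center, each = nPerClass)
        }))
    })
    rownames(x) <- paste0(rep(LETTERS[1:k], each = nPerClass),
                          seq_len(nPerClass))
    list(x = x, labels = rep(LETTERS[1:k], each = nPerClass))
}

test_that("UPGMA trees merge tight classes first and have monotone heights", {
    b <- blobs(4, 3, seed = 2)
    tree <- hcaCluster(b$x)
    expect_s3_class(tree, "hclust")
    expect_equal(nrow(tree$merge), nrow(b$x) - 1)
    expect_true(all(diff(tree$height) >= -1e-12))
    expect_equal(hcaCorrectClustering(tree, b$labels), 100)
    expect_equal(hcaCorrectFirstCluster(tree, b$labels), 100)
})

test_that("dendrogram statistics read a hand-constructed linkage correctly", {
    ## leaves 1,2 = class X; 3,4 = class Y; tree: (1,2)@1, (3,4)@2, join@5
    tree <- structure(list(
        merge = rbind(c(-1, -2), c(-3, -4), c(1, 2)),
        height = c(1, 2, 5),
        labels = c("x1", "x2", "y1", "y2"), method = "average"),
        class = "hclust")
    labels <- c("X", "X", "Y", "Y")
    expect_equal(hcaCorrectClustering(tree, labels), 100)
    ## gaps: X forms at 1, absorbed at 5 -> 4/5; Y forms at 2 -> 3/5
    expect_equal(hcaDiscriminationDistance(tree, labels), (4/5 + 3/5) / 2)
    expect_equal(hcaDiscriminationDistance(tree, labels, "absorption"), 1)
    ## contaminated variant: (x1, y1) first
    bad <- structure(list(
        merge = rbind(c(-1, -3), c(-2, -4), c(1, 2)),
        height = c(1, 2, 5),
        labels = c("x1", "x2", "y1", "y2"), method = "average"),
        class = "hclust")
    expect_equal(hcaCorrectClustering(bad, labels), 0)
    expect_equal(hcaDiscriminationDistance(bad, labels), 0)
    expect_equal(hcaCorrectFirstCluster(bad, labels), 0)
    ## one of four classes contaminated -> 75: C's members only ever join
    ## the A+B supercluster, never each other alone
    tree8 <- structure(list(
        merge = rbind(c(-1, -2), c(-3, -4), c(-7, -8), c(1, 2),
                      c(-5, 4), c(-6, 5), c(3, 6)),
        height = c(1, 1, 1, 2, 3, 4, 6),
        labels = paste0("s", 1:8), method = "average"), class = "hclust")
    lab8 <- c("A", "A", "B", "B", "C", "C", "D", "D")
    expect_equal(hcaCorrectClustering(tree8, lab8), 75)
    ## a singleton class forming at height 0
    tree3 <- structure(list(
        merge = rbind(c(-1, -2), c(-3, 1)),
        height = c(1, 4),
        labels = c("a1", "a2", "b1"), method = "average"), class = "hclust")
    expect_equal(hcaCorrectClustering(tree3, c("A", "A", "B")), 100)
    ## B: leaf absorbed at 4, gap (4 - 0)/4; A: (4 - 1)/4
    expect_equal(hcaDiscriminationDistance(tree3, c("A", "A", "B")),
                 (1 + 3/4) / 2)
})

test_that("a sample first merging into a pure own-class cluster counts correct", {
    tree <- structure(list(
        merge = rbind(c(-1, -2), c(-3, 1), c(-4, 2)),
        height = c(1, 2, 6),
        labels = c("a1", "a2", "a3", "b1"), method = "average"),
        class = "hclust")
    labels <- c("A", "A", "A", "B")
    ## a3 joins the pure (a1, a2) cluster -> correct; b1 joins an A cluster
    expect_equal(hcaCorrectFirstCluster(tree, labels), 75)
})

test_that("best-of-restarts K-means recovers separated blobs deterministically", {
    b <- blobs(5, 2, seed = 4)
    km1 <- kmeansCluster(b$x, 2, restarts = 20, seed = 3)
    km2 <- kmeansCluster(b$x, 2, restarts = 20, seed = 3)
    expect_identical(km1$cluster, km2$cluster)
    ev <- kmeansEval(km1, b$labels)
    expect_equal(ev$correct_clustering_pct, 100)
    expect_equal(ev$adjusted_rand, 1)
    ## k = n gives zero inertia
    kmn <- kmeansCluster(b$x, nrow(b$x), restarts = 2, seed = 1)
    expect_equal(kmn$tot.withinss, 0)
})

test_that("K-means statistics handle centroid geometry and chance agreement", {
    ## two clusters at distance 4 = the maximum -> discrimination distance 1
    x <- rbind(a1 = c(0, 0), a2 = c(0, 0.2), b1 = c(4, 0), b2 = c(4, 0.2))
    km <- kmeansCluster(x, 2, restarts = 5, seed = 2)
    ev <- kmeansEval(km, c("A", "A", "B", "B"))
    expect_equal(ev$discrimination_distance, 1, tolerance = 1e-9)
    ## ARI of a random partition is near zero in expectation
    withSeed(8, {
        labs <- rep(LETTERS[1:3], each = 10)
        aris <- replicate(300, mclust::adjustedRandIndex(sample(labs), labs))
    })
    expect_lt(abs(mean(aris)), 0.05)
    ## ARI is invariant to cluster relabeling
    part <- km$cluster
    relab <- c(2, 1)[part]
    expect_equal(mclust::adjustedRandIndex(part, c("A", "A", "B", "B")),
                 mclust::adjustedRandIndex(relab, c("A", "A", "B", "B")))
})

test_that("stratified folds preserve class balance and reject tiny classes", {
    labs <- rep(c("A", "B", "C"), times = c(6, 6, 9))
    f <- stratifiedFolds(labs, 3, seed = 1)
    for (k in 1:3) {
        expect_equal(sum(labs[f == k] == "A"), 2)
        expect_equal(sum(labs[f == k] == "C"), 3)
    }
    expect_error(stratifiedFolds(c("A", "A", "B"), 2, 1), "smaller")
    expect_identical(stratifiedFolds(labs, 3, 5), stratifiedFolds(labs, 3, 5))
})

test_that("random-forest CV is perfect on separable data and honest on noise", {
    b <- blobs(6, 2, seed = 6, p = 5)
    cv <- rfClassifyCV(b$x, b$labels, nFolds = 3, nIterations = 4, seed = 2)
    expect_equal(cv$accuracy_mean, 1)
    expect_equal(cv$accuracy_sd, 0)
    ## bit-reproducible under the master seed
    cv2 <- rfClassifyCV(b$x, b$labels, nFolds = 3, nIterations = 4, seed = 2)
    expect_identical(cv$accuracies, cv2$accuracies)
    expect_identical(cv$importance, cv2$importance)
    ## shuffled labels land near chance (1/2)
    noise <- withSeed(3, sample(b$labels))
    cvn <- rfClassifyCV(b$x, noise, nFolds = 3, nIterations = 10, seed = 4)
    expect_lt(abs(cvn$accuracy_mean - 0.5), 0.2)
    expect_error(rfClassifyCV(b$x, rep(c("A","B","C","D"), 3), nFolds = 5),
                 "smaller")
})

test_that("NIPALS PLS2 matches least squares at full rank and predicts toys", {
    withSeed(10, {
        X <- matrix(rnorm(40), 10, 4)
        B <- matrix(c(1, -2, 0, 3, 0.5, 1, -1, 0), 4, 2)
        Y <- X %*% B + 0.01 * matrix(rnorm(20), 10, 2)
    })
    fit <- plsNipals(X, Y, ncomp = 4)
    ## with all components, PLS regression equals OLS
    ols <- stats::lm.fit(cbind(1, X), Y)$coefficients[-1, ]
    expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-8)
    pred <- predict(fit, X)
    expect_equal(pred, Y, tolerance = 0.05)
    expect_error(plsNipals(X, Y, ncomp = 9), "rank")
})

test_that("PLS-DA CV separates blobs, honors fixed components, breaks ties low", {
    b <- blobs(6, 3, seed = 12, p = 6)
    cv <- plsdaClassifyCV(b$x, b$labels, nComponents = 2, nFolds = 3,
                          nIterations = 3, seed = 7)
    expect_equal(cv$accuracy_mean, 1)
    ## auto selection also succeeds on an easy problem
    cva <- plsdaClassifyCV(b$x, b$labels, nComponents = "auto", nFolds = 3,
                           nIterations = 2, maxComponents = 4, seed = 3)
    expect_gt(cva$accuracy_mean, 0.9)
    ## argmax tie -> first (lowest) class index
    Yhat <- rbind(c(0.4, 0.4, 0.2))
    expect_equal(as.character(smdin:::.plsDecision(Yhat, c("A", "B", "C"))),
                 "A")
    ## two-class threshold rule at exactly 0.5
    expect_equal(as.character(smdin:::.plsDecision(cbind(c(0.49, 0.5)),
                                                   c("A", "B"))),
                 c("A", "B"))
})

test_that("permutation p-values use the add-one estimator with a positive floor", {
    b <- blobs(5, 2, seed = 14, p = 4)
    quickCV <- function(profile, labels, seed)
        rfClassifyCV(profile, labels, nFolds = 2, nIterations = 1,
                     nTrees = 50, seed = seed)$accuracy_mean
    pt <- permutationTest(b$x, b$labels, quickCV, nPerm = 19, seed = 5)
    expect_equal(pt$p_value, 1 / 20)      # separable: no permutation wins
    expect_equal(pt$observed, 1)
    ## the estimator can never return zero and is bounded by 1
    expect_true(all(vapply(1:3, function(s)
        permutationTest(b$x, withSeed(s, sample(b$labels)), quickCV,
                        nPerm = 9, seed = s)$p_value, numeric(1)) > 0))
})

test_that("cross-validated ROC reaches AUC 1 on separable data, 0.5 on noise", {
    b <- blobs(10, 2, seed = 16, p = 4)
    roc <- rocAucCV(b$x, b$labels, "rf", nFolds = 5, seed = 2)
    expect_equal(roc$auc, 1)
    rocP <- rocAucCV(b$x, b$labels, "plsda", nFolds = 5, nComponents = 2,
                     seed = 2)
    expect_equal(rocP$auc, 1)
    ## pure-noise features: AUC near 1/2 at n = 200
    withSeed(21, {
        xn <- matrix(rnorm(200 * 8), 200, 8)
        ln <- rep(c("A", "B"), each = 100)
    })
    rocN <- rocAucCV(xn, ln, "plsda", nFolds = 5, nComponents = 2, seed = 3)
    expect_lt(abs(rocN$auc - 0.5), 0.1)
    expect_error(rocAucCV(b$x, rep(c("A", "B", "C"), length.out = 20), "rf"),
                 "two classes")
})
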