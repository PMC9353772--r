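mkComplete <- function(seed = 1, nf = 40, ns = 8, missing = 0.3) {
    withSeed(seed, {
        x <- matrix(rlnorm(nf * ns, 10, 1), nf, ns,
                    dimnames = list(sprintf("f%02d", 1:nf),
                                    sprintf("s%02d", 1:ns)))
        x[sample(length(x), round(missing * length(x)))] <- NA
        ## keep every sample and feature observed at least once
        x[1, ] <- rlnorm(ns, 10, 1)
    })
    MassFeatureSet(x, seq(100, by = 17.3, length.out = nf),
                   rep(c("A", "B"), each = ns / 2))
}

test_that("fifth-minimum imputation fills gaps per sample", {
    x <- cbind(s1 = c(10, NA, 50), s2 = c(NA, 5, 20))
    rownames(x) <- c("f1", "f2", "f3")
    m <- MassFeatureSet(x, c(100, 200, 300), c("A", "B"))
    out <- intensityMatrix(imputeFifthMin(m))
    expect_equal(out["f2", "s1"], 2)   # min(10, 50)/5
    expect_equal(out["f1", "s2"], 1)   # min(5, 20)/5
    ## no missing -> identity
    full <- imputeFifthMin(imputeFifthMin(m))
    expect_equal(intensityMatrix(full), out)
})

test_that("random-forest imputation completes the matrix plausibly and reproducibly", {
    m <- mkComplete(3)
    out1 <- imputeRandomForest(m, seed = 9)
    out2 <- imputeRandomForest(m, seed = 9)
    expect_false(anyNA(intensityMatrix(out1)))
    expect_identical(intensityMatrix(out1), intensityMatrix(out2))
    ## observed cells are untouched
    obs <- !is.na(intensityMatrix(m))
    expect_equal(intensityMatrix(out1)[obs], intensityMatrix(m)[obs])
    ## no missing -> identity
    expect_identical(intensityMatrix(imputeRandomForest(out1, seed = 1)),
                     intensityMatrix(out1))
    ## imputed values stay within a broad data-driven range
    imp <- intensityMatrix(out1)[!obs]
    expect_true(all(imp >= min(intensityMatrix(m), na.rm = TRUE) / 5 - 1e-9))
    expect_true(all(imp <= max(intensityMatrix(m), na.rm = TRUE) + 1e-9))
})

test_that("reference-feature normalization divides by the reference and drops it", {
    x <- rbind(ref = c(2, 4), f2 = c(10, 40), f3 = c(6, 8))
    colnames(x) <- c("s1", "s2")
    m <- MassFeatureSet(x, c(554.262022, 300, 400), c("A", "B"))
    out <- normalizeReferenceFeature(m, 554.262022, tolPpm = 1)
    expect_equal(nrow(out), 2)
    expect_equal(unname(intensityMatrix(out)["f2", ]), c(5, 10))
    expect_error(normalizeReferenceFeature(m, 100), "no feature within")
    dup <- MassFeatureSet(rbind(x, ref2 = c(1, 1)),
                          c(554.262022, 300, 400, 554.262023), c("A", "B"))
    expect_error(normalizeReferenceFeature(dup, 554.262022), "ambiguous")
})

test_that("quotient normalization is dilution-invariant and fixes known scalings", {
    m <- imputeFifthMin(mkComplete(5))
    x <- intensityMatrix(m)
    x2 <- x; x2[, 4] <- x2[, 4] * 11
    m2 <- MassFeatureSet(x2, neutralMass(m), classLabels(m))
    expect_equal(intensityMatrix(normalizePQN(m)),
                 intensityMatrix(normalizePQN(m2)), tolerance = 1e-12)
    ## identical samples stay identical
    same <- MassFeatureSet(matrix(rep(c(1, 2, 3), 4), 3,
                                  dimnames = list(paste0("f", 1:3),
                                                  paste0("s", 1:4))),
                           c(100, 200, 300), rep("A", 4))
    ns <- intensityMatrix(normalizePQN(same))
    expect_true(all(apply(ns, 1, function(r) diff(range(r)) == 0)))
    expect_error(normalizePQN(mkComplete(1)), "complete matrix")
})

test_that("the generalized log reduces to log2 at lambda zero and is monotone", {
    m <- imputeFifthMin(mkComplete(2))
    expect_equal(intensityMatrix(glogTransform(m, 0)),
                 log2(intensityMatrix(m)))
    xs <- sort(withSeed(3, runif(50, 0.01, 100)))
    for (lam in c(0, 1, 1e4)) {
        g <- log2((xs + sqrt(xs^2 + lam)) / 2)
        expect_true(all(diff(g) > 0), info = paste("lambda", lam))
    }
    neg <- MassFeatureSet(cbind(s1 = c(0, 2), s2 = c(1, 3)) ,
                          c(100, 200), c("A", "B"))
    expect_error(glogTransform(neg, 0), "nonpositive")
})

test_that("Pareto scaling centers features and leaves variance equal to prior SD", {
    m <- glogTransform(imputeFifthMin(mkComplete(4)), 0)
    ps <- intensityMatrix(paretoScale(m))
    expect_true(max(abs(rowMeans(ps))) < 1e-12)
    pre <- apply(intensityMatrix(m), 1, sd)
    post <- apply(ps, 1, var)
    expect_equal(unname(post), unname(pre), tolerance = 1e-12)
    ## constant features become zero rows
    x <- rbind(f1 = c(5, 5, 5), f2 = c(1, 2, 3))
    cm <- MassFeatureSet(x, c(100, 200), rep("A", 3))
    expect_true(all(intensityMatrix(paretoScale(cm))["f1", ] == 0))
})

test_that("the full pipeline yields complete centered matrices and guards the split", {
    m <- mkComplete(6, nf = 60, ns = 12)
    out <- idtPipeline(m, cfg = idtConfig("fifth_min", "pqn"))
    expect_false(anyNA(intensityMatrix(out)))
    expect_true(max(abs(rowMeans(intensityMatrix(out)))) < 1e-10)
    ## train/test: test features absent get the train minimum, and the
    ## applied scaling comes from the train fit
    tr <- m[, 1:8]
    te <- m[, 9:12]
    teX <- intensityMatrix(te)
    teX[5, ] <- NA   # feature absent from every test sample
    te <- MassFeatureSet(teX, neutralMass(m), classLabels(m)[9:12])
    split <- idtPipeline(tr, te, idtConfig("fifth_min", "pqn"))
    expect_false(anyNA(intensityMatrix(split$test)))
    expect_equal(featureIds(split$test), featureIds(split$train))
    ## the test rows are NOT centered by their own means (train-fitted)
    expect_gt(max(abs(rowMeans(intensityMatrix(split$test)))), 1e-6)
    disjoint <- MassFeatureSet(matrix(1:4, 2,
                                      dimnames = list(c("q1", "q2"), NULL)),
                               c(1, 2), c("A", "B"))
    expect_error(idtPipeline(tr, disjoint, idtConfig()), "no features")
})
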