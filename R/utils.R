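#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so stochastic steps (forests, K-means
#' restarts, fold draws) are reproducible without clobbering the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

## deterministic sub-seed derivation: one master seed fans out to
## per-iteration / per-fold / per-permutation seeds, kept below 2^31
.subSeed <- function(seed, ...) {
    parts <- c(seed, ...)
    s <- 0
    for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
    as.integer(s)
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of \code{nFolds} folds with class proportions
#' preserved (within each class, a shuffled round-robin). Errors if any
#' class has fewer members than folds.
#'
#' @param labels class labels.
#' @param nFolds number of folds.
#' @param seed RNG seed for the shuffle.
#' @return integer fold assignment, same length/order as \code{labels}.
#' @export
stratifiedFolds <- function(labels, nFolds, seed = 1) {
    y <- factor(labels)
    small <- table(y) < nFolds
    if (any(small))
        stop("class(es) smaller than the fold count: ",
             paste(names(which(small)), collapse = ", "))
    folds <- integer(length(y))
    withSeed(seed, {
        for (g in levels(y)) {
            idx <- sample(which(y == g))
            folds[idx] <- rep_len(seq_len(nFolds), length(idx))
        }
    })
    folds
}
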