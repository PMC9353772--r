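#' Hierarchical clustering of a profile matrix
#'
#' UPGMA (average linkage) agglomeration on Euclidean distances, the
#' reference unsupervised method for profile matrices. Returns a standard
#' \code{hclust} object (merge list + monotone heights). Ties in the
#' distance matrix are resolved deterministically by \code{stats::hclust}
#' (lowest observation pair first).
#'
#' @param profile numeric matrix, samples x features.
#' @return an object of class \code{hclust}.
#' @export
hcaCluster <- function(profile) {
    stopifnot(nrow(profile) >= 2)
    stats::hclust(stats::dist(profile), method = "average")
}

## member leaf indices of every node of an hclust tree:
## negative ids = leaves, positive = merge rows
.mergeMembers <- function(tree) {
    n <- nrow(tree$merge) + 1L
    members <- vector("list", nrow(tree$merge))
    getm <- function(id) if (id < 0) -id else members[[id]]
    for (i in seq_len(nrow(tree$merge))) {
        members[[i]] <- sort(c(getm(tree$merge[i, 1]),
                               getm(tree$merge[i, 2])))
    }
    members
}

## for a class: the node (leaf or merge) holding exactly its samples, or NA
.pureNode <- function(members, classIdx) {
    if (length(classIdx) == 1L) return(-classIdx)   # a leaf is a pure node
    hit <- which(vapply(members, function(m)
        length(m) == length(classIdx) && all(m == sort(classIdx)),
        logical(1)))
    if (length(hit)) hit[1] else NA_integer_
}

#' Dendrogram-based clustering performance statistics
#'
#' Three statistics read off an agglomerative tree against ground-truth
#' classes.
#'
#' \code{hcaCorrectClustering}: a class is correctly clustered when some tree
#' node contains exactly its samples (all replicates join each other before
#' anything else); the statistic is the percentage of correct classes.
#'
#' \code{hcaDiscriminationDistance}: per correctly clustered class, the
#' height gap between the merge that forms the pure class node and the merge
#' that absorbs it into a larger cluster, normalized by the tree's maximum
#' merge height; incorrectly clustered classes score 0, and the statistic is
#' the mean over classes. With \code{variant = "absorption"} the absorption
#' height itself (normalized) is used instead of the gap.
#'
#' \code{hcaCorrectFirstCluster}: the percentage of samples whose first
#' merge joins them only with samples of their own class (joining an
#' existing pure own-class cluster counts as correct).
#'
#' @param tree an \code{hclust} from [hcaCluster()].
#' @param labels class labels in the order of the clustered rows.
#' @return a percentage in [0, 100], or for the discrimination distance a
#'   value in [0, 1].
#' @name hca-statistics
NULL

#' @rdname hca-statistics
#' @export
hcaCorrectClustering <- function(tree, labels) {
    members <- .mergeMembers(tree)
    classes <- split(seq_along(labels), labels)
    correct <- vapply(classes, function(idx)
        !is.na(.pureNode(members, idx)), logical(1))
    100 * mean(correct)
}

#' @rdname hca-statistics
#' @param variant "gap" (formation-to-absorption height difference, default)
#'   or "absorption" (absorption height).
#' @export
hcaDiscriminationDistance <- function(tree, labels,
                                      variant = c("gap", "absorption")) {
    variant <- match.arg(variant)
    members <- .mergeMembers(tree)
    classes <- split(seq_along(labels), labels)
    maxH <- max(tree$height)
    if (maxH <= 0) return(0)
    vals <- vapply(classes, function(idx) {
        node <- .pureNode(members, idx)
        if (is.na(node)) return(0)
        hForm <- if (node < 0) 0 else tree$height[node]
        absorb <- which(tree$merge[, 1] == node | tree$merge[, 2] == node)
        if (!length(absorb)) return(0)   # class node is the root
        hAbs <- tree$height[absorb[1]]
        if (variant == "gap") (hAbs - hForm) / maxH else hAbs / maxH
    }, numeric(1))
    mean(vals)
}

#' @rdname hca-statistics
#' @export
hcaCorrectFirstCluster <- function(tree, labels) {
    members <- .mergeMembers(tree)
    getm <- function(id) if (id < 0) -id else members[[id]]
    correct <- logical(length(labels))
    for (i in seq_len(nrow(tree$merge))) {
        a <- tree$merge[i, 1]; b <- tree$merge[i, 2]
        for (leaf in c(a, b)[c(a, b) < 0]) {
            other <- if (leaf == a) b else a
            correct[-leaf] <- all(labels[getm(other)] == labels[-leaf])
        }
    }
    100 * mean(correct)
}

#' Best-of-restarts K-means clustering
#'
#' Euclidean K-means with the number of clusters set to the number of
#' classes and the lowest-inertia solution over \code{restarts} random
#' initializations retained; reproducible under \code{seed}.
#'
#' @param profile numeric matrix, samples x features.
#' @param k number of clusters.
#' @param restarts random restarts (default 20).
#' @param seed RNG seed.
#' @return a \code{stats::kmeans} fit.
#' @export
kmeansCluster <- function(profile, k, restarts = 20, seed = 1) {
    stopifnot(k <= nrow(profile), restarts >= 1)
    ## Hartigan-Wong needs k < n; the k = n edge case is exact under Lloyd
    alg <- if (k == nrow(profile)) "Lloyd" else "Hartigan-Wong"
    withSeed(seed, stats::kmeans(profile, centers = k, nstart = restarts,
                                 iter.max = 100, algorithm = alg))
}

#' Partition-based clustering performance statistics
#'
#' Evaluates a K-means partition against ground truth. A class counts as
#' correctly clustered only when some cluster contains all of its samples
#' and nothing else (total homogeneity and completeness) — stricter than the
#' dendrogram criterion. The discrimination distance of a correct class is
#' the distance from its cluster centroid to the nearest other centroid,
#' normalized by the maximum pairwise centroid distance (0 for incorrect
#' classes; mean over classes). The adjusted Rand index is the
#' chance-corrected pair-counting agreement between partition and classes.
#'
#' @param fit a \code{stats::kmeans} fit from [kmeansCluster()].
#' @param labels class labels in row order of the clustered profile.
#' @return list with \code{correct_clustering_pct},
#'   \code{discrimination_distance}, \code{adjusted_rand}.
#' @export
kmeansEval <- function(fit, labels) {
    part <- fit$cluster
    classes <- split(seq_along(labels), labels)
    clusters <- split(seq_along(part), part)
    matchOf <- vapply(classes, function(idx) {
        hit <- which(vapply(clusters, function(cidx)
            length(cidx) == length(idx) && all(sort(cidx) == sort(idx)),
            logical(1)))
        if (length(hit)) as.integer(names(clusters)[hit[1]]) else NA_integer_
    }, integer(1))
    cd <- as.matrix(stats::dist(fit$centers))
    maxD <- max(cd)
    dd <- vapply(seq_along(classes), function(i) {
        cl <- matchOf[i]
        if (is.na(cl) || maxD == 0 || nrow(fit$centers) < 2) return(0)
        min(cd[cl, -cl]) / maxD
    }, numeric(1))
    list(correct_clustering_pct = 100 * mean(!is.na(matchOf)),
         discrimination_distance = mean(dd),
         adjusted_rand = mclust::adjustedRandIndex(part, labels))
}
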