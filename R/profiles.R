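#' Graph-metric profile matrices
#'
#' Each metric turns a set of per-sample networks (sMDiNs) into a samples x
#' features numeric matrix suitable for ordinary clustering/classification:
#' node centralities keep the mass features as columns (0 when a feature is
#' absent from a sample's network), MDB impact metrics use the MDB labels as
#' columns, and the graphlet-correlation features use orbit pairs. No cell
#' is ever missing — absence is encoded as 0.
#'
#' @param smdins named list of [MassDiffNet-class], one per sample (e.g. from
#'   [sampleNetworks()]).
#' @param universe character, the full feature-id universe defining the
#'   column set shared across samples; must cover every network's nodes.
#' @name graph-profiles
NULL

.profileSkeleton <- function(smdins, universe) {
    miss <- setdiff(unique(unlist(lapply(smdins, function(n)
        igraph::V(n@graph)$name))), universe)
    if (length(miss))
        stop("universe does not cover network node(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
    matrix(0, nrow = length(smdins), ncol = length(universe),
           dimnames = list(names(smdins), universe))
}

#' @describeIn graph-profiles node degree (number of incident edges; parallel
#'   MDB edges count separately).
#' @export
degreeProfile <- function(smdins, universe) {
    out <- .profileSkeleton(smdins, universe)
    for (s in names(smdins)) {
        g <- smdins[[s]]@graph
        if (igraph::vcount(g))
            out[s, igraph::V(g)$name] <- igraph::degree(g)
    }
    out
}

#' @describeIn graph-profiles betweenness centrality: for node v, the sum
#'   over unordered node pairs \{s, t\} (both different from v) of the
#'   fraction of shortest s-t paths passing through v. Unnormalized, as is
#'   conventional for mass-difference network profiling; computed on the
#'   simple-graph skeleton (parallel edges carry no path information).
#' @export
betweennessProfile <- function(smdins, universe) {
    out <- .profileSkeleton(smdins, universe)
    for (s in names(smdins)) {
        g <- igraph::simplify(smdins[[s]]@graph)
        if (igraph::vcount(g))
            out[s, igraph::V(g)$name] <-
                igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    }
    out
}

#' @describeIn graph-profiles closeness centrality with the component
#'   correction for disconnected graphs:
#'   \code{C(v) = ((n-1)/(N-1)) * (n-1)/sum(d(u,v))} where n is the size of
#'   v's connected component (v included), N the network's node count and
#'   the sum runs over the nodes reaching v. Isolated-in-subgraph and absent
#'   features are 0.
#' @export
closenessProfile <- function(smdins, universe) {
    out <- .profileSkeleton(smdins, universe)
    for (s in names(smdins)) {
        g <- igraph::simplify(smdins[[s]]@graph)
        N <- igraph::vcount(g)
        if (N == 0) next
        comp <- igraph::components(g)
        n <- comp$csize[comp$membership]
        d <- igraph::distances(g)
        sumd <- apply(d, 1, function(r) sum(r[is.finite(r) & r > 0]))
        cc <- numeric(N)
        ok <- n > 1 & N > 1
        cc[ok] <- ((n[ok] - 1) / (N - 1)) * ((n[ok] - 1) / sumd[ok])
        out[s, igraph::V(g)$name] <- cc
    }
    out
}

#' @describeIn graph-profiles MDB impact (MDBI): per sample, the fraction of
#'   the network's edges attributed to each MDB. Rows sum to 1 whenever the
#'   network has at least one edge; an empty network yields an all-zero row.
#' @param mdbs an [MDBTable-class] giving the column universe of MDB labels.
#' @export
mdbiProfile <- function(smdins, mdbs = defaultMDBs()) {
    labs <- mdbLabels(mdbs)
    out <- matrix(0, nrow = length(smdins), ncol = length(labs),
                  dimnames = list(names(smdins), labs))
    for (s in names(smdins)) {
        e <- igraph::E(smdins[[s]]@graph)$mdb
        if (length(e)) {
            tab <- table(factor(e, levels = labs))
            out[s, ] <- as.numeric(tab) / length(e)
        }
    }
    out
}

#' Node importance from degree profiles
#'
#' Fits a random forest to the training samples' degree profiles against the
#' class labels and returns the gini (mean decrease in impurity) importance
#' of every feature, normalized to sum to 1. This supervised weight vector
#' drives the weighted MDB impact ([wmdbiProfile()]): nodes whose degree is
#' characteristic of the classes make their edges count more. If the forest
#' assigns zero importance everywhere (e.g. all-constant profiles), the
#' fallback is uniform weights.
#'
#' @param trainProfiles numeric matrix, samples x features (degree profile).
#' @param trainLabels class labels (>= 2 classes required).
#' @param nTrees number of trees (default 100).
#' @param seed RNG seed for the forest.
#' @return named numeric vector of weights summing to 1.
#' @export
nodeImportanceFromDegree <- function(trainProfiles, trainLabels,
                                     nTrees = 100, seed = 1) {
    y <- factor(trainLabels)
    if (nlevels(y) < 2) stop("need at least two classes")
    ## constant columns carry no split information (and stall the forest);
    ## they get zero importance, or uniform weights if nothing varies
    varying <- apply(trainProfiles, 2, function(col) diff(range(col)) > 0)
    imp <- numeric(ncol(trainProfiles))
    if (any(varying)) {
        imp[varying] <- withSeed(seed, {
            fit <- randomForest::randomForest(
                x = trainProfiles[, varying, drop = FALSE], y = y,
                ntree = nTrees)
            fit$importance[, "MeanDecreaseGini"]
        })
    }
    imp <- pmax(imp, 0)
    if (sum(imp) == 0) imp[] <- 1
    stats::setNames(imp / sum(imp), colnames(trainProfiles))
}

#' @describeIn graph-profiles weighted MDB impact (WMDBI): each edge is
#'   weighted by the summed importance of its two endpoint nodes, and the
#'   cell for MDB b is the weight of b's edges over the total edge weight.
#'   Samples whose edges all carry zero weight fall back to the plain MDBI
#'   row. Rows sum to 1 whenever edges exist.
#' @param importance named numeric node-weight vector (see
#'   [nodeImportanceFromDegree()]); features without an entry weigh 0.
#' @export
wmdbiProfile <- function(smdins, mdbs = defaultMDBs(), importance) {
    labs <- mdbLabels(mdbs)
    out <- matrix(0, nrow = length(smdins), ncol = length(labs),
                  dimnames = list(names(smdins), labs))
    plain <- mdbiProfile(smdins, mdbs)
    for (s in names(smdins)) {
        g <- smdins[[s]]@graph
        if (igraph::ecount(g) == 0) next
        el <- igraph::as_edgelist(g)
        w <- .lookupWeight(importance, el[, 1]) +
            .lookupWeight(importance, el[, 2])
        if (sum(w) == 0) { out[s, ] <- plain[s, ]; next }
        agg <- tapply(w, factor(igraph::E(g)$mdb, levels = labs), sum,
                      default = 0)
        out[s, ] <- as.numeric(agg) / sum(w)
    }
    out
}

.lookupWeight <- function(importance, ids) {
    w <- importance[ids]
    w[is.na(w)] <- 0
    unname(w)
}
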