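#' Build a mass-difference network
#'
#' Connects every pair of features whose absolute neutral-mass difference
#' matches an MDB's monoisotopic delta mass within a relative tolerance. The
#' tolerance window for a pair (u, v) is \code{ppm * 1e-6 * max(m(u), m(v))}
#' by default: measurement error scales with the measured masses, and a ppm
#' of the (tiny) difference itself would be physically unattainable. With
#' \code{toleranceRef = "sum"} the reference is \code{m(u) + m(v)} instead.
#'
#' Edges are undirected (an addition one way is a loss the other way) and a
#' pair may carry several MDB labels if more than one delta matches — all
#' matching edges are created, no best-match selection. The edge attribute
#' \code{residual_ppm} stores the signed residual of the match in ppm of the
#' reference mass. The result is identical to a brute-force scan over all
#' pairs and all MDBs; internally a sort-and-window search keeps it near
#' O(n log n) per MDB.
#'
#' @param x a [MassFeatureSet-class], or a named numeric vector of neutral
#'   masses (names = feature ids).
#' @param mdbs an [MDBTable-class] (default [defaultMDBs()]).
#' @param ppm relative tolerance in parts per million (default 1).
#' @param toleranceRef reference mass for the window: "max" (default) or
#'   "sum".
#' @return a [MassDiffNet-class] containing every feature as a vertex (also
#'   the unconnected ones — drop them with [deriveSMDiN()] or inspect them
#'   via [summarizeNetwork()]).
#' @examples
#' net <- buildMDiN(c(a = 100, b = 114.015650, c = 116.031300))
#' edgeTable(net)   # a-b via CH2, b-c via H2
#' @export
buildMDiN <- function(x, mdbs = defaultMDBs(), ppm = 1,
                      toleranceRef = c("max", "sum")) {
    toleranceRef <- match.arg(toleranceRef)
    stopifnot(ppm > 0)
    masses <- if (is(x, "MassFeatureSet")) neutralMass(x) else x
    if (is.null(names(masses)))
        names(masses) <- sprintf("F%04d", seq_along(masses))
    ord <- order(masses)
    ms <- masses[ord]
    n <- length(ms)
    ef <- et <- elab <- eres <- list()
    deltas <- mdbMasses(mdbs)
    if (n >= 2) for (b in seq_along(deltas)) {
        d <- deltas[b]
        ## upper bound on the window so the exact per-pair check below can
        ## never be clipped: reference mass <= 2 * larger mass
        slack <- ppm * 1e-6 * 2
        lo <- findInterval(ms + d - (ms + d) * slack, ms) + 1L
        hi <- findInterval(ms + d + (ms + d) * slack, ms)
        for (i in which(lo <= hi)) {
            j <- lo[i]:hi[i]
            j <- j[j != i]
            if (!length(j)) next
            diff <- ms[j] - ms[i]
            ref <- if (toleranceRef == "max") pmax(ms[i], ms[j]) else ms[i] + ms[j]
            keep <- abs(abs(diff) - d) <= ppm * 1e-6 * ref
            if (any(keep)) {
                j <- j[keep]
                ef[[length(ef) + 1L]] <- rep(names(ms)[i], length(j))
                et[[length(et) + 1L]] <- names(ms)[j]
                elab[[length(elab) + 1L]] <- rep(names(deltas)[b], length(j))
                eres[[length(eres) + 1L]] <-
                    (abs(diff[keep]) - d) / (ref[keep] * 1e-6)
            }
        }
    }
    edges <- data.frame(from = as.character(unlist(ef)),
                        to = as.character(unlist(et)),
                        mdb = as.character(unlist(elab)),
                        residual_ppm = as.numeric(unlist(eres)),
                        stringsAsFactors = FALSE)
    if (nrow(edges)) {
        ## each undirected pair was found twice (once from each endpoint)
        a <- pmin(edges$from, edges$to)
        b <- pmax(edges$from, edges$to)
        keep <- !duplicated(paste(a, b, edges$mdb))
        edges <- data.frame(from = a, to = b, mdb = edges$mdb,
                            residual_ppm = edges$residual_ppm,
                            stringsAsFactors = FALSE)[keep, , drop = FALSE]
    }
    g <- igraph::graph_from_data_frame(
        edges,
        directed = FALSE,
        vertices = data.frame(name = names(masses), mass = unname(masses)))
    new("MassDiffNet", graph = g, universeSize = length(masses))
}

#' Derive a per-sample mass-difference network (sMDiN)
#'
#' Induces the subgraph of a dataset-level network on the features detected
#' in one sample and removes degree-0 nodes (unconnected features establish
#' no transformation and are uninformative). Because an edge depends only on
#' its two endpoint masses, this equals building the network from scratch on
#' the sample's masses.
#'
#' @param net a [MassDiffNet-class].
#' @param presentFeatures character, feature ids detected in the sample
#'   (must be a subset of the network's vertices).
#' @return a [MassDiffNet-class]; \code{universeSize} is the number of
#'   present features before isolated-node removal.
#' @export
deriveSMDiN <- function(net, presentFeatures) {
    g <- net@graph
    missing <- setdiff(presentFeatures, igraph::V(g)$name)
    if (length(missing))
        stop("feature(s) not in network: ", paste(missing, collapse = ", "))
    sub <- igraph::induced_subgraph(g, presentFeatures)
    sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
    new("MassDiffNet", graph = sub,
        universeSize = length(presentFeatures))
}

#' Per-sample networks for every sample of a dataset
#'
#' @param x a [MassFeatureSet-class].
#' @param net optional prebuilt dataset [MassDiffNet-class] for \code{x}
#'   (built with [buildMDiN()] if omitted).
#' @param ... passed to [buildMDiN()] when \code{net} is missing.
#' @return named list of [MassDiffNet-class], one sMDiN per sample.
#' @export
sampleNetworks <- function(x, net = buildMDiN(x, ...), ...) {
    occ <- occurrenceMatrix(x)
    lapply(stats::setNames(sampleIds(x), sampleIds(x)), function(s)
        deriveSMDiN(net, rownames(occ)[occ[, s]]))
}

#' Summarize network structure
#'
#' Computes the column set of the usual MDiN characteristics table: node and
#' edge counts, size of the largest connected component, percentage of
#' connected (degree >= 1) nodes relative to the feature universe, and the
#' diameter and radius of the largest component (unweighted shortest paths
#' on the simple skeleton). An empty network yields all zeros.
#'
#' @param net a [MassDiffNet-class].
#' @param totalFeatureCount denominator for the connected-node percentage;
#'   defaults to the network's recorded universe size.
#' @return a one-row \code{data.frame} with columns \code{n_nodes},
#'   \code{n_edges}, \code{largest_component}, \code{pct_connected},
#'   \code{diameter}, \code{radius}.
#' @export
summarizeNetwork <- function(net, totalFeatureCount = net@universeSize) {
    g <- net@graph
    n <- igraph::vcount(g)
    e <- igraph::ecount(g)
    if (n == 0 || e == 0) {
        conn <- if (n) sum(igraph::degree(g) > 0) else 0
        return(data.frame(n_nodes = n, n_edges = e, largest_component = 0,
                          pct_connected = if (totalFeatureCount)
                              100 * conn / totalFeatureCount else 0,
                          diameter = 0, radius = 0))
    }
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    sub <- igraph::simplify(sub)
    ecc <- igraph::eccentricity(sub)
    data.frame(
        n_nodes = n, n_edges = e,
        largest_component = max(comp$csize),
        pct_connected = 100 * sum(igraph::degree(g) > 0) / totalFeatureCount,
        diameter = max(ecc), radius = min(ecc))
}

#' @describeIn MassDiffNet-accessors the underlying igraph object.
#' @param x a \code{MassDiffNet}.
#' @export
setMethod("asIgraph", "MassDiffNet", function(x) x@graph)

#' @describeIn MassDiffNet-accessors vertex masses, named by feature id.
#' @export
setMethod("nodeMasses", "MassDiffNet", function(x)
    stats::setNames(igraph::V(x@graph)$mass, igraph::V(x@graph)$name))

#' @describeIn MassDiffNet-accessors edges as a data.frame (from, to, mdb,
#'   residual_ppm).
#' @export
setMethod("edgeTable", "MassDiffNet", function(x) {
    g <- x@graph
    if (igraph::ecount(g) == 0)
        return(data.frame(from = character(0), to = character(0),
                          mdb = character(0), residual_ppm = numeric(0)))
    el <- igraph::as_edgelist(g)
    data.frame(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
               mdb = igraph::E(g)$mdb,
               residual_ppm = igraph::E(g)$residual_ppm,
               stringsAsFactors = FALSE)
})

#' @export
setMethod("show", "MassDiffNet", function(object) {
    g <- object@graph
    cat(sprintf("MassDiffNet: %d nodes, %d edges (universe %d features)\n",
                igraph::vcount(g), igraph::ecount(g), object@universeSize))
    if (igraph::ecount(g)) {
        tab <- sort(table(igraph::E(g)$mdb), decreasing = TRUE)
        cat("  top MDBs:",
            paste(utils::head(names(tab), 5), utils::head(tab, 5),
                  sep = ":", collapse = " "), "\n")
    }
})

#' Accessors for MassDiffNet
#'
#' @name MassDiffNet-accessors
#' @rdname MassDiffNet-accessors
NULL

#' Export / import a mass-difference network
#'
#' \code{exportNetwork} writes GraphML (Cytoscape-importable; node \code{mass}
#' attribute, edge \code{mdb} and \code{residual_ppm} attributes) or a
#' 4-column edge TSV (\code{from}, \code{to}, \code{mdb},
#' \code{residual_ppm}; lossy for isolated nodes by construction of the
#' format, so the TSV also carries the node table in a sibling file when
#' \code{nodesPath} is given). \code{importNetwork} reads either format back;
#' node and edge sets round-trip losslessly for GraphML.
#'
#' @param net a [MassDiffNet-class].
#' @param path output file.
#' @param format "graphml" or "edge-tsv".
#' @param nodesPath optional node-table TSV (feature id + mass) written next
#'   to an edge TSV so isolated nodes survive the round trip.
#' @return invisibly, \code{path}.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "edge-tsv"),
                          nodesPath = NULL) {
    format <- match.arg(format)
    if (format == "graphml") {
        igraph::write_graph(net@graph, path, format = "graphml")
    } else {
        utils::write.table(edgeTable(net), path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        if (!is.null(nodesPath)) {
            nm <- nodeMasses(net)
            utils::write.table(
                data.frame(feature_id = names(nm),
                           mass = sprintf("%.9f", nm)),
                nodesPath, sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    invisible(path)
}

#' @rdname exportNetwork
#' @param universeSize universe size to record on import (defaults to the
#'   imported node count).
#' @export
importNetwork <- function(path, format = c("graphml", "edge-tsv"),
                          nodesPath = NULL, universeSize = NULL) {
    format <- match.arg(format)
    if (format == "graphml") {
        g <- igraph::read_graph(path, format = "graphml")
        g <- igraph::as_undirected(g, mode = "each")
    } else {
        edges <- utils::read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
        verts <- if (!is.null(nodesPath)) {
            nt <- utils::read.table(nodesPath, header = TRUE, sep = "\t",
                                    colClasses = c("character", "numeric"))
            data.frame(name = nt$feature_id, mass = nt$mass)
        } else {
            ids <- unique(c(edges$from, edges$to))
            data.frame(name = ids, mass = NA_real_)
        }
        g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                           vertices = verts)
    }
    new("MassDiffNet", graph = g,
        universeSize = as.integer(universeSize %||% igraph::vcount(g)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
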