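#' Graphlet orbit counts
#'
#' Counts, for every node, how often it occupies each automorphism orbit
#' (0-14) of the connected 2-, 3- and 4-node graphlets: edge (orbit 0),
#' path of three (1 end, 2 middle), triangle (3), path of four (4 end,
#' 5 middle), claw (6 leaf, 7 center), 4-cycle (8), paw — triangle with a
#' pendant edge (9 pendant, 10 triangle-edge node, 11 hub), diamond
#' (12 degree-2, 13 degree-3) and the complete 4-clique (14). Counts are
#' over induced subgraphs of the simple-graph skeleton (parallel MDB edges
#' collapse for topology), so the orbit-0 column equals the simple degree.
#'
#' Connected subgraphs are enumerated once each with the ESU enumeration
#' scheme and classified by within-subgraph degree sequence; the result is
#' identical to exhaustive enumeration over all node subsets.
#'
#' @param net a [MassDiffNet-class] or an \code{igraph} object.
#' @return integer matrix, nodes x 15, columns \code{o0..o14}.
#' @examples
#' tri <- igraph::make_ring(3)
#' countGraphletOrbits(tri)   # per node: o0 = 2, o3 = 1
#' @export
countGraphletOrbits <- function(net) {
    g <- if (is(net, "MassDiffNet")) net@graph else net
    g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
    n <- igraph::vcount(g)
    counts <- matrix(0L, nrow = n, ncol = 15,
                     dimnames = list(igraph::V(g)$name,
                                     paste0("o", 0:14)))
    if (n == 0) return(counts)
    counts[, "o0"] <- igraph::degree(g)
    if (n < 3) return(counts)
    adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
    A <- matrix(FALSE, n, n)
    el <- igraph::as_edgelist(g, names = FALSE)
    A[el] <- TRUE
    A[el[, 2:1, drop = FALSE]] <- TRUE

    tally3 <- function(s) {
        a <- s[1]; b <- s[2]; d <- s[3]
        m <- A[a, b] + A[a, d] + A[b, d]
        if (m == 2L) {
            degw <- c(A[a, b] + A[a, d], A[a, b] + A[b, d], A[a, d] + A[b, d])
            counts[s[degw == 2L], "o2"] <<- counts[s[degw == 2L], "o2"] + 1L
            counts[s[degw == 1L], "o1"] <<- counts[s[degw == 1L], "o1"] + 1L
        } else counts[s, "o3"] <<- counts[s, "o3"] + 1L
    }
    tally4 <- function(s) {
        sub <- A[s, s]
        degw <- colSums(sub)
        m <- sum(degw) / 2L
        if (m == 3L) {
            if (max(degw) == 3L) {      # claw
                counts[s[degw == 3L], "o7"] <<- counts[s[degw == 3L], "o7"] + 1L
                counts[s[degw == 1L], "o6"] <<- counts[s[degw == 1L], "o6"] + 1L
            } else {                    # path of four
                counts[s[degw == 1L], "o4"] <<- counts[s[degw == 1L], "o4"] + 1L
                counts[s[degw == 2L], "o5"] <<- counts[s[degw == 2L], "o5"] + 1L
            }
        } else if (m == 4L) {
            if (max(degw) == 3L) {      # paw
                counts[s[degw == 1L], "o9"] <<- counts[s[degw == 1L], "o9"] + 1L
                counts[s[degw == 2L], "o10"] <<- counts[s[degw == 2L], "o10"] + 1L
                counts[s[degw == 3L], "o11"] <<- counts[s[degw == 3L], "o11"] + 1L
            } else                      # 4-cycle
                counts[s, "o8"] <<- counts[s, "o8"] + 1L
        } else if (m == 5L) {           # diamond
            counts[s[degw == 2L], "o12"] <<- counts[s[degw == 2L], "o12"] + 1L
            counts[s[degw == 3L], "o13"] <<- counts[s[degw == 3L], "o13"] + 1L
        } else                          # 4-clique
            counts[s, "o14"] <<- counts[s, "o14"] + 1L
    }
    ## ESU: each connected induced subgraph of size 3 and 4 visited once
    extend <- function(sub, ext, root) {
        while (length(ext)) {
            w <- ext[1]
            ext <- ext[-1]
            newSub <- c(sub, w)
            if (length(newSub) == 3L) tally3(newSub)
            if (length(newSub) == 4L) { tally4(newSub); next }
            excl <- adj[[w]]
            excl <- excl[excl > root & !(excl %in% newSub)]
            ## exclusive neighbourhood: not adjacent to the old subgraph
            if (length(excl)) {
                inOld <- vapply(excl, function(u) any(A[u, sub]), logical(1))
                excl <- excl[!inOld]
            }
            extend(newSub, c(ext, excl), root)
        }
    }
    for (v in seq_len(n)) {
        ext <- adj[[v]]
        extend(v, ext[ext > v], v)
    }
    counts
}

## the 11 non-redundant orbits of 2-4-node graphlets (the redundant
## 3, 12, 13, 14 are linear combinations of the others plus degree terms)
.GCD11_ORBITS <- c(0, 1, 2, 4, 5, 6, 7, 8, 9, 10, 11)

#' Graphlet-correlation (GCD-11) features of one network
#'
#' Restricts the orbit-count matrix to the 11 non-redundant orbits of up to
#' 4-node graphlets, appends one all-ones dummy node (so that constant
#' columns never make the correlation undefined), Spearman-correlates the
#' orbit columns (average ranks on ties) and returns the unique off-diagonal
#' entries of the resulting 11 x 11 graphlet correlation matrix as a named
#' 55-vector (optionally 66 with the unit diagonal included). This is the
#' network's topology signature used as one row of the GCD profile matrix.
#'
#' @param counts orbit-count matrix from [countGraphletOrbits()], or a
#'   [MassDiffNet-class] (counted on the fly).
#' @param includeDiagonal logical, append the 11 diagonal entries too.
#' @return named numeric vector of length 55 (or 66); all zeros for an empty
#'   network.
#' @export
gcdFeatures <- function(counts, includeDiagonal = FALSE) {
    if (is(counts, "MassDiffNet")) counts <- countGraphletOrbits(counts)
    orbs <- paste0("o", .GCD11_ORBITS)
    pairNames <- outer(orbs, orbs, paste, sep = "_")
    upper <- upper.tri(pairNames, diag = includeDiagonal)
    nm <- t(pairNames)[t(upper)]   # row-major order o0_o1, o0_o2, ...
    if (nrow(counts) == 0)
        return(stats::setNames(numeric(length(nm)), nm))
    M <- rbind(counts[, orbs, drop = FALSE], 1)
    S <- suppressWarnings(stats::cor(M, method = "spearman"))
    S[is.na(S)] <- 0
    stats::setNames(t(S)[t(upper)], nm)
}

#' @describeIn graph-profiles graphlet-correlation profile: one
#'   [gcdFeatures()] vector per sample (55 orbit-pair columns).
#' @param includeDiagonal see [gcdFeatures()].
#' @export
gcdProfile <- function(smdins, includeDiagonal = FALSE) {
    rows <- lapply(smdins, function(net)
        gcdFeatures(countGraphletOrbits(net), includeDiagonal))
    out <- do.call(rbind, rows)
    rownames(out) <- names(smdins)
    out
}
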