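## Independent brute-force oracles and toy-object builders shared by the
## suite. Everything here is deliberately naive: full pair scans, all-subset
## enumeration, textbook path-count DP — never the package's own algorithms.

## a MassDiffNet from an explicit edge table (for metric unit tests)
toyNet <- function(edges, masses, universe = length(masses)) {
    if (is.null(names(masses)) && length(masses))
        names(masses) <- paste0("n", seq_along(masses))
    if (!length(masses)) names(masses) <- character(0)
    if (!nrow(edges)) {
        g <- igraph::make_empty_graph(directed = FALSE) +
            igraph::vertices(names(masses), mass = unname(masses))
    } else {
        if (is.null(edges$mdb)) edges$mdb <- "CH2"
        if (is.null(edges$residual_ppm)) edges$residual_ppm <- 0
        g <- igraph::graph_from_data_frame(
            edges, directed = FALSE,
            vertices = data.frame(name = names(masses), mass = unname(masses)))
    }
    new("MassDiffNet", graph = g, universeSize = as.integer(universe))
}

## simple undirected igraph from an edge matrix over 1..n
toyGraph <- function(n, edgeMat) {
    igraph::make_empty_graph(n, directed = FALSE) +
        igraph::edges(t(edgeMat))
}

## O(n^2 * |MDB|) full scan for the edge set (vectorized over pairs)
bruteEdges <- function(masses, mdbs = defaultMDBs(), ppm = 1) {
    if (is.null(names(masses)))
        names(masses) <- paste0("n", seq_along(masses))
    dm <- mdbMasses(mdbs)
    D <- abs(outer(masses, masses, "-"))
    R <- outer(masses, masses, pmax)
    out <- list()
    for (b in seq_along(dm)) {
        hit <- which(abs(D - dm[b]) <= ppm * 1e-6 * R, arr.ind = TRUE)
        hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
        if (nrow(hit))
            out[[length(out) + 1L]] <- data.frame(
                from = names(masses)[hit[, 1]], to = names(masses)[hit[, 2]],
                mdb = names(dm)[b], stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(from = character(0), to = character(0),
                          mdb = character(0)))
    res <- do.call(rbind, out)
    a <- pmin(res$from, res$to); b2 <- pmax(res$from, res$to)
    res$from <- a; res$to <- b2
    res[order(res$from, res$to, res$mdb), , drop = FALSE]
}

edgeKey <- function(df) sort(paste(df$from, df$to, df$mdb))

## all-subset graphlet-orbit oracle: enumerate every 3- and 4-node subset,
## keep the connected ones, classify by within-subset degrees
bruteOrbits <- function(g) {
    g <- igraph::simplify(g)
    n <- igraph::vcount(g)
    A <- matrix(FALSE, n, n)
    el <- igraph::as_edgelist(g, names = FALSE)
    A[el] <- TRUE; A[el[, 2:1, drop = FALSE]] <- TRUE
    counts <- matrix(0L, n, 15, dimnames = list(igraph::V(g)$name,
                                                paste0("o", 0:14)))
    counts[, "o0"] <- igraph::degree(g)
    if (n >= 3) {
        for (s in utils::combn(n, 3, simplify = FALSE)) {
            degw <- colSums(A[s, s])
            m <- sum(degw) / 2
            if (m < 2 || any(degw == 0)) next
            if (m == 2) {
                counts[s[degw == 2], "o2"] <- counts[s[degw == 2], "o2"] + 1L
                counts[s[degw == 1], "o1"] <- counts[s[degw == 1], "o1"] + 1L
            } else counts[s, "o3"] <- counts[s, "o3"] + 1L
        }
    }
    if (n >= 4) {
        for (s in utils::combn(n, 4, simplify = FALSE)) {
            degw <- colSums(A[s, s])
            m <- sum(degw) / 2
            if (m < 3 || any(degw == 0)) next
            if (m == 3) {
                if (max(degw) == 3) {
                    counts[s[degw == 3], "o7"] <- counts[s[degw == 3], "o7"] + 1L
                    counts[s[degw == 1], "o6"] <- counts[s[degw == 1], "o6"] + 1L
                } else {
                    counts[s[degw == 1], "o4"] <- counts[s[degw == 1], "o4"] + 1L
                    counts[s[degw == 2], "o5"] <- counts[s[degw == 2], "o5"] + 1L
                }
            } else if (m == 4) {
                if (max(degw) == 3) {
                    counts[s[degw == 1], "o9"] <- counts[s[degw == 1], "o9"] + 1L
                    counts[s[degw == 2], "o10"] <- counts[s[degw == 2], "o10"] + 1L
                    counts[s[degw == 3], "o11"] <- counts[s[degw == 3], "o11"] + 1L
                } else counts[s, "o8"] <- counts[s, "o8"] + 1L
            } else if (m == 5) {
                counts[s[degw == 2], "o12"] <- counts[s[degw == 2], "o12"] + 1L
                counts[s[degw == 3], "o13"] <- counts[s[degw == 3], "o13"] + 1L
            } else counts[s, "o14"] <- counts[s, "o14"] + 1L
        }
    }
    counts
}

## hand-rolled BFS distances (adjacency-list queue), independent of igraph
bruteDistances <- function(g) {
    n <- igraph::vcount(g)
    adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
    D <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        d <- rep(Inf, n); d[s] <- 0
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            for (u in adj[[v]]) if (!is.finite(d[u])) {
                d[u] <- d[v] + 1
                queue <- c(queue, u)
            }
        }
        D[s, ] <- d
    }
    D
}

## textbook path-count betweenness: sigma(s,t) by DP over BFS layers,
## sigma(s,t|v) = sigma(s,v) * sigma(v,t) when v lies on a geodesic
bruteBetweenness <- function(g) {
    g <- igraph::simplify(g)
    n <- igraph::vcount(g)
    D <- bruteDistances(g)
    adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
    sigma <- matrix(0, n, n)
    for (s in seq_len(n)) {
        sigma[s, s] <- 1
        for (v in order(D[s, ])) {
            if (v == s || !is.finite(D[s, v])) next
            pre <- adj[[v]][D[s, adj[[v]]] == D[s, v] - 1]
            sigma[s, v] <- sum(sigma[s, pre])
        }
    }
    bc <- numeric(n)
    for (v in seq_len(n)) {
        tot <- 0
        for (s in seq_len(n - 1)) for (t in (s + 1):n) {
            if (s == v || t == v || !is.finite(D[s, t])) next
            if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
                D[s, v] + D[v, t] == D[s, t])
                tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
        bc[v] <- tot
    }
    bc
}

## component-corrected closeness from brute-force BFS distances
bruteCloseness <- function(g) {
    g <- igraph::simplify(g)
    n <- igraph::vcount(g)
    if (n == 0) return(numeric(0))
    D <- bruteDistances(g)
    vapply(seq_len(n), function(v) {
        reach <- which(is.finite(D[, v]) & seq_len(n) != v)
        nv <- length(reach) + 1
        if (nv < 2 || n < 2) return(0)
        ((nv - 1) / (n - 1)) * ((nv - 1) / sum(D[reach, v]))
    }, numeric(1))
}

## random sparse test graph
randomGraph <- function(n, p, seed) {
    withSeed(seed, igraph::sample_gnp(n, p, directed = FALSE))
}

## small aligned matrix with controllable missingness
toyMatrix <- function(values, masses, labels) {
    MassFeatureSet(values, masses, labels)
}
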