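## small named networks used across the metric tests
starNet <- function() toyNet(data.frame(from = "c0", to = c("l1", "l2", "l3")),
                             c(c0 = 1, l1 = 2, l2 = 3, l3 = 4))
pathNet <- function() toyNet(data.frame(from = c("a", "b"), to = c("b", "c")),
                             c(a = 1, b = 2, c = 3))

test_that("degree profiles report per-sample degrees over the universe", {
    smd <- list(s1 = pathNet(), s2 = starNet())
    uni <- c("a", "b", "c", "c0", "l1", "l2", "l3", "zz")
    dp <- degreeProfile(smd, uni)
    expect_equal(dp["s1", c("a", "b", "c")], c(a = 1, b = 2, c = 1))
    expect_equal(unname(dp["s1", "zz"]), 0)
    expect_equal(unname(dp["s2", "c0"]), 3)
    ## parallel MDB edges each count toward degree
    multi <- toyNet(data.frame(from = c("a", "a"), to = c("b", "b"),
                               mdb = c("CH2", "O")), c(a = 1, b = 2))
    expect_equal(unname(degreeProfile(list(s = multi), c("a", "b"))[1, ]),
                 c(2, 2))
    expect_error(degreeProfile(smd, c("a", "b")), "universe")
})

test_that("betweenness matches the path-count definition on toys and random graphs", {
    smd <- list(s1 = starNet(), s2 = pathNet())
    bp <- betweennessProfile(smd, c("a","b","c","c0","l1","l2","l3"))
    expect_equal(unname(bp["s1", c("c0", "l1")]), c(3, 0)) # 3 leaf pairs
    expect_equal(unname(bp["s2", "b"]), 1)                 # single (a,c) pair
    tri <- toyNet(data.frame(from = c("a","b","c"), to = c("b","c","a")),
                  c(a = 1, b = 2, c = 3))
    expect_true(all(betweennessProfile(list(s = tri), c("a","b","c")) == 0))
    for (s in 1:6) {
        g <- randomGraph(25, 0.12, 300 + s)
        igraph::V(g)$name <- paste0("v", 1:25)
        igraph::V(g)$mass <- 1:25
        net <- new("MassDiffNet", graph = g, universeSize = 25L)
        got <- betweennessProfile(list(x = net), igraph::V(g)$name)[1, ]
        expect_equal(unname(got), bruteBetweenness(g), tolerance = 1e-9,
                     info = paste("seed", s))
    }
})

test_that("closeness applies the component correction exactly", {
    smd <- list(s1 = starNet(), s2 = pathNet())
    cp <- closenessProfile(smd, c("a","b","c","c0","l1","l2","l3"))
    expect_equal(unname(cp["s1", c("c0", "l1")]), c(1, 0.6))
    expect_equal(unname(cp["s2", c("b", "a")]), c(1, 2/3))
    ## two disjoint edges: n = 2, N = 4 -> every node (1/3)*(1/1)
    two <- toyNet(data.frame(from = c("a", "c"), to = c("b", "d")),
                  c(a = 1, b = 2, c = 3, d = 4))
    expect_equal(unname(closenessProfile(list(s = two),
                                         c("a","b","c","d"))[1, ]),
                 rep(1/3, 4))
    for (s in 1:6) {
        g <- randomGraph(22, 0.1, 500 + s)
        igraph::V(g)$name <- paste0("v", 1:22)
        igraph::V(g)$mass <- 1:22
        net <- new("MassDiffNet", graph = g, universeSize = 22L)
        got <- closenessProfile(list(x = net), igraph::V(g)$name)[1, ]
        expect_equal(unname(got), bruteCloseness(g), tolerance = 1e-12,
                     info = paste("seed", s))
    }
})

test_that("MDB impact rows are edge fractions summing to one", {
    mdbs <- defaultMDBs()
    net <- toyNet(data.frame(from = c("a","a","a","b"),
                             to = c("b","c","d","c"),
                             mdb = c("CH2","CH2","CH2","O")),
                  c(a = 1, b = 2, c = 3, d = 4))
    mp <- mdbiProfile(list(s1 = net, s2 = pathNet()), mdbs)
    expect_equal(unname(mp["s1", c("CH2", "O")]), c(0.75, 0.25))
    expect_equal(sum(mp["s1", ]), 1)
    ## a single edge gives weight 1 to its MDB
    single <- toyNet(data.frame(from = "a", to = "b", mdb = "SO3"),
                     c(a = 1, b = 2))
    expect_equal(unname(mdbiProfile(list(s = single), mdbs)[1, "SO3"]), 1)
    ## empty graph: all-zero row, not NaN
    empty <- toyNet(data.frame(from = character(0), to = character(0)),
                    numeric(0), universe = 0)
    expect_true(all(mdbiProfile(list(s = empty), mdbs) == 0))
})

test_that("node importance is a normalized gini vector that finds the marker", {
    ## one feature's degree separates the classes perfectly
    withSeed(11, {
        n <- 30
        prof <- cbind(marker = rep(c(0, 4), each = n / 2) + runif(n, 0, .2),
                      noise1 = runif(n, 0, 4), noise2 = runif(n, 0, 4))
    })
    labs <- rep(c("A", "B"), each = 15)
    imp <- nodeImportanceFromDegree(prof, labs, seed = 5)
    expect_equal(sum(imp), 1)
    expect_equal(names(which.max(imp)), "marker")
    expect_error(nodeImportanceFromDegree(prof, rep("A", 30)), "two classes")
    ## degenerate constant profiles fall back to uniform weights
    flat <- matrix(1, 10, 3, dimnames = list(NULL, c("x", "y", "z")))
    expect_equal(unname(nodeImportanceFromDegree(flat, rep(c("A","B"), 5),
                                                 seed = 1)),
                 rep(1/3, 3))
})

test_that("weighted MDB impact reweights edges by endpoint importance", {
    mdbs <- defaultMDBs()
    net <- toyNet(data.frame(from = c("a", "c"), to = c("b", "d"),
                             mdb = c("CH2", "O")),
                  c(a = 1, b = 2, c = 3, d = 4))
    imp <- c(a = 0.3, b = 0.1, c = 0.05, d = 0.05)
    wp <- wmdbiProfile(list(s = net), mdbs, imp)
    expect_equal(unname(wp[1, c("CH2", "O")]), c(0.8, 0.2))
    expect_equal(sum(wp), 1)
    ## uniform importances reduce WMDBI to MDBI
    uni <- stats::setNames(rep(0.25, 4), c("a","b","c","d"))
    expect_equal(wmdbiProfile(list(s = net), mdbs, uni),
                 mdbiProfile(list(s = net), mdbs))
    ## all-zero weights fall back to the MDBI row
    zero <- stats::setNames(rep(0, 4), c("a","b","c","d"))
    expect_equal(wmdbiProfile(list(s = net), mdbs, zero),
                 mdbiProfile(list(s = net), mdbs))
})

test_that("profile matrices are row-permutation equivariant", {
    withSeed(9, {
        masses <- stats::setNames(runif(50, 80, 500), sprintf("m%02d", 1:50))
        masses[1:15] <- masses[16:30] + 14.015650
        present <- replicate(4, sample(names(masses), 30), simplify = FALSE)
    })
    net <- buildMDiN(masses)
    smd <- lapply(stats::setNames(present, paste0("s", 1:4)),
                  function(p) deriveSMDiN(net, p))
    dp <- degreeProfile(smd, names(masses))
    perm <- c("s3", "s1", "s4", "s2")
    dpPerm <- degreeProfile(smd[perm], names(masses))
    expect_equal(dpPerm, dp[perm, ])
})
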