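## Build a small synthetic site table: nCopies rigid copies of a compact
## arrangement (signature 1D1G1L1Q) per structure, optionally plus one
## strongly deformed conformer.
compactDGLQ <- function() rbind(c(-3, 0, 0), c(3, 0, 0), c(0, 3, 0),
                                c(0, -1.3, 2.8))
elongDGLQ <- function() rbind(c(3.87, -1.45, 0.19), c(5.59, -1.23, -1.24),
                              c(-5.09, 0.87, 1.38), c(-5.19, -0.15, -1.16))

test_that("the RMSD threshold splits conformers into separate clusters", {
    base <- mkSiteRow(c("D", "G", "L", "Q"), ca = compactDGLQ(),
                      id = "p1:A:1", structure = "p1")
    sites <- rbind(base,
                   transformSiteRow(base, theta = 0.9,
                                    shift = c(12, 0, 0), id = "p2:A:1",
                                    structure = "p2"),
                   transformSiteRow(base, theta = 2.2,
                                    shift = c(0, 15, 0), id = "p3:A:1",
                                    structure = "p3"),
                   mkSiteRow(c("D", "G", "L", "Q"), ca = elongDGLQ(),
                             id = "p4:A:1", structure = "p4"))
    cl <- clusterSites(sites, rmsdt = 4.5)
    expect_equal(sort(cl$clusters$nSites, decreasing = TRUE), c(3L, 1L))
    expect_equal(cl$clusters$clusterId, c("1D1G1L1Q-1", "1D1G1L1Q-2"))
    expect_equal(cl$clusters$referenceSiteId[1], "p1:A:1")
    expect_error(clusterSites(sites, rmsdt = 0), "positive")
})

test_that("an infinite threshold collapses each signature into one cluster", {
    s1 <- mkSiteRow(c("D", "G", "L", "Q"), ca = compactDGLQ(),
                    id = "a:A:1", structure = "a")
    s2 <- mkSiteRow(c("D", "G", "L", "Q"), ca = elongDGLQ(),
                    id = "b:A:1", structure = "b")
    s3 <- mkSiteRow(c("C", "C", "C", "H"), ca = compactDGLQ(),
                    id = "a:A:2", structure = "a", gridId = 2L)
    cl <- clusterSites(rbind(s1, s2, s3), rmsdt = Inf)
    expect_equal(nrow(cl$clusters), 2L)
    expect_equal(sort(cl$clusters$signature), c("1D1G1L1Q", "3C1H"))
})

test_that("greedy clustering satisfies the replay-verification contract", {
    set.seed(61)
    sites <- list()
    n <- 0L
    for (p in 1:5) for (copy in 1:2) {
        conf <- if (runif(1) < 0.5) compactDGLQ() else elongDGLQ()
        n <- n + 1L
        sites[[n]] <- transformSiteRow(
            mkSiteRow(c("D", "G", "L", "Q"),
                      ca = conf + matrix(rnorm(12, 0, 0.3), 4),
                      id = sprintf("p%d:A:%d", p, copy),
                      structure = sprintf("p%d", p), gridId = copy),
            theta = runif(1, 0, 2 * pi), shift = runif(3, -20, 20))
    }
    for (p in 1:5) for (copy in 1:2) {
        conf <- compactDGLQ() + matrix(rnorm(12, 0, 0.3), 4)
        n <- n + 1L
        sites[[n]] <- transformSiteRow(
            mkSiteRow(c("C", "C", "H", "S"), ca = conf,
                      id = sprintf("p%d:A:%d", p, copy + 10),
                      structure = sprintf("p%d", p), gridId = copy + 10L),
            theta = runif(1, 0, 2 * pi), shift = runif(3, -20, 20))
    }
    sites <- do.call(rbind, sites)
    cl <- clusterSites(sites, rmsdt = 2)
    expect_true(verifyClusteringReplay(sites, cl, rmsdt = 2))
    ## determinism: identical input order gives identical assignments
    cl2 <- clusterSites(sites, rmsdt = 2)
    expect_identical(cl$members$clusterId, cl2$members$clusterId)
    expect_identical(cl$clusters$clusterId, cl2$clusters$clusterId)
})

test_that("a single-site run produces the minimal four-node graph", {
    s <- mkSiteRow(c("D", "G", "L", "Q"), ca = compactDGLQ(),
                   id = "x:A:1", structure = "x")
    g <- buildPatternGraph("x", s, clusterSites(s, 4.5))
    ig <- g@graph
    expect_equal(sort(unique(igraph::V(ig)$type)),
                 c("CLUSTER", "PATTERN", "PROTEIN", "SITE"))
    expect_equal(igraph::vcount(ig), 4L)
    expect_equal(igraph::ecount(ig), 3L)
    expect_equal(sort(igraph::E(ig)$type),
                 c("CLUSTER_IN_PATTERN", "PATTERN_IN_PROTEIN",
                   "SITE_IN_CLUSTER"))
})

test_that("edge counts obey the graph identities on a random fixture", {
    set.seed(67)
    sites <- list()
    for (p in 1:4) {
        base <- transformSiteRow(
            mkSiteRow(c("D", "G", "L", "Q"), ca = compactDGLQ(),
                      id = sprintf("p%d:A:1", p),
                      structure = sprintf("p%d", p)),
            theta = runif(1, 0, 6), shift = runif(3, -10, 10))
        sites[[length(sites) + 1L]] <- base
        if (p <= 2)
            sites[[length(sites) + 1L]] <- mkSiteRow(
                c("C", "C", "C", "H"), ca = elongDGLQ(),
                id = sprintf("p%d:A:2", p),
                structure = sprintf("p%d", p), gridId = 2L)
    }
    sites <- do.call(rbind, sites)
    cl <- clusterSites(sites, rmsdt = 3)
    g <- buildPatternGraph(paste0("p", 1:5), sites, cl)  # p5 has no sites
    ig <- g@graph
    tab <- table(igraph::E(ig)$type)
    expect_equal(unname(tab["SITE_IN_CLUSTER"]), nrow(sites))
    expect_equal(unname(tab["CLUSTER_IN_PATTERN"]), nrow(g@clusters))
    expect_equal(unname(tab["PATTERN_IN_PROTEIN"]), sum(g@patterns$inProt))
    ## every SITE has exactly one outgoing SITE_IN_CLUSTER edge
    siteV <- igraph::V(ig)[igraph::V(ig)$type == "SITE"]
    expect_true(all(igraph::degree(ig, siteV, mode = "out") == 1))
    ## conservation identities
    expect_equal(sum(g@patterns$totalSites), nrow(sites))
    expect_equal(sum(g@clusters$nSites), nrow(sites))
    expect_true(all(g@patterns$inProt + g@patterns$notIn == 5))
})

test_that("coverage percentages follow the published formulas", {
    expect_equal(pcv(44, 46), 95.7)
    expect_equal(pcv(10, 10), 100.0)
    expect_equal(pcv(8, 10), 80.0)
    expect_equal(ccv(3, 3), 100.0)
    expect_equal(ccv(1, 3), 33.3)
    expect_equal(ccv(1, 1), 100.0)
    expect_error(pcv(5, 4))
    expect_error(ccv(0, 3))
})

test_that("pattern ranking filters by minimum coverage and sorts by PCv then signature", {
    set.seed(71)
    sites <- rbind(
        mkSiteRow(c("D", "G", "L", "Q"), ca = compactDGLQ(),
                  id = "p1:A:1", structure = "p1"),
        transformSiteRow(mkSiteRow(c("D", "G", "L", "Q"),
                                   ca = compactDGLQ(), id = "p2:A:1",
                                   structure = "p2"), theta = 1),
        mkSiteRow(c("C", "C", "C", "H"), ca = compactDGLQ(),
                  id = "p1:A:2", structure = "p1", gridId = 2L))
    g <- buildPatternGraph(c("p1", "p2"), sites, clusterSites(sites, 4.5))
    all <- rankPatterns(g, mc = 0)
    expect_equal(nrow(all), 2L)
    expect_equal(all$signature[1], "1D1G1L1Q")   # higher PCv first
    filtered <- rankPatterns(g, mc = 80)
    expect_equal(nrow(filtered), sum(all$pcv >= 80))
    expect_equal(filtered$signature, "1D1G1L1Q")
    ## regex query layer
    expect_equal(queryPatterns(g, "^3C")$signature, "3C1H")
})

test_that("graph exports can be re-read and reproduce the statistics", {
    sites <- rbind(
        mkSiteRow(c("D", "G", "L", "Q"), ca = compactDGLQ(),
                  id = "p1:A:1", structure = "p1"),
        transformSiteRow(mkSiteRow(c("D", "G", "L", "Q"),
                                   ca = compactDGLQ(), id = "p2:A:1",
                                   structure = "p2"), theta = 0.5))
    g <- buildPatternGraph(c("p1", "p2", "p3"), sites,
                           clusterSites(sites, 4.5))
    fml <- tempfile(fileext = ".graphml")
    fjs <- tempfile(fileext = ".json")
    exportGraphML(g, fml)
    exportGraphJSON(g, fjs)
    re <- igraph::read_graph(fml, format = "graphml")
    expect_equal(igraph::vcount(re), igraph::vcount(g@graph))
    expect_equal(igraph::ecount(re), igraph::ecount(g@graph))
    js <- jsonlite::read_json(fjs, simplifyVector = TRUE)
    expect_equal(js$patterns$pcv, g@patterns$pcv)
    ## recompute PCv from the exported member table alone
    inProt <- length(unique(js$members$structureId[
        js$members$signature == "1D1G1L1Q"]))
    expect_equal(round(100 * inProt / js$nSubmitted, 1),
                 js$patterns$pcv[js$patterns$signature == "1D1G1L1Q"])
})
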