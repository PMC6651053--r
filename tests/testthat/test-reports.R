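discoveryToy <- function(nStruct = 2, seed = 19) {
    tpl <- motifTemplate(c("C", "H", "L", "S"),
                         ca = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
                                    c(1.5, 1.5, 2.5)))
    set <- makeStructures(plantSpec(tpl, seed = seed), nStruct)
    lapply(names(set), function(id) readPDB(set[[id]], structureId = id))
}

test_that("two identical toy structures give one pattern at full coverage", {
    ps <- discoveryToy(1)
    two <- list(ps[[1]], {
        cp <- ps[[1]]; cp@structureId <- "copy"; cp
    })
    run <- runDiscovery(two, st = 1.5, rt = 4, rmsdt = 2)
    pat <- rankPatterns(run)
    expect_equal(nrow(pat), 1L)
    expect_equal(pat$pcv, 100)
    expect_equal(pat$nClusters, 1L)
    expect_equal(pat$maxClusterPct, 100)
    expect_equal(clusterTable(run)$ccv, 100)
})

test_that("backbone-only structures stay in the denominator as NotIn", {
    ps <- discoveryToy(2)
    bb <- readPDB(backboneOnlyPDB(6), structureId = "lowres")
    run <- runDiscovery(c(ps, list(bb)), st = 1.5, rt = 4, rmsdt = 2)
    expect_equal(length(run@structureIds), 3L)
    pat <- patternTable(run)
    expect_equal(pat$inProt, 2L)
    expect_equal(pat$notIn, 1L)
    expect_equal(pat$pcv, pcv(2, 3))
    ## recount from the exported site table: no sites from the low-res one
    expect_false("lowres" %in% siteTable(run)$structureId)
})

test_that("written tables are self-consistent with the JSON graph export", {
    run <- runDiscovery(discoveryToy(3), st = 1.5, rt = 4, rmsdt = 2)
    out <- file.path(tempdir(), "p3dout")
    writeResults(run, out)
    expect_true(all(file.exists(file.path(out,
        c("patterns.tsv", "patterns.json", "clusters.tsv",
          "clusters.json", "sites.tsv", "sites.json", "graph.graphml",
          "graph.json")))))
    pat <- utils::read.delim(file.path(out, "patterns.tsv"))
    js <- jsonlite::read_json(file.path(out, "graph.json"),
                              simplifyVector = TRUE)
    for (i in seq_len(nrow(pat))) {
        sig <- pat$signature[i]
        inProt <- length(unique(
            js$sites$structureId[js$sites$signature == sig]))
        expect_equal(pat$inProt[i], inProt)
        expect_equal(pat$pcv[i], round(100 * inProt / js$nSubmitted, 1))
        expect_equal(pat$totalSites[i], sum(js$sites$signature == sig))
    }
    unlink(out, recursive = TRUE)
})

test_that("repeated runs on the same inputs are identical", {
    a <- runDiscovery(discoveryToy(3), st = 1.5, rt = 4, rmsdt = 2)
    b <- runDiscovery(discoveryToy(3), st = 1.5, rt = 4, rmsdt = 2)
    expect_identical(siteTable(a)$siteId, siteTable(b)$siteId)
    expect_identical(clusterTable(a), clusterTable(b))
    expect_identical(patternTable(a), patternTable(b))
})

test_that("the sequence view of a one-site cluster lists its residues", {
    run <- runDiscovery(discoveryToy(1), st = 1.5, rt = 4, rmsdt = 2)
    cid <- clusterTable(run)$clusterId[1]
    v <- clusterSequenceView(run, cid)
    expect_equal(nrow(v), 1L)
    expect_equal(unname(unlist(v[1, c("R1", "R2", "R3", "R4")])),
                 c("C1", "H2", "L3", "S4"))
    expect_error(clusterSequenceView(run, "nope-1"), "unknown cluster")
})

test_that("sequence view columns follow the superposition mapping, not sequence order", {
    ## second structure carries the same geometry with its two leucine
    ## positions exchanged in the sequence numbering
    ca <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
    s1 <- mkSiteRow(c("L", "L", "C", "H"), ca = ca, id = "p1:A:1",
                    structure = "p1")
    s2 <- mkSiteRow(c("L", "L", "C", "H"), ca = ca[c(2, 1, 3, 4), ],
                    id = "p2:A:1", structure = "p2",
                    resno = c(10, 20, 30, 40))
    sites <- rbind(s1, s2)
    g <- buildPatternGraph(c("p1", "p2"), sites, clusterSites(sites, 2))
    v <- clusterSequenceView(g, "1C1H2L-1")
    ## reference row in plain order
    expect_equal(unname(unlist(v[1, c("R1", "R2", "R3", "R4")])),
                 c("L1", "L2", "C3", "H4"))
    ## member row: column 1 must hold the residue superposing onto L1,
    ## which is the second leucine (resno 20) of the member site
    expect_equal(unname(unlist(v[2, c("R1", "R2")])), c("L20", "L10"))
})

test_that("superposed cluster export round-trips coordinates and RMSDs", {
    tpl <- motifTemplate(c("C", "H", "L", "S"),
                         ca = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
                                    c(1.5, 1.5, 2.5)))
    set <- makeStructures(plantSpec(tpl, jitterSd = 0.3, seed = 23), 4)
    ps <- lapply(names(set), function(id) readPDB(set[[id]],
                                                  structureId = id))
    run <- runDiscovery(ps, st = 1.5, rt = 4, rmsdt = 2)
    cid <- clusterTable(run)$clusterId[1]
    mem <- memberTable(run)
    mem <- mem[mem$clusterId == cid, ]
    f <- tempfile(fileext = ".pdb")
    writeSuperposedCluster(run, cid, f)
    txt <- readLines(f)
    expect_equal(sum(grepl("^MODEL", txt)), nrow(mem))
    ## re-read each model and recompute its RMSD to model 1 directly
    ends <- which(grepl("^ENDMDL", txt))
    starts <- which(grepl("^MODEL", txt))
    models <- lapply(seq_along(starts), function(k)
        residueTable(readPDB(txt[(starts[k] + 1):(ends[k] - 1)],
                             structureId = paste0("m", k))))
    refPts <- function(res) rbind(
        as.matrix(res[, c("cax", "cay", "caz")]),
        as.matrix(res[, c("scx", "scy", "scz")]))
    ref <- refPts(models[[1]])
    ## residues are written in correspondence order, so the paired RMSD
    ## without further superposition must reproduce the stored values
    cl <- clusterTable(run)
    refSite <- cl$referenceSiteId[cl$clusterId == cid]
    ordIds <- c(refSite, setdiff(mem$siteId, refSite))
    for (k in seq_along(models)) {
        d <- refPts(models[[k]]) - ref
        got <- sqrt(mean(rowSums(d^2)))
        expect_equal(got, mem$rmsd[match(ordIds[k], mem$siteId)],
                     tolerance = 2e-3)
    }
})

test_that("the C3H1 sequence scan finds exactly the planted motifs", {
    minimal <- paste0("C", strrep("A", 8), "C", strrep("A", 5), "C",
                      strrep("A", 3), "H")
    hit <- scanPrositeC3H1(minimal)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$start, 0L)
    expect_equal(hit$end, nchar(minimal))
    expect_equal(hit$cysHis[[1]], c(1L, 10L, 16L, 20L))
    expect_equal(nrow(scanPrositeC3H1(strrep("A", 60))), 0L)
    ## construction oracle: k planted motifs in random spacer sequence
    set.seed(73)
    for (k in 1:3) {
        spacer <- function(n) paste(sample(setdiff(c(LETTERS[1:20]),
            c("B", "J", "O", "U", "X", "Z", "C", "H")), n,
            replace = TRUE), collapse = "")
        seqs <- paste0(spacer(5),
                       paste(replicate(k, paste0(minimal, spacer(4))),
                             collapse = ""))
        expect_equal(nrow(scanPrositeC3H1(seqs)), k)
    }
})
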