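#' Run the full pattern-discovery pipeline
#'
#' Reads each input structure, drops side-chain-less residues, builds the
#' per-chain grids, enumerates and deduplicates sites, clusters them
#' greedily under the RMSD threshold, unifies everything into the
#' pattern graph and (optionally) writes the result bundle. Structures
#' that parse but yield no usable residues or no sites (for example
#' backbone-only depositions) are kept in the submission denominator and
#' show up through the patterns' NotIn counts; structures that fail to
#' parse are logged and skipped entirely.
#'
#' @param inputs the submitted structures: a character vector of PDB file
#'   paths and/or a list of [ProteinStructure-class] objects.
#' @param st,rt,dt,rmsdt thresholds in angstrom: grid spacing, search
#'   radius, zone displacement, clustering RMSD threshold.
#' @param mc minimum coverage filter in percent for the ranked pattern
#'   table.
#' @param outputDir optional directory; when given, pattern / cluster /
#'   site tables (TSV + JSON), the GraphML and JSON graph exports are
#'   written there.
#' @param verbose emit per-structure progress messages.
#' @return a [PatternGraph-class] with structures attached and the run
#'   parameters recorded; use [rankPatterns()], [clusterSequenceView()],
#'   [writeSuperposedCluster()] and [queryPatterns()] on it.
#' @examples
#' tpl <- motifTemplate(c("D", "G", "L", "Q"),
#'                      ca = rbind(c(0, 0, 0), c(3, 0, 0),
#'                                 c(0, 3, 0), c(0, 0, 3)))
#' pdbs <- makeStructures(plantSpec(tpl, seed = 7), 2)
#' ps <- lapply(seq_along(pdbs), function(i)
#'     readPDB(pdbs[[i]], structureId = paste0("toy", i)))
#' run <- runDiscovery(ps, st = 1.5, rt = 4, rmsdt = 2)
#' rankPatterns(run)
#' @export
runDiscovery <- function(inputs, st, rt, dt = 0, rmsdt, mc = 0,
                         outputDir = NULL, verbose = FALSE) {
    params <- gridParams(st, rt, dt)
    if (!is.numeric(rmsdt) || rmsdt <= 0)
        stop("'rmsdt' must be a positive RMSD threshold")
    if (mc < 0 || mc > 100) stop("'mc' must be a percentage in [0, 100]")
    if (is.character(inputs)) inputs <- as.list(inputs)
    structs <- list()
    for (inp in inputs) {
        ps <- if (is(inp, "ProteinStructure")) inp else
            tryCatch(readPDB(inp), error = function(e) {
                warning("skipping unparseable structure: ",
                        conditionMessage(e), call. = FALSE)
                NULL
            })
        if (!is.null(ps)) structs[[structureId(ps)]] <- ps
    }
    if (length(structs) == 0L)
        stop("no valid structures in the submission")

    allSites <- list()
    info <- list()
    for (id in names(structs)) {
        filtered <- tryCatch(filterSidechainless(structs[[id]]),
                             error = function(e) NULL)
        sites <- if (is.null(filtered)) {
            message("structure '", id,
                    "': no residues with side chains; no detectable patterns")
            .emptySites()
        } else {
            structs[[id]] <- filtered
            suppressMessages(findSites(filtered, params))
        }
        if (verbose)
            message(sprintf("%s: %d residues, %d deduplicated site(s)", id,
                            if (is.null(filtered)) 0L
                            else nrow(filtered@residues), nrow(sites)))
        allSites[[id]] <- sites
        info[[id]] <- data.frame(structureId = id,
                                 nResidues = if (is.null(filtered)) 0L
                                             else nrow(filtered@residues),
                                 nSites = nrow(sites),
                                 stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, allSites)
    rownames(sites) <- NULL
    clustering <- clusterSites(sites, rmsdt)
    graph <- buildPatternGraph(structs, sites, clustering,
                               params = list(st = st, rt = rt, dt = dt,
                                             rmsdt = rmsdt, mc = mc))
    if (!is.null(outputDir)) writeResults(graph, outputDir)
    graph
}

#' Write the result bundle of a discovery run
#'
#' Writes the ranked pattern table (filtered at the run's minimum
#' coverage), the cluster table, the site table (TSV and JSON each) and
#' the graph exports (GraphML + JSON) into a directory.
#'
#' @param graph a [PatternGraph-class].
#' @param outputDir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeResults <- function(graph, outputDir) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    mc <- if (!is.null(graph@params$mc)) graph@params$mc else 0
    pat <- rankPatterns(graph, mc)
    utils::write.table(pat, file.path(outputDir, "patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(pat, file.path(outputDir, "patterns.json"),
                         dataframe = "rows", digits = NA)
    utils::write.table(graph@clusters,
                       file.path(outputDir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(graph@clusters,
                         file.path(outputDir, "clusters.json"),
                         dataframe = "rows", digits = NA)
    writeSiteTable(graph@sites, file.path(outputDir, "sites.tsv"))
    writeSiteTable(graph@sites, file.path(outputDir, "sites.json"))
    exportGraphML(graph, file.path(outputDir, "graph.graphml"))
    exportGraphJSON(graph, file.path(outputDir, "graph.json"))
    invisible(outputDir)
}
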