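#' Protein coverage of a pattern
#'
#' \code{PCv = 100 * InProt / nSubmitted}: the percentage of the
#' submitted structures that contain at least one site of a pattern,
#' reported to one decimal. A structure that yields zero sites (for
#' example a backbone-only deposition) still counts in the denominator.
#'
#' @param inProt number of structures containing the pattern.
#' @param nSubmitted number of structures submitted.
#' @return percentage, rounded to one decimal.
#' @examples
#' pcv(44, 46)  # 95.7
#' @export
pcv <- function(inProt, nSubmitted) {
    stopifnot(nSubmitted >= 1, inProt >= 0, inProt <= nSubmitted)
    round(100 * inProt / nSubmitted, 1)
}

#' Cluster coverage within a pattern
#'
#' \code{CCv = 100 * (structures represented in the cluster) /
#' (structures containing the pattern)}: how much of the pattern's
#' protein spread a single conformational cluster accounts for. A
#' pattern present in three structures whose cluster spans one of them
#' has CCv 33.3.
#'
#' @param nClusterProteins distinct structures among the cluster members.
#' @param nPatternProteins distinct structures containing the pattern.
#' @return percentage, rounded to one decimal.
#' @export
ccv <- function(nClusterProteins, nPatternProteins) {
    stopifnot(nPatternProteins >= 1, nClusterProteins >= 1,
              nClusterProteins <= nPatternProteins)
    round(100 * nClusterProteins / nPatternProteins, 1)
}

#' Greedy RMSD-threshold clustering of same-signature sites
#'
#' Sites are processed in deterministic order (structure submission
#' order, then chain, then grid index, then zone). Each site is compared
#' against the reference sites of the existing clusters of its signature,
#' in cluster-creation order, and joins the first cluster whose reference
#' it matches within \code{rmsdt}; otherwise it founds a new cluster and
#' becomes its reference. Permissive thresholds therefore merge
#' conformationally different sites (false positives), strict thresholds
#' split them.
#'
#' @param sites a site table ([findSites()] output, possibly row-bound
#'   across structures in submission order).
#' @param rmsdt clustering RMSD threshold in angstrom (> 0; may be `Inf`,
#'   which yields one cluster per signature).
#' @return list with two data.frames: \code{clusters} (clusterId of the
#'   form \code{"<signature>-<ordinal>"}, signature, referenceSiteId,
#'   nSites) and \code{members} (siteId, clusterId, rmsd to the cluster
#'   reference, exhaustive flag, and list-columns rotation, translation,
#'   mapping holding the stored superposition onto the reference).
#' @export
clusterSites <- function(sites, rmsdt) {
    if (!is.numeric(rmsdt) || length(rmsdt) != 1L || is.na(rmsdt) ||
        rmsdt <= 0)
        stop("'rmsdt' must be a single positive RMSD threshold")
    clusters <- list()   # per cluster: signature, ordinal, refIdx
    bySig <- list()      # signature -> integer cluster indices, creation order
    mem <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
        sig <- sites$signature[i]
        assigned <- NA_integer_
        fit <- NULL
        for (ci in bySig[[sig]]) {
            refIdx <- clusters[[ci]]$refIdx
            cand <- siteRMSD(sites[i, , drop = FALSE],
                             sites[refIdx, , drop = FALSE])
            if (cand@rmsd <= rmsdt) {
                assigned <- ci
                fit <- cand
                break
            }
        }
        if (is.na(assigned)) {
            ordinal <- length(bySig[[sig]]) + 1L
            clusters[[length(clusters) + 1L]] <-
                list(signature = sig, ordinal = ordinal, refIdx = i)
            assigned <- length(clusters)
            bySig[[sig]] <- c(bySig[[sig]], assigned)
            n <- nrow(sites$residues[[i]])
            fit <- new("SuperpositionResult", rmsd = 0, rotation = diag(3),
                       translation = numeric(3), mapping = seq_len(n),
                       exhaustive = TRUE)
        }
        mem[[i]] <- list(cluster = assigned, fit = fit)
    }
    clDf <- data.frame(
        clusterId = vapply(clusters, function(cl)
            paste0(cl$signature, "-", cl$ordinal), ""),
        signature = vapply(clusters, `[[`, "", "signature"),
        ordinal = vapply(clusters, function(cl) cl$ordinal, 0L),
        referenceSiteId = sites$siteId[vapply(clusters, function(cl)
            cl$refIdx, 0L)],
        stringsAsFactors = FALSE)
    memDf <- data.frame(
        siteId = sites$siteId,
        structureId = sites$structureId,
        signature = sites$signature,
        clusterId = clDf$clusterId[vapply(mem, `[[`, 0L, "cluster")],
        rmsd = vapply(mem, function(m) m$fit@rmsd, 0),
        exhaustive = vapply(mem, function(m) m$fit@exhaustive, TRUE),
        stringsAsFactors = FALSE)
    memDf$rotation <- I(lapply(mem, function(m) m$fit@rotation))
    memDf$translation <- I(lapply(mem, function(m) m$fit@translation))
    memDf$mapping <- I(lapply(mem, function(m) m$fit@mapping))
    clDf$nSites <- as.integer(table(memDf$clusterId)[clDf$clusterId])
    list(clusters = clDf, members = memDf)
}

#' Unify sites and clusters into the pattern graph
#'
#' Builds the typed graph of PROTEIN, SITE, CLUSTER and PATTERN nodes
#' joined by SITE_IN_CLUSTER, CLUSTER_IN_PATTERN and PATTERN_IN_PROTEIN
#' edges, and computes every coverage statistic: per pattern InProt,
#' NotIn, PCv, total sites, number of clusters and the best cluster
#' coverage; per cluster InProt and CCv. The pattern node with the most
#' PATTERN_IN_PROTEIN edges is the most conserved 3D-pattern.
#'
#' @param structures the submitted structures: a (named) list of
#'   [ProteinStructure-class] objects and/or a character vector of
#'   structure identifiers (structures with zero sites must be included
#'   so they count in the coverage denominator).
#' @param sites combined site table in submission order.
#' @param clustering result of [clusterSites()].
#' @param params optional list of run parameters stored for reporting.
#' @return a [PatternGraph-class].
#' @export
buildPatternGraph <- function(structures, sites, clustering,
                              params = list()) {
    if (is.character(structures)) {
        ids <- structures
        structs <- list()
    } else {
        structs <- structures
        ids <- vapply(structures, function(s)
            if (is(s, "ProteinStructure")) structureId(s) else as.character(s),
            "")
        names(structs) <- ids
    }
    if (anyDuplicated(ids))
        stop("duplicated structure identifiers in submission")
    if (!all(sites$structureId %in% ids))
        stop("site table references structures not in the submission")
    clusters <- clustering$clusters
    members <- clustering$members
    if (!all(sites$siteId %in% members$siteId) ||
        nrow(members) != nrow(sites))
        stop("internal consistency error: orphan or duplicated site assignments")
    n <- length(ids)

    ## cluster-level statistics
    cProt <- lapply(split(members$structureId, members$clusterId), unique)
    clusters$inProt <- lengths(cProt)[clusters$clusterId]
    ## pattern-level statistics
    pProt <- lapply(split(sites$structureId, sites$signature), unique)
    sigs <- sort(names(pProt))
    patterns <- data.frame(signature = sigs,
                           inProt = lengths(pProt)[sigs],
                           stringsAsFactors = FALSE)
    patterns$notIn <- n - patterns$inProt
    patterns$pcv <- pcv(patterns$inProt, n)
    patterns$totalSites <-
        as.integer(table(sites$signature)[patterns$signature])
    patterns$nClusters <-
        as.integer(table(clusters$signature)[patterns$signature])
    clusters$ccv <- ccv(clusters$inProt,
                        patterns$inProt[match(clusters$signature,
                                              patterns$signature)])
    patterns$maxClusterPct <- vapply(patterns$signature, function(s)
        max(clusters$ccv[clusters$signature == s]), 0)
    rownames(patterns) <- rownames(clusters) <- NULL

    g <- .makeIgraph(ids, sites, clusters, members, patterns, pProt)
    new("PatternGraph", graph = g, structures = structs,
        structureIds = ids, sites = sites, clusters = clusters,
        members = members, patterns = patterns, params = params)
}

.makeIgraph <- function(ids, sites, clusters, members, patterns, pProt) {
    vProt <- paste0("PROTEIN:", ids)
    vSite <- paste0("SITE:", sites$siteId)
    vClus <- paste0("CLUSTER:", clusters$clusterId)
    vPat <- paste0("PATTERN:", patterns$signature)
    vertices <- data.frame(
        name = c(vProt, vSite, vClus, vPat),
        type = c(rep("PROTEIN", length(vProt)), rep("SITE", length(vSite)),
                 rep("CLUSTER", length(vClus)), rep("PATTERN", length(vPat))),
        stringsAsFactors = FALSE)
    eSC <- data.frame(from = paste0("SITE:", members$siteId),
                      to = paste0("CLUSTER:", members$clusterId),
                      type = "SITE_IN_CLUSTER", stringsAsFactors = FALSE)
    eCP <- data.frame(from = paste0("CLUSTER:", clusters$clusterId),
                      to = paste0("PATTERN:", clusters$signature),
                      type = "CLUSTER_IN_PATTERN", stringsAsFactors = FALSE)
    ePP <- do.call(rbind, lapply(names(pProt), function(s)
        data.frame(from = paste0("PATTERN:", s),
                   to = paste0("PROTEIN:", pProt[[s]]),
                   type = "PATTERN_IN_PROTEIN", stringsAsFactors = FALSE)))
    edges <- rbind(eSC, eCP, ePP)
    igraph::graph_from_data_frame(edges, directed = TRUE,
                                  vertices = vertices)
}

#' Rank patterns by protein coverage
#'
#' @param graph a [PatternGraph-class].
#' @param mc minimum coverage filter in percent (0-100): only patterns
#'   with \code{PCv >= mc} are returned.
#' @return data.frame with one row per pattern (signature, inProt, notIn,
#'   pcv, totalSites, nClusters, maxClusterPct), sorted by PCv descending
#'   then signature ascending.
#' @export
rankPatterns <- function(graph, mc = 0) {
    stopifnot(is(graph, "PatternGraph"), mc >= 0, mc <= 100)
    p <- graph@patterns
    p <- p[p$pcv >= mc, , drop = FALSE]
    p <- p[order(-p$pcv, p$signature), , drop = FALSE]
    rownames(p) <- NULL
    p
}

#' Query patterns by a sub-pattern regular expression
#'
#' @param graph a [PatternGraph-class].
#' @param regex regular expression applied to the canonical signature
#'   text, e.g. \code{"^2C.*2H$"}.
#' @param mc minimum coverage filter in percent.
#' @return the matching rows of [rankPatterns()].
#' @export
queryPatterns <- function(graph, regex, mc = 0) {
    p <- rankPatterns(graph, mc)
    p[matchSubpattern(p$signature, regex), , drop = FALSE]
}

#' Export the pattern graph as GraphML
#'
#' @param graph a [PatternGraph-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
exportGraphML <- function(graph, file) {
    igraph::write_graph(graph@graph, file, format = "graphml")
    invisible(file)
}

#' Export the pattern graph as JSON
#'
#' Writes typed node and edge lists (plus the pattern, cluster and site
#' attribute tables) so that every reported statistic can be recomputed
#' from the export.
#'
#' @param graph a [PatternGraph-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
exportGraphJSON <- function(graph, file) {
    g <- graph@graph
    nodes <- data.frame(name = igraph::V(g)$name,
                        type = igraph::V(g)$type, stringsAsFactors = FALSE)
    ed <- igraph::as_data_frame(g, what = "edges")
    mem <- graph@members[, c("siteId", "structureId", "signature",
                             "clusterId", "rmsd", "exhaustive")]
    jsonlite::write_json(
        list(nSubmitted = length(graph@structureIds),
             structures = graph@structureIds,
             nodes = nodes, edges = ed,
             patterns = graph@patterns, clusters = graph@clusters,
             sites = .flattenSites(graph@sites), members = mem,
             params = graph@params),
        file, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    invisible(file)
}
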