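#' @import methods
NULL

#' Grid construction parameters
#'
#' Holds the three geometric thresholds that control site enumeration:
#' the lattice spacing \code{st} (angstrom) between virtual reference
#' coordinates, the search radius \code{rt} (angstrom) within which residues
#' are collected around a reference coordinate, and the displacement
#' \code{dt} (angstrom) used to expand each retained reference coordinate
#' into seven elliptical two-center search zones (\code{dt = 0} disables the
#' expansion and only spherical neighbourhoods are searched).
#'
#' @slot st numeric(1), lattice spacing in angstrom, > 0.
#' @slot rt numeric(1), search radius in angstrom, > 0.
#' @slot dt numeric(1), zone displacement in angstrom, >= 0.
#'
#' @seealso [gridParams()], [buildGrid()], [expandZones()]
#' @exportClass GridParams
setClass("GridParams",
         representation(st = "numeric", rt = "numeric", dt = "numeric"))

setValidity("GridParams", function(object) {
    msg <- character()
    for (s in c("st", "rt", "dt")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (length(msg) == 0L) {
        if (object@st <= 0) msg <- c(msg, "'st' must be > 0")
        if (object@rt <= 0) msg <- c(msg, "'rt' must be > 0")
        if (object@dt < 0)  msg <- c(msg, "'dt' must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Parsed protein structure
#'
#' A protein structure reduced to its standard-amino-acid ATOM records
#' (first model only, alternate location 'A'/blank only) together with a
#' per-residue table of representative points: the alpha carbon and the
#' unweighted centroid of the side-chain heavy atoms (for glycine the
#' centroid is defined as the alpha carbon).
#'
#' @slot structureId character(1), PDB accession or file stem.
#' @slot atoms data.frame of ATOM records (chain, resno, insert, resid,
#'   elety, element, x, y, z, o).
#' @slot residues data.frame with one row per residue: chain, resno,
#'   insert, key, name3, code1, hasSC, cax/cay/caz, scx/scy/scz.
#'
#' @seealso [readPDB()], [filterSidechainless()], [representativePoints()]
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(structureId = "character",
                        atoms = "data.frame",
                        residues = "data.frame"))

setValidity("ProteinStructure", function(object) {
    msg <- character()
    if (length(object@structureId) != 1L || is.na(object@structureId))
        msg <- c(msg, "'structureId' must be a single string")
    r <- object@residues
    need <- c("chain", "resno", "insert", "key", "name3", "code1", "hasSC",
              "cax", "cay", "caz", "scx", "scy", "scz")
    if (!all(need %in% names(r)))
        msg <- c(msg, "residue table is missing required columns")
    else {
        if (nrow(r) == 0L)
            msg <- c(msg, "structure has no standard residues")
        if (anyDuplicated(r$key))
            msg <- c(msg, "(chain, resno, insert) must be unique")
        if (nrow(r) && !all(r$code1 %in% AA1))
            msg <- c(msg, "residue one-letter codes outside the 20 standard amino acids")
    }
    if (length(msg)) msg else TRUE
})

#' Grid of virtual coordinates for one chain
#'
#' The retained virtual reference coordinates of one chain: lattice points
#' (spacing \code{st}) inside the padded bounding box of the chain's
#' representative points that gather at least four residues within the
#' search radius \code{rt}.
#'
#' @slot structureId character(1).
#' @slot chainId character(1).
#' @slot params a [GridParams-class] object.
#' @slot points data.frame with columns gridId, x, y, z, nResidues, sorted
#'   by gridId (lexicographic over the x, y, z lattice steps).
#'
#' @seealso [buildGrid()]
#' @exportClass VirtualGrid
setClass("VirtualGrid",
         representation(structureId = "character",
                        chainId = "character",
                        params = "GridParams",
                        points = "data.frame"))

setValidity("VirtualGrid", function(object) {
    msg <- character()
    p <- object@points
    if (!all(c("gridId", "x", "y", "z", "nResidues") %in% names(p)))
        msg <- c(msg, "points table is missing required columns")
    else {
        if (is.unsorted(p$gridId, strictly = TRUE) && nrow(p) > 1L)
            msg <- c(msg, "grid points must be strictly sorted by gridId")
        if (nrow(p) && any(p$nResidues < 4L))
            msg <- c(msg, "every retained grid point must have >= 4 residues in range")
    }
    if (length(msg)) msg else TRUE
})

#' Result of an optimal rigid-body superposition
#'
#' Rotation, translation, minimised RMSD and (for site comparisons) the
#' type-preserving residue correspondence between the two point sets or
#' sites. The transform maps the first argument onto the second:
#' \code{x' = R x + t}.
#'
#' @slot rmsd numeric(1), angstrom, >= 0.
#' @slot rotation 3x3 proper rotation matrix (det +1).
#' @slot translation numeric(3), angstrom.
#' @slot mapping integer vector; \code{mapping[i] = j} pairs residue i of
#'   the first site with residue j of the second (empty for plain
#'   point-set superpositions).
#' @slot exhaustive logical(1); TRUE when the residue correspondence was
#'   found by exhaustive permutation search, FALSE when the greedy
#'   refinement fallback was used.
#'
#' @seealso [kabsch()], [siteRMSD()]
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
         representation(rmsd = "numeric",
                        rotation = "matrix",
                        translation = "numeric",
                        mapping = "integer",
                        exhaustive = "logical"))

setValidity("SuperpositionResult", function(object) {
    msg <- character()
    if (length(object@rmsd) != 1L || object@rmsd < -1e-9)
        msg <- c(msg, "'rmsd' must be a single non-negative number")
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)))
        msg <- c(msg, "'rotation' must be 3x3")
    else {
        if (max(abs(crossprod(R) - diag(3))) > 1e-6)
            msg <- c(msg, "'rotation' must be orthonormal")
        if (abs(det(R) - 1) > 1e-6)
            msg <- c(msg, "'rotation' must be proper (det +1)")
    }
    if (length(object@translation) != 3L)
        msg <- c(msg, "'translation' must be length 3")
    if (length(msg)) msg else TRUE
})

#' Unified pattern/cluster/site graph
#'
#' The central result container: all sites discovered across the submitted
#' structures, their greedy RMSD-threshold clustering, the per-signature
#' pattern statistics, and the typed graph with PROTEIN, SITE, CLUSTER and
#' PATTERN nodes connected by SITE_IN_CLUSTER, CLUSTER_IN_PATTERN and
#' PATTERN_IN_PROTEIN edges.
#'
#' @slot graph an \pkg{igraph} graph with vertex attribute \code{type} and
#'   edge attribute \code{type}.
#' @slot structures named list of [ProteinStructure-class] objects (may be
#'   empty for graphs rebuilt from exported tables).
#' @slot structureIds character, the submitted structure identifiers
#'   (including structures that yielded zero sites).
#' @slot sites data.frame, one row per deduplicated site.
#' @slot clusters data.frame, one row per cluster (clusterId, signature,
#'   referenceSiteId, nSites, inProt, ccv).
#' @slot members data.frame, one row per site with its cluster assignment,
#'   RMSD to the cluster reference and stored superposition.
#' @slot patterns data.frame, one row per signature (inProt, notIn, pcv,
#'   totalSites, nClusters, maxClusterPct).
#' @slot params list of the run parameters (st, rt, dt, rmsdt, mc).
#'
#' @seealso [buildPatternGraph()], [runDiscovery()], [rankPatterns()]
#' @exportClass PatternGraph
setClass("PatternGraph",
         representation(graph = "ANY",
                        structures = "list",
                        structureIds = "character",
                        sites = "data.frame",
                        clusters = "data.frame",
                        members = "data.frame",
                        patterns = "data.frame",
                        params = "list"))

setValidity("PatternGraph", function(object) {
    msg <- character()
    n <- length(object@structureIds)
    if (n < 1L)
        msg <- c(msg, "at least one submitted structure is required")
    p <- object@patterns
    if (nrow(p)) {
        if (!isTRUE(all(p$inProt + p$notIn == n)))
            msg <- c(msg, "inProt + notIn must equal the number of submitted structures")
    }
    if (nrow(object@members) != nrow(object@sites))
        msg <- c(msg, "every site must have exactly one cluster assignment")
    if (length(msg)) msg else TRUE
})
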