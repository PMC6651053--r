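#' @rdname ProteinStructure-class
#' @param x a \code{ProteinStructure} (or other object with an identifier).
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname VirtualGrid-class
#' @param x a \code{VirtualGrid}.
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))

#' @rdname PatternGraph-class
#' @param x a \code{PatternGraph}.
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname PatternGraph-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname PatternGraph-class
#' @export
setGeneric("patternTable", function(x) standardGeneric("patternTable"))

#' @rdname PatternGraph-class
#' @export
setGeneric("memberTable", function(x) standardGeneric("memberTable"))

setMethod("structureId", "ProteinStructure", function(x) x@structureId)

setMethod("chainIds", "ProteinStructure",
          function(x) unique(x@residues$chain))

setMethod("residueTable", "ProteinStructure", function(x) x@residues)

setMethod("gridPoints", "VirtualGrid", function(x) x@points)

setMethod("siteTable", "PatternGraph", function(x) x@sites)

setMethod("clusterTable", "PatternGraph", function(x) x@clusters)

setMethod("patternTable", "PatternGraph", function(x) x@patterns)

setMethod("memberTable", "PatternGraph", function(x) x@members)

setMethod("show", "ProteinStructure", function(object) {
    r <- object@residues
    cat("ProteinStructure '", object@structureId, "': ",
        nrow(r), " residues in ", length(unique(r$chain)), " chain(s) [",
        paste(unique(r$chain), collapse = ","), "], ",
        nrow(object@atoms), " atoms\n", sep = "")
})

setMethod("show", "GridParams", function(object) {
    cat(sprintf("GridParams: st = %g A, rt = %g A, dt = %g A\n",
                object@st, object@rt, object@dt))
})

setMethod("show", "VirtualGrid", function(object) {
    cat(sprintf("VirtualGrid %s:%s — %d retained reference coordinate(s) (st %g, rt %g, dt %g)\n",
                object@structureId, object@chainId, nrow(object@points),
                object@params@st, object@params@rt, object@params@dt))
})

setMethod("show", "SuperpositionResult", function(object) {
    cat(sprintf("SuperpositionResult: rmsd = %.4f A%s\n", object@rmsd,
                if (length(object@mapping))
                    sprintf(", %d residue pairs (%s correspondence search)",
                            length(object@mapping),
                            if (object@exhaustive) "exhaustive" else "greedy")
                else ""))
})

setMethod("show", "PatternGraph", function(object) {
    cat(sprintf(paste0("PatternGraph: %d structure(s), %d site(s), ",
                       "%d cluster(s), %d pattern(s)\n"),
                length(object@structureIds), nrow(object@sites),
                nrow(object@clusters), nrow(object@patterns)))
    if (nrow(object@patterns)) {
        top <- object@patterns[order(-object@patterns$pcv,
                                     object@patterns$signature), ][1L, ]
        cat(sprintf("  top pattern: %s (PCv %.1f%%, %d sites, %d clusters)\n",
                    top$signature, top$pcv, top$totalSites, top$nClusters))
    }
})
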