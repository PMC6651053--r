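#' Sequence view of a cluster's structural alignment
#'
#' One row per member site, columns in structural-correspondence order:
#' column j of every row holds the residue that superposes onto residue j
#' of the cluster's reference site, labelled with its one-letter code and
#' original (author) PDB numbering. Structurally equivalent residues
#' therefore share a column even when their sequence order differs from
#' site to site — conserved arrangements need not follow any sequence
#' motif.
#'
#' @param graph a [PatternGraph-class].
#' @param clusterId a cluster identifier, e.g. \code{"3C1H-1"}.
#' @return data.frame with columns siteId, structureId, chain, rmsd and
#'   R1..Rk residue labels.
#' @export
clusterSequenceView <- function(graph, clusterId) {
    mem <- graph@members[graph@members$clusterId == clusterId, ,
                         drop = FALSE]
    if (nrow(mem) == 0L) stop("unknown cluster '", clusterId, "'")
    cl <- graph@clusters[graph@clusters$clusterId == clusterId, ]
    sidx <- match(mem$siteId, graph@sites$siteId)
    k <- graph@sites$nResidues[match(cl$referenceSiteId,
                                     graph@sites$siteId)]
    rows <- lapply(seq_len(nrow(mem)), function(m) {
        res <- graph@sites$residues[[sidx[m]]]
        mapping <- mem$mapping[[m]]       # member residue i -> reference j
        labels <- character(k)
        labels[mapping] <- .residueLabels(res)
        labels
    })
    out <- data.frame(siteId = mem$siteId, structureId = mem$structureId,
                      chain = graph@sites$chain[sidx],
                      rmsd = round(mem$rmsd, 3), stringsAsFactors = FALSE)
    lab <- do.call(rbind, rows)
    colnames(lab) <- paste0("R", seq_len(k))
    cbind(out, as.data.frame(lab, stringsAsFactors = FALSE))
}

#' Write a cluster's sequence view to a text table
#'
#' @inheritParams clusterSequenceView
#' @param file output path (tab-separated).
#' @return the view data.frame, invisibly.
#' @export
writeClusterSequenceView <- function(graph, clusterId, file) {
    v <- clusterSequenceView(graph, clusterId)
    utils::write.table(v, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(v)
}

#' Export a cluster as a superposed multi-model PDB
#'
#' Model 1 holds the reference site's residues in their original
#' coordinates; model k holds member k's residues transformed by the
#' rotation/translation stored at clustering time, so all models are
#' superposed on the reference. Residues are written in structural
#' correspondence order (residue j of every model matches residue j of
#' model 1).
#'
#' @param graph a [PatternGraph-class] built with structures attached
#'   (as [runDiscovery()] does).
#' @param clusterId a cluster identifier.
#' @param file output PDB path.
#' @return the path, invisibly.
#' @export
writeSuperposedCluster <- function(graph, clusterId, file) {
    mem <- graph@members[graph@members$clusterId == clusterId, ,
                         drop = FALSE]
    if (nrow(mem) == 0L) stop("unknown cluster '", clusterId, "'")
    if (length(graph@structures) == 0L)
        stop("the pattern graph carries no structures; rebuild with them attached")
    cl <- graph@clusters[graph@clusters$clusterId == clusterId, ]
    refFirst <- which(mem$siteId == cl$referenceSiteId)
    ord <- c(refFirst, setdiff(seq_len(nrow(mem)), refFirst))
    lines <- character()
    for (m in seq_along(ord)) {
        i <- ord[m]
        sidx <- match(mem$siteId[i], graph@sites$siteId)
        res <- graph@sites$residues[[sidx]]
        mapping <- mem$mapping[[i]]
        res <- res[order(mapping), , drop = FALSE]  # correspondence order
        ps <- graph@structures[[mem$structureId[i]]]
        atoms <- ps@atoms
        akey <- .residueKey(atoms$chain, atoms$resno, atoms$insert)
        atoms <- atoms[akey %in% res$key, , drop = FALSE]
        akey <- akey[akey %in% res$key]
        atoms <- atoms[order(match(akey, res$key)), , drop = FALSE]
        R <- mem$rotation[[i]]
        tr <- mem$translation[[i]]
        xyz <- as.matrix(atoms[, c("x", "y", "z")])
        xyz <- sweep(tcrossprod(xyz, R), 2, tr, "+")
        atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
        block <- .pdbBlock(atoms, end = FALSE)
        block <- block[!grepl("^END", block)]
        lines <- c(lines, sprintf("MODEL     %4d", m), block, "ENDMDL")
    }
    writeLines(c(lines, "END"), file)
    invisible(file)
}

#' Scan a sequence for the zinc-finger C3H1 sequence motif
#'
#' Finds all (possibly overlapping) occurrences of the PROSITE-style
#' pattern C-x(8)-C-x(5)-C-x(3)-H, i.e. the regular expression
#' \code{C.\{8\}C.\{5\}C.\{3\}H}, used to cross-check structurally
#' discovered 3C1H sites against the canonical sequence motif.
#'
#' @param sequence one-letter amino-acid sequence (single string).
#' @return data.frame with columns \code{start} and \code{end}: 0-based
#'   half-open spans (each of width 19), plus \code{cysHis}, a
#'   list-column of the 1-based positions of the three cysteines and the
#'   histidine of each match.
#' @examples
#' scanPrositeC3H1(paste0("C", strrep("A", 8), "C", strrep("A", 5),
#'                        "C", strrep("A", 3), "H"))
#' @export
scanPrositeC3H1 <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    m <- gregexpr("(?=C.{8}C.{5}C.{3}H)", sequence, perl = TRUE)[[1]]
    if (m[1] == -1)
        return(data.frame(start = integer(), end = integer(),
                          cysHis = I(list())))
    starts <- as.integer(m)                # 1-based match starts
    out <- data.frame(start = starts - 1L, end = starts + 19L)
    out$cysHis <- I(lapply(starts, function(s)
        c(s, s + 9L, s + 15L, s + 19L)))
    out
}
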