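## One-letter codes of the 20 standard amino acids.
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Backbone heavy-atom names; everything else (minus hydrogens) is side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.isHydrogen <- function(element, elety) {
    el <- toupper(trimws(ifelse(is.na(element), "", element)))
    ifelse(el != "", el %in% c("H", "D"),
           grepl("^[0-9]*[HD]", trimws(elety)))
}

.residueKey <- function(chain, resno, insert) {
    paste(chain, resno, ifelse(is.na(insert) | insert == "", "", insert),
          sep = ":")
}

## Build the per-residue representative-point table from an atom table.
## Residues without an alpha carbon cannot carry representative points and
## are dropped with a warning.
.buildResidueTable <- function(atoms, structureId) {
    key <- .residueKey(atoms$chain, atoms$resno, atoms$insert)
    first <- !duplicated(key)
    res <- data.frame(chain = atoms$chain[first],
                      resno = atoms$resno[first],
                      insert = ifelse(is.na(atoms$insert[first]), "",
                                      atoms$insert[first]),
                      key = key[first],
                      name3 = atoms$resid[first],
                      stringsAsFactors = FALSE)
    res$code1 <- suppressWarnings(bio3d::aa321(res$name3))
    bad <- !(res$code1 %in% AA1)
    if (any(bad)) {
        warning(sprintf("%s: dropping %d residue(s) without a standard one-letter code (%s)",
                        structureId, sum(bad),
                        paste(unique(res$name3[bad]), collapse = ", ")),
                call. = FALSE)
        keep <- res$key[!bad]
        atoms <- atoms[key %in% keep, , drop = FALSE]
        key <- key[key %in% keep]
        res <- res[!bad, , drop = FALSE]
    }
    isCA <- trimws(atoms$elety) == "CA"
    caIdx <- match(res$key, key[isCA])
    caAtoms <- atoms[isCA, , drop = FALSE]
    res$cax <- caAtoms$x[caIdx]
    res$cay <- caAtoms$y[caIdx]
    res$caz <- caAtoms$z[caIdx]
    noCA <- is.na(res$cax)
    if (any(noCA)) {
        warning(sprintf("%s: dropping %d residue(s) lacking an alpha carbon",
                        structureId, sum(noCA)), call. = FALSE)
        atoms <- atoms[key %in% res$key[!noCA], , drop = FALSE]
        key <- .residueKey(atoms$chain, atoms$resno, atoms$insert)
        res <- res[!noCA, , drop = FALSE]
    }
    sc <- !(trimws(atoms$elety) %in% BACKBONE_ATOMS) &
        !.isHydrogen(atoms$element, atoms$elety)
    scx <- vapply(split(atoms$x[sc], key[sc]), mean, 0)
    scy <- vapply(split(atoms$y[sc], key[sc]), mean, 0)
    scz <- vapply(split(atoms$z[sc], key[sc]), mean, 0)
    i <- match(res$key, names(scx))
    res$hasSC <- !is.na(i)
    res$scx <- scx[i]
    res$scy <- scy[i]
    res$scz <- scz[i]
    ## glycine has no side chain by construction: centroid := alpha carbon
    gly <- res$code1 == "G"
    res$scx[gly] <- res$cax[gly]
    res$scy[gly] <- res$cay[gly]
    res$scz[gly] <- res$caz[gly]
    rownames(res) <- NULL
    rownames(atoms) <- NULL
    list(atoms = atoms, residues = res)
}

#' Read a protein structure from PDB format
#'
#' Parses standard ATOM records into a [ProteinStructure-class].
#' HETATM records (waters, ions, ligands) are excluded — the discovery
#' method deliberately uses no co-crystallized ligand or ion information.
#' For multi-model files only the first model is kept; for alternate
#' locations only blank or 'A' records are kept; residues without a
#' standard one-letter amino-acid code (selenomethionine maps to M) are
#' dropped with a warning.
#'
#' @param source path to a PDB file, or PDB-format text (a single string
#'   with embedded newlines or a character vector of lines).
#' @param structureId identifier for the structure; defaults to the file
#'   stem (or \code{"structure"} for literal text input).
#'
#' @return a [ProteinStructure-class] object.
#' @examples
#' pdb <- makeStructures(plantSpec(motifTemplate(c("D", "G", "L", "Q"),
#'                                 ca = rbind(c(0, 0, 0), c(3, 0, 0),
#'                                            c(0, 3, 0), c(0, 0, 3))),
#'                                 seed = 1), 1)[[1]]
#' readPDB(pdb, structureId = "toy")
#' @export
readPDB <- function(source, structureId = NULL) {
    isText <- length(source) > 1L || grepl("\n", source[1L]) ||
        grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK)", source[1L])
    if (isText) {
        path <- tempfile(fileext = ".pdb")
        on.exit(unlink(path))
        writeLines(unlist(strsplit(source, "\n", fixed = TRUE)), path)
        if (is.null(structureId)) structureId <- "structure"
    } else {
        path <- source
        if (!file.exists(path))
            stop("cannot read PDB source: ", path)
        if (is.null(structureId))
            structureId <- sub("\\.(pdb|ent)$", "", basename(path),
                               ignore.case = TRUE)
    }
    pdb <- tryCatch({
        out <- NULL
        utils::capture.output(
            out <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                                    rm.alt = TRUE,
                                                    verbose = FALSE)))
        out
    },
        error = function(e) stop("PDB parse error in '", structureId, "': ",
                                 conditionMessage(e), call. = FALSE))
    at <- pdb$atom
    at <- at[at$type == "ATOM", , drop = FALSE]
    at <- at[!.isHydrogen(at$elesy, at$elety), , drop = FALSE]
    if (nrow(at) == 0L)
        stop("empty structure: '", structureId,
             "' contains no standard ATOM records", call. = FALSE)
    atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                        resno = at$resno,
                        insert = ifelse(is.na(at$insert), "", at$insert),
                        resid = at$resid,
                        elety = trimws(at$elety),
                        element = ifelse(is.na(at$elesy), "", trimws(at$elesy)),
                        x = at$x, y = at$y, z = at$z,
                        o = ifelse(is.na(at$o), 1, at$o),
                        stringsAsFactors = FALSE)
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
        stop("PDB parse error in '", structureId,
             "': non-finite atom coordinates", call. = FALSE)
    built <- .buildResidueTable(atoms, structureId)
    if (nrow(built$residues) == 0L)
        stop("empty structure: '", structureId,
             "' contains no standard residues", call. = FALSE)
    new("ProteinStructure", structureId = structureId,
        atoms = built$atoms, residues = built$residues)
}

#' Write a structure back to PDB format
#'
#' @param structure a [ProteinStructure-class].
#' @param file output path; when \code{NULL} the PDB text is returned as a
#'   character vector of lines instead.
#' @return the output path (or the PDB lines when \code{file} is NULL),
#'   invisibly.
#' @export
writePDB <- function(structure, file = NULL) {
    lines <- .pdbBlock(structure@atoms, end = TRUE)
    if (is.null(file)) return(invisible(lines))
    writeLines(lines, file)
    invisible(file)
}

## Format an atom table as PDB lines via bio3d's writer.
.pdbBlock <- function(atoms, end = FALSE) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    suppressWarnings(bio3d::write.pdb(
        file = path,
        xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
        type = rep("ATOM", nrow(atoms)),
        resno = atoms$resno,
        resid = atoms$resid,
        eleno = seq_len(nrow(atoms)),
        elety = atoms$elety,
        chain = atoms$chain,
        insert = ifelse(atoms$insert == "", NA, atoms$insert),
        o = atoms$o,
        b = rep(0, nrow(atoms)),
        elesy = atoms$element,
        end = end))
    readLines(path)
}

#' Drop residues whose side chain was not resolved
#'
#' Backbone-only depositions (common in low-resolution cryo-EM models)
#' carry no side-chain coordinates, and without side chains residue
#' arrangements cannot be characterised. Every non-glycine residue
#' lacking side-chain heavy atoms is removed; glycine is retained with
#' its centroid defined as the alpha carbon. Chains left empty disappear.
#'
#' @param structure a [ProteinStructure-class].
#' @return the filtered [ProteinStructure-class].
#' @details Idempotent. If no residue survives, an error of class
#'   \code{emptyStructureError} is signalled; [runDiscovery()] treats such
#'   structures as contributing zero sites (they still count in the
#'   protein-coverage denominator).
#' @export
filterSidechainless <- function(structure) {
    res <- structure@residues
    keep <- res$hasSC | res$code1 == "G"
    if (!any(keep))
        stop(.emptyStructureError(structure@structureId))
    res <- res[keep, , drop = FALSE]
    atoms <- structure@atoms
    akey <- .residueKey(atoms$chain, atoms$resno, atoms$insert)
    atoms <- atoms[akey %in% res$key, , drop = FALSE]
    rownames(res) <- rownames(atoms) <- NULL
    new("ProteinStructure", structureId = structure@structureId,
        atoms = atoms, residues = res)
}

.emptyStructureError <- function(id) {
    structure(class = c("emptyStructureError", "error", "condition"),
              list(message = paste0("no detectable patterns: structure '", id,
                                    "' has no residues with side-chain atoms"),
                   call = NULL))
}

#' Representative points of each residue
#'
#' Returns the two representative points used throughout the method:
#' the alpha carbon and the unweighted centroid of the side-chain heavy
#' atoms (atoms other than N, CA, C, O, OXT and hydrogens). For glycine
#' the centroid equals the alpha carbon. Residue membership in grid
#' neighbourhoods and search zones is decided by the side-chain centroid.
#'
#' @param structure a [ProteinStructure-class] (ideally after
#'   [filterSidechainless()]).
#' @param chain optional chain identifier to restrict to.
#' @return data.frame with one row per residue: key, chain, resno, insert,
#'   code1, cax/cay/caz (alpha carbon) and scx/scy/scz (side-chain
#'   centroid), in angstrom.
#' @export
representativePoints <- function(structure, chain = NULL) {
    res <- structure@residues
    if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
    rownames(res) <- NULL
    res[, c("key", "chain", "resno", "insert", "code1",
            "cax", "cay", "caz", "scx", "scy", "scz")]
}
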