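## Hand-formatted PDB records for parser tests (fixed-column PDB layout).
pdbLine <- function(type, serial, name, alt, resn, chain, resi, x, y, z,
                    occ = 1, elem = substr(trimws(name), 1, 1)) {
    nm <- if (nchar(name) >= 4) substr(name, 1, 4) else
        sprintf(" %-3s", name)
    sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, nm, alt, resn, chain, resi, x, y, z, occ, 0, elem)
}

## Full residue: backbone + CB at a chosen side-chain centroid.
pdbResidue <- function(serial, resn, chain, resi, ca, cb = NULL) {
    ln <- c(pdbLine("ATOM", serial, "N", " ", resn, chain, resi,
                    ca[1] - 1.2, ca[2] + 0.8, ca[3], elem = "N"),
            pdbLine("ATOM", serial + 1, "CA", " ", resn, chain, resi,
                    ca[1], ca[2], ca[3], elem = "C"),
            pdbLine("ATOM", serial + 2, "C", " ", resn, chain, resi,
                    ca[1] + 1.2, ca[2] + 0.7, ca[3], elem = "C"),
            pdbLine("ATOM", serial + 3, "O", " ", resn, chain, resi,
                    ca[1] + 2, ca[2] + 1.6, ca[3], elem = "O"))
    if (!is.null(cb))
        ln <- c(ln, pdbLine("ATOM", serial + 4, "CB", " ", resn, chain,
                            resi, cb[1], cb[2], cb[3], elem = "C"))
    ln
}

## A residue data.frame in the package's internal layout.
mkRes <- function(codes, ca, sc = NULL, chain = "A",
                  resno = seq_along(codes)) {
    ca <- as.matrix(ca)
    if (is.null(sc)) sc <- sweep(ca, 2, c(0, 0, 1.2), "+")
    sc <- as.matrix(sc)
    sc[codes == "G", ] <- ca[codes == "G", ]
    data.frame(chain = chain, resno = resno, insert = "",
               key = paste(chain, resno, "", sep = ":"),
               name3 = "XXX", code1 = codes, hasSC = codes != "G",
               cax = ca[, 1], cay = ca[, 2], caz = ca[, 3],
               scx = sc[, 1], scy = sc[, 2], scz = sc[, 3],
               stringsAsFactors = FALSE)
}

## A one-row site table as produced by findSites.
mkSiteRow <- function(codes, ca, sc = NULL, id = "s1", structure = "str",
                      chain = "A", gridId = 1L, resno = seq_along(codes)) {
    res <- mkRes(codes, ca, sc, chain, resno)
    data.frame(siteId = id, structureId = structure, chain = chain,
               gridId = gridId, zone = 0L, ox = 0, oy = 0, oz = 0,
               signature = componentSignature(codes),
               nResidues = length(codes), residues = I(list(res)),
               stringsAsFactors = FALSE)
}

## Rigid transform of a site's coordinates (rotation about z + translation).
transformSiteRow <- function(site, theta = 0, shift = c(0, 0, 0),
                             id = site$siteId, structure = site$structureId,
                             gridId = site$gridId) {
    R <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0), c(0, 0, 1))
    res <- site$residues[[1]]
    ca <- sweep(tcrossprod(as.matrix(res[, c("cax", "cay", "caz")]), R),
                2, shift, "+")
    sc <- sweep(tcrossprod(as.matrix(res[, c("scx", "scy", "scz")]), R),
                2, shift, "+")
    res$cax <- ca[, 1]; res$cay <- ca[, 2]; res$caz <- ca[, 3]
    res$scx <- sc[, 1]; res$scy <- sc[, 2]; res$scz <- sc[, 3]
    out <- site
    out$siteId <- id
    out$structureId <- structure
    out$gridId <- gridId
    out$residues <- I(list(res))
    out
}

## Structure with residues at exact coordinates (CA at ca, side-chain
## centroid encoded as a single CB at sc; glycine gets no CB).
psFromCoords <- function(codes, ca, sc = ca, id = "fix") {
    ca <- as.matrix(ca); sc <- as.matrix(sc)
    ln <- unlist(lapply(seq_along(codes), function(i)
        pdbResidue(10 * i, bio3d::aa123(codes[i]), "A", i, ca[i, ],
                   cb = if (codes[i] == "G") NULL else sc[i, ])))
    readPDB(c(ln, "END"), structureId = id)
}

## Backbone-only structure (no side chains anywhere, no glycine).
backboneOnlyPDB <- function(n = 6) {
    ln <- unlist(lapply(seq_len(n), function(i)
        pdbResidue(10 * i, "ALA", "A", i, c(3 * i, 0, 0), cb = NULL)))
    c(ln, "END")
}
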