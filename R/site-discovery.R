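#' Canonical component signature of a residue set
#'
#' Collapses a residue arrangement into its composition signature: the
#' concatenation of (count, one-letter code) pairs in strict alphabetical
#' code order, e.g. the residues H31, I32, K10, K90, L11, L12, L7, P92,
#' S3, S8, T9 become \code{"1H1I2K3L1P2S1T"}. All sites sharing one
#' signature form one 3D-pattern, regardless of conformation; the
#' signature is independent of residue order and of sequence position.
#'
#' @param codes character vector of one-letter amino-acid codes (or a
#'   residue data.frame with a \code{code1} column).
#' @return character(1), the canonical signature text.
#' @examples
#' componentSignature(c("C", "C", "C", "H"))            # "3C1H"
#' componentSignature(c("Q", "L", "G", "D"))            # "1D1G1L1Q"
#' @export
componentSignature <- function(codes) {
    if (is.data.frame(codes)) codes <- codes$code1
    if (length(codes) == 0L) stop("signature of an empty residue set")
    if (!all(codes %in% AA1))
        stop("unknown one-letter amino-acid code(s): ",
             paste(setdiff(codes, AA1), collapse = ", "))
    tab <- table(codes)
    cds <- sort(names(tab))
    paste0(as.integer(tab[cds]), cds, collapse = "")
}

#' Parse a signature back into residue counts
#'
#' Inverse of [componentSignature()]: \code{parseSignature(componentSignature(x))}
#' recovers the per-code counts.
#'
#' @param text a canonical signature string, e.g. \code{"3C1H"}.
#' @return named integer vector of counts, names in alphabetical order.
#' @export
parseSignature <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    m <- gregexpr("([0-9]+)([A-Z])", text)
    if (m[[1]][1] == -1 ||
        sum(attr(m[[1]], "match.length")) != nchar(text))
        stop("not a canonical signature: '", text, "'")
    parts <- regmatches(text, m)[[1]]
    counts <- as.integer(sub("[A-Z]$", "", parts))
    codes <- sub("^[0-9]+", "", parts)
    if (is.unsorted(codes, strictly = TRUE))
        stop("not a canonical signature (codes not strictly alphabetical): '",
             text, "'")
    stats::setNames(counts, codes)
}

#' Match a sub-pattern query against signatures
#'
#' Applies a user regular expression to canonical signature texts, e.g.
#' \code{"^2C.*2H$"} selects the patterns that begin with exactly two
#' cysteines and end with exactly two histidines.
#'
#' @param signature character vector of canonical signature texts.
#' @param regex a single regular expression.
#' @return logical vector, one element per signature.
#' @export
matchSubpattern <- function(signature, regex) {
    stopifnot(is.character(regex), length(regex) == 1L)
    out <- tryCatch(grepl(regex, signature),
                    error = function(e)
                        stop("invalid regular expression '", regex, "': ",
                             conditionMessage(e), call. = FALSE),
                    warning = function(w)
                        stop("invalid regular expression '", regex, "'",
                             call. = FALSE))
    out
}

## Assemble one site row (residues sorted by sequence number for display;
## discovery itself is order-independent).
.makeSite <- function(structureId, chain, gridId, zone, origin, res) {
    ord <- order(res$resno, res$insert)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
    siteId <- paste0(structureId, ":", chain, ":", gridId,
                     if (zone > 0L) paste0(":z", zone) else "")
    data.frame(siteId = siteId, structureId = structureId, chain = chain,
               gridId = gridId, zone = as.integer(zone),
               ox = origin[1], oy = origin[2], oz = origin[3],
               signature = componentSignature(res$code1),
               nResidues = nrow(res),
               residues = I(list(res)),
               stringsAsFactors = FALSE)
}

.emptySites <- function() {
    data.frame(siteId = character(), structureId = character(),
               chain = character(), gridId = integer(), zone = integer(),
               ox = numeric(), oy = numeric(), oz = numeric(),
               signature = character(), nResidues = integer(),
               residues = I(list()), stringsAsFactors = FALSE)
}

#' Enumerate all candidate sites of a structure
#'
#' For every chain (processed separately), builds the grid of virtual
#' coordinates and collects, around each retained reference coordinate
#' (and around each of its seven displaced zones when \code{dt > 0}), the
#' residues whose side-chain centroid lies within \code{rt}. Every group
#' of at least four residues is emitted as a site; sites with identical
#' residue sets within a chain are deduplicated, keeping the first in
#' (gridId, zone) order. The output is ordered by (chain, gridId, zone).
#'
#' @param structure a [ProteinStructure-class] after
#'   [filterSidechainless()].
#' @param params a [GridParams-class].
#' @return data.frame of sites with columns siteId, structureId, chain,
#'   gridId, zone (0 for the spherical neighbourhood, 1-7 for displaced
#'   zones), ox/oy/oz (the reference coordinate), signature, nResidues and
#'   a list-column \code{residues} holding each site's residue table.
#' @export
findSites <- function(structure, params) {
    stopifnot(is(structure, "ProteinStructure"), is(params, "GridParams"))
    out <- list()
    for (ch in chainIds(structure)) {
        res <- structure@residues[structure@residues$chain == ch, ,
                                  drop = FALSE]
        if (nrow(res) < 4L) next
        grid <- buildGrid(structure, params, chain = ch)
        gp <- grid@points
        if (nrow(gp) == 0L) next
        pts <- as.matrix(res[, c("scx", "scy", "scz")])
        rt2 <- params@rt^2 + 1e-9
        sites <- list()
        seen <- character()
        centers <- as.matrix(gp[, c("x", "y", "z")])
        for (k in seq_len(nrow(gp))) {
            ctr <- centers[k, ]
            d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
                (pts[, 3] - ctr[3])^2
            membersets <- list(`0` = which(d2 <= rt2))
            if (params@dt > 0) {
                zn <- expandZones(ctr, params@dt)
                for (z in seq_len(7L)) {
                    da <- (pts[, 1] - zn$x1[z])^2 + (pts[, 2] - zn$y1[z])^2 +
                        (pts[, 3] - zn$z1[z])^2
                    db <- (pts[, 1] - zn$x2[z])^2 + (pts[, 2] - zn$y2[z])^2 +
                        (pts[, 3] - zn$z2[z])^2
                    membersets[[as.character(z)]] <-
                        which(da <= rt2 | db <= rt2)
                }
            }
            for (zname in names(membersets)) {
                idx <- membersets[[zname]]
                if (length(idx) < 4L) next
                setKey <- paste(sort(idx), collapse = ",")
                if (setKey %in% seen) next
                seen <- c(seen, setKey)
                sites[[length(sites) + 1L]] <-
                    .makeSite(structureId(structure), ch, gp$gridId[k],
                              as.integer(zname), ctr,
                              res[idx, , drop = FALSE])
            }
        }
        if (length(sites)) out[[ch]] <- do.call(rbind, sites)
    }
    if (!length(out)) {
        message("no sites found in structure '", structureId(structure), "'")
        return(.emptySites())
    }
    sites <- do.call(rbind, out)
    sites <- sites[order(sites$chain, sites$gridId, sites$zone), ,
                   drop = FALSE]
    rownames(sites) <- NULL
    sites
}

#' Export a site table to TSV or JSON
#'
#' Flattens the residue list-column into colon-separated residue labels
#' (\code{"H31:I32:..."}, author PDB numbering with insertion codes).
#'
#' @param sites a site table from [findSites()] or [siteTable()].
#' @param file output path ending in \code{.tsv} or \code{.json}.
#' @return the flattened data.frame, invisibly.
#' @export
writeSiteTable <- function(sites, file) {
    flat <- .flattenSites(sites)
    if (grepl("\\.json$", file))
        jsonlite::write_json(flat, file, dataframe = "rows", digits = NA)
    else
        utils::write.table(flat, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(flat)
}

.residueLabels <- function(res) {
    paste0(res$code1, res$resno, ifelse(res$insert == "", "", res$insert))
}

.flattenSites <- function(sites) {
    data.frame(siteId = sites$siteId, structureId = sites$structureId,
               chain = sites$chain, gridId = sites$gridId,
               zone = sites$zone,
               residues = vapply(sites$residues,
                                 function(r) paste(.residueLabels(r),
                                                   collapse = ":"), ""),
               signature = sites$signature,
               ox = sites$ox, oy = sites$oy, oz = sites$oz,
               stringsAsFactors = FALSE)
}
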