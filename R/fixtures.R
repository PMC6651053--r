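## Run expr with a local, restored RNG state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

## Uniform random rotation matrix (normalised quaternion).
.randomRotation <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
          c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
          c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Define a motif template
#'
#' A template is a residue arrangement in a local coordinate frame: one
#' one-letter code, one alpha-carbon position and one intended
#' side-chain-centroid position per residue. Planted copies of the
#' template are written with a single pseudo side-chain atom placed
#' exactly at the intended centroid, so the fixture's geometric ground
#' truth is independent of side-chain chemistry. Glycine centroids are
#' forced to the alpha carbon, matching the parsing convention.
#'
#' @param codes character vector (>= 4) of one-letter amino-acid codes.
#' @param ca numeric n x 3 matrix of alpha-carbon coordinates (angstrom).
#' @param sc optional n x 3 matrix of side-chain centroids; defaults to
#'   \code{ca} displaced by 1.5 angstrom along +z.
#' @param name template label.
#' @return a list of class \code{"MotifTemplate"} with elements codes,
#'   ca, sc, name and radius (largest distance of any representative
#'   point from the template centroid).
#' @export
motifTemplate <- function(codes, ca, sc = NULL, name = "motif") {
    ca <- as.matrix(ca)
    if (length(codes) < 4L)
        stop("a template needs at least four residues")
    if (nrow(ca) != length(codes) || ncol(ca) != 3L)
        stop("'ca' must be a length(codes) x 3 matrix")
    if (!all(codes %in% AA1))
        stop("unknown one-letter code(s) in template")
    if (is.null(sc)) sc <- sweep(ca, 2, c(0, 0, 1.5), "+")
    sc <- as.matrix(sc)
    if (!all(dim(sc) == dim(ca))) stop("'sc' must match 'ca' in shape")
    sc[codes == "G", ] <- ca[codes == "G", ]
    ctr <- colMeans(rbind(ca, sc))
    radius <- sqrt(max(rowSums(sweep(rbind(ca, sc), 2, ctr)^2)))
    structure(list(codes = codes, ca = ca, sc = sc, name = name,
                   radius = radius), class = "MotifTemplate")
}

#' Specify how to plant a template into synthetic structures
#'
#' @param template a [motifTemplate()].
#' @param nCopies planted copies per structure, each under an independent
#'   uniform random rotation and translation.
#' @param jitterSd Gaussian per-point, per-coordinate noise (angstrom,
#'   >= 0) applied to every planted representative point.
#' @param nDecoys random single decoy residues per structure, placed away
#'   from every planted copy (and from each other, so decoys cannot
#'   aggregate into spurious four-residue sites).
#' @param box edge length of the cubic placement region (angstrom).
#' @param seed integer seed; structure k of a run uses seed + k - 1, so
#'   output is byte-identical across calls.
#' @param clearance minimum distance between planted-copy centers and to
#'   decoys (angstrom); defaults to \code{2 * radius + 8}, keeping copy
#'   bounding spheres disjoint and decoys out of search range.
#' @return a list of class \code{"PlantSpec"}.
#' @export
plantSpec <- function(template, nCopies = 1, jitterSd = 0, nDecoys = 0,
                      box = 40, seed = 1, clearance = NULL) {
    stopifnot(inherits(template, "MotifTemplate"), nCopies >= 1,
              jitterSd >= 0, nDecoys >= 0, box > 0)
    if (is.null(clearance)) clearance <- 2 * template$radius + 8
    structure(list(template = template, nCopies = nCopies,
                   jitterSd = jitterSd, nDecoys = nDecoys, box = box,
                   seed = as.integer(seed), clearance = clearance),
              class = "PlantSpec")
}

.placeCenters <- function(n, box, margin, clearance, existing = NULL) {
    centers <- existing
    for (k in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(2000L)) {
            p <- stats::runif(3, margin, box - margin)
            if (is.null(centers) ||
                all(sqrt(colSums((t(centers) - p)^2)) >= clearance)) {
                centers <- rbind(centers, p)
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("generation error: box too small to separate planted copies/decoys")
    }
    centers
}

## Atom table for one residue with a pseudo side chain encoding the
## intended centroid (no CB for glycine: its centroid is the CA).
.residueAtoms <- function(code, resno, ca, sc) {
    name3 <- bio3d::aa123(code)
    at <- data.frame(chain = "A", resno = resno, insert = "",
                     resid = name3,
                     elety = c("N", "CA", "C", "O"),
                     element = c("N", "C", "C", "O"),
                     x = ca[1] + c(-1.2, 0, 1.25, 1.95),
                     y = ca[2] + c(0.77, 0, 0.68, 1.65),
                     z = ca[3], o = 1, stringsAsFactors = FALSE)
    if (code != "G")
        at <- rbind(at, data.frame(chain = "A", resno = resno, insert = "",
                                   resid = name3, elety = "CB",
                                   element = "C", x = sc[1], y = sc[2],
                                   z = sc[3], o = 1,
                                   stringsAsFactors = FALSE))
    at
}

.structureFromResidues <- function(codes, ca, sc) {
    atoms <- do.call(rbind, lapply(seq_along(codes), function(i)
        .residueAtoms(codes[i], i, ca[i, ], sc[i, ])))
    .pdbBlock(atoms, end = TRUE)
}

#' Generate synthetic PDB structures with planted motifs
#'
#' Each structure contains \code{nCopies} rigid-body-transformed copies
#' of the template (independent uniform rotations and translations, plus
#' optional Gaussian per-point jitter) and \code{nDecoys} isolated decoy
#' residues. The written pseudo side-chain atom sits exactly at the
#' intended centroid, so parsing a generated structure recovers the
#' planted representative points up to PDB coordinate precision (3
#' decimals) and jitter.
#'
#' @param spec a [plantSpec()].
#' @param nStructures number of structures to generate.
#' @return named list of PDB texts (character vectors of lines), names
#'   \code{synth01, synth02, ...}; attribute \code{"groundTruth"} holds,
#'   per structure, the copy centers, rotations and the residue numbers
#'   of each planted copy.
#' @export
makeStructures <- function(spec, nStructures) {
    stopifnot(inherits(spec, "PlantSpec"), nStructures >= 1)
    tpl <- spec$template
    n <- nrow(tpl$ca)
    out <- list()
    truth <- list()
    for (s in seq_len(nStructures)) {
        gen <- .withSeed(spec$seed + s - 1L, {
            margin <- tpl$radius + 1
            if (2 * margin >= spec$box)
                stop("generation error: box too small for the template")
            centers <- .placeCenters(spec$nCopies, spec$box, margin,
                                     spec$clearance)
            rots <- replicate(spec$nCopies, .randomRotation(),
                              simplify = FALSE)
            codes <- character(); ca <- NULL; sc <- NULL
            copyResnos <- list()
            for (k in seq_len(spec$nCopies)) {
                R <- rots[[k]]
                caK <- sweep(tcrossprod(tpl$ca, R), 2, centers[k, ], "+")
                scK <- sweep(tcrossprod(tpl$sc, R), 2, centers[k, ], "+")
                if (spec$jitterSd > 0) {
                    caK <- caK + matrix(stats::rnorm(3 * n, 0,
                                                     spec$jitterSd), n)
                    scK <- scK + matrix(stats::rnorm(3 * n, 0,
                                                     spec$jitterSd), n)
                    scK[tpl$codes == "G", ] <- caK[tpl$codes == "G", ]
                }
                copyResnos[[k]] <- length(codes) + seq_len(n)
                codes <- c(codes, tpl$codes)
                ca <- rbind(ca, caK); sc <- rbind(sc, scK)
            }
            if (spec$nDecoys > 0) {
                dec <- .placeCenters(spec$nDecoys, spec$box, 1,
                                     spec$clearance, existing = centers)
                dec <- dec[-seq_len(spec$nCopies), , drop = FALSE]
                dCodes <- sample(setdiff(AA1, "G"), spec$nDecoys,
                                 replace = TRUE)
                codes <- c(codes, dCodes)
                ca <- rbind(ca, dec)
                sc <- rbind(sc, sweep(dec, 2, c(0, 0, 1.5), "+"))
            }
            list(pdb = .structureFromResidues(codes, ca, sc),
                 centers = centers, rotations = rots,
                 copyResnos = copyResnos)
        })
        id <- sprintf("synth%02d", s)
        out[[id]] <- gen$pdb
        truth[[id]] <- gen[c("centers", "rotations", "copyResnos")]
    }
    attr(out, "groundTruth") <- truth
    out
}

#' Synthetic zinc-finger-style fixture
#'
#' Builds one synthetic chain whose sequence contains the
#' C-x(8)-C-x(5)-C-x(3)-H motif exactly once and whose four key residues
#' (three cysteines, one histidine) form a compact spatial 3C1H cluster
#' (representative points mutually within 6 angstrom), while all spacer
#' residues lie on a distant line where no four residues ever share a
#' search sphere. Spacer identities are random but never cysteine or
#' histidine, so the sequence scan ground truth is exact.
#'
#' @param seed integer seed (output is byte-identical per seed).
#' @return list with elements \code{pdb} (PDB text lines),
#'   \code{sequence} (one-letter string), \code{spans} (the
#'   [scanPrositeC3H1()] ground truth, 0-based half-open),
#'   \code{keyResnos} (residue numbers of the three cysteines and the
#'   histidine) and \code{groundTruth} (a JSON-serialisable list of the
#'   same).
#' @export
makeC3H1Fixture <- function(seed = 1) {
    .withSeed(seed, {
        nLead <- 2L
        motifLen <- 20L
        nTail <- 2L
        total <- nLead + motifLen + nTail
        keyOffsets <- c(1L, 10L, 16L, 20L)      # C, C, C, H within the motif
        keyResnos <- nLead + keyOffsets
        codes <- sample(setdiff(AA1, c("C", "H")), total, replace = TRUE)
        codes[keyResnos] <- c("C", "C", "C", "H")
        ## compact spatial cluster for the key residues (pairwise < 6 A)
        keySc <- rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 2.6, 0),
                       c(1.5, 1.0, 2.2))
        sc <- matrix(NA_real_, total, 3)
        ca <- matrix(NA_real_, total, 3)
        sc[keyResnos, ] <- keySc
        ca[keyResnos, ] <- sweep(keySc, 2, c(0.8, 0.6, 0.5), "+")
        spacers <- setdiff(seq_len(total), keyResnos)
        line <- cbind(25 + 3.2 * (seq_along(spacers) - 1), 0, 0)
        ca[spacers, ] <- line
        sc[spacers, ] <- sweep(line, 2, c(0.4, 0.4, 1.2), "+")
        spans <- data.frame(start = nLead, end = nLead + motifLen)
        spans$cysHis <- I(list(keyResnos))
        list(pdb = .structureFromResidues(codes, ca, sc),
             sequence = paste(codes, collapse = ""),
             spans = spans,
             keyResnos = keyResnos,
             groundTruth = list(keyResnos = keyResnos,
                                span = c(nLead, nLead + motifLen)))
    })
}

#' Synthetic three-structure, two-conformer benchmark set
#'
#' Builds three small synthetic structures sharing one planted
#' \code{1D1G1L1Q} arrangement — a compact conformer present in all three
#' (twice in the first) — while the third structure additionally carries
#' an elongated conformer of the same composition. The elongated
#' arrangement spans more than two search-sphere diameters, so it is only
#' reachable through a displaced two-center zone (\code{dt > 0}); three
#' anchor residues placed perpendicular to its long axis retain the
#' central grid point while staying outside the capturing zone. At the
#' thresholds st 2, rt 5, dt 2, rmsdt 4.5 the expected outcome is one
#' pattern \code{1D1G1L1Q} at PCv 100 with a four-site cluster spanning
#' all three structures (CCv 100) and a single-site second cluster
#' (CCv 33.3).
#'
#' This set is a synthetic stand-in: it emulates the topology of a
#' multi-target benchmark (three unrelated proteins sharing one
#' conserved surface arrangement in two conformational clusters), not
#' any real deposition.
#'
#' @param seed integer seed for the copy rotations and jitter.
#' @param jitterSd Gaussian per-point noise (angstrom) applied to the
#'   compact copies (the elongated conformer is written exactly).
#' @return named list of three PDB texts (\code{twoConfA}, \code{twoConfB},
#'   \code{twoConfC}).
#' @export
makeTwoConformerSet <- function(seed = 1, jitterSd = 0.3) {
    ## compact reference conformation (fits one search sphere)
    caT <- rbind(c(-3, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, -1.3, 2.8))
    scT <- sweep(caT, 2, c(0, 0, 1.2), "+")
    scT[2, ] <- caT[2, ]                        # glycine: centroid = CA
    ## elongated conformation (zone-only; minimal RMSD to the compact
    ## conformer over all type-preserving mappings exceeds 5 angstrom)
    caE <- rbind(c(3.87, -1.45, 0.19), c(5.59, -1.23, -1.24),
                 c(-5.09, 0.87, 1.38), c(-5.19, -0.15, -1.16))
    scE <- sweep(caE, 2, c(0, 0, 1.2), "+")
    scE[2, ] <- caE[2, ]
    ## anchors: centroids at radius 4.85 perpendicular to the long axis —
    ## inside the retention sphere (rt 5), outside both zone centers
    anchSc <- rbind(c(0, 4.85, 0), c(0, -4.85, 0), c(0, 0, 4.85))
    anchCa <- sweep(anchSc, 2, c(0, 0, 1.2), "-")
    codes <- c("D", "G", "L", "Q")
    jit <- function(x, sd) if (sd > 0)
        x + matrix(stats::rnorm(length(x), 0, sd), nrow(x)) else x
    placeRes <- function(codes, ca, sc, center, R, startRes, sd = 0) {
        ca <- jit(sweep(tcrossprod(ca, R), 2, center, "+"), sd)
        sc <- jit(sweep(tcrossprod(sc, R), 2, center, "+"), sd)
        sc[codes == "G", ] <- ca[codes == "G", , drop = FALSE]
        do.call(rbind, lapply(seq_along(codes), function(i)
            .residueAtoms(codes[i], startRes + i - 1L, ca[i, ], sc[i, ])))
    }
    .withSeed(seed, {
        A <- rbind(placeRes(codes, caT, scT, c(10, 10, 10),
                            .randomRotation(), 1L, jitterSd),
                   placeRes(codes, caT, scT, c(40, 12, 12),
                            .randomRotation(), 11L, jitterSd))
        B <- placeRes(codes, caT, scT, c(15, 20, 10), .randomRotation(),
                      1L, jitterSd)
        Cc <- placeRes(codes, caT, scT, c(10, 10, 10), .randomRotation(),
                       1L, jitterSd)
        ## one isolated corner residue pins the chain's bounding-box
        ## minimum (hence the lattice anchor) at exactly (2, 2, 2); the
        ## elongated block is then snapped onto the st = 2 lattice
        corner <- .residueAtoms("T", 30L, c(2, 2, 0.8), c(2, 2, 2))
        c0 <- c(2, 2, 2) + 2 * round((c(44, 15, 15) - c(2, 2, 2)) / 2)
        Cc <- rbind(Cc, corner,
                    placeRes(codes, caE, scE, c0, diag(3), 11L),
                    placeRes(c("A", "S", "V"), anchCa, anchSc, c0,
                             diag(3), 21L))
        list(twoConfA = .pdbBlock(A, end = TRUE),
             twoConfB = .pdbBlock(B, end = TRUE),
             twoConfC = .pdbBlock(Cc, end = TRUE))
    })
}
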