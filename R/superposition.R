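#' Optimal rigid-body superposition of paired point sets
#'
#' Closed-form least-squares superposition (SVD of the covariance of the
#' centred point sets, with determinant correction so only proper
#' rotations are returned — mirror superpositions would violate protein
#' chirality). Finds the rotation R and translation t minimising
#' \deqn{RMSD = \sqrt{\sum_i \|R p_i + t - q_i\|^2 / N}.}
#'
#' @param p,q N x 3 matrices of paired coordinates (N >= 3), angstrom.
#' @return a [SuperpositionResult-class] (empty mapping).
#' @export
kabsch <- function(p, q) {
    p <- as.matrix(p); q <- as.matrix(q)
    if (!all(dim(p) == dim(q)))
        stop("point sets must have identical dimensions")
    if (ncol(p) != 3L) stop("points must be N x 3")
    if (nrow(p) < 3L) stop("at least 3 paired points are required")
    pm <- colMeans(p); qm <- colMeans(q)
    pc <- sweep(p, 2, pm); qc <- sweep(q, 2, qm)
    H <- crossprod(pc, qc)          # 3x3 covariance
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    if (d == 0) d <- 1              # fully degenerate covariance
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    t <- qm - as.numeric(R %*% pm)
    resid <- sweep(tcrossprod(p, R), 2, t, "+") - q
    rmsd <- sqrt(mean(rowSums(resid^2)))
    new("SuperpositionResult", rmsd = rmsd, rotation = R,
        translation = as.numeric(t), mapping = integer(),
        exhaustive = TRUE)
}

## All permutations of 1..n (n small).
.perms <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (sub in .perms(n - 1L))
        for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(sub, n, pos - 1L)
    out
}

.sitePoints <- function(res) {
    ## two representative points per residue: alpha carbon + side-chain centroid
    rbind(as.matrix(res[, c("cax", "cay", "caz")]),
          as.matrix(res[, c("scx", "scy", "scz")]))
}

.rmsdForMapping <- function(resA, resB, mapping) {
    n <- nrow(resA)
    pa <- .sitePoints(resA)
    pb <- .sitePoints(resB[mapping, , drop = FALSE])
    kabsch(pa, pb)
}

## Greedy correspondence refinement for large same-type groups: start from
## a centroid-distance-ranked pairing, then alternate superposition and
## per-type nearest-neighbour reassignment until stable.
.greedyMapping <- function(resA, resB, groupsA, groupsB) {
    n <- nrow(resA)
    mapping <- integer(n)
    ctrA <- colMeans(as.matrix(resA[, c("scx", "scy", "scz")]))
    ctrB <- colMeans(as.matrix(resB[, c("scx", "scy", "scz")]))
    dA <- sqrt((resA$scx - ctrA[1])^2 + (resA$scy - ctrA[2])^2 +
                   (resA$scz - ctrA[3])^2)
    dB <- sqrt((resB$scx - ctrB[1])^2 + (resB$scy - ctrB[2])^2 +
                   (resB$scz - ctrB[3])^2)
    for (tp in names(groupsA)) {
        ia <- groupsA[[tp]][order(dA[groupsA[[tp]]])]
        ib <- groupsB[[tp]][order(dB[groupsB[[tp]]])]
        mapping[ia] <- ib
    }
    best <- .rmsdForMapping(resA, resB, mapping)
    for (iter in seq_len(30L)) {
        R <- best@rotation; tr <- best@translation
        a <- sweep(tcrossprod(as.matrix(resA[, c("scx", "scy", "scz")]), R),
                   2, tr, "+")
        b <- as.matrix(resB[, c("scx", "scy", "scz")])
        newMap <- integer(n)
        for (tp in names(groupsA)) {
            ia <- groupsA[[tp]]; ib <- groupsB[[tp]]
            avail <- rep(TRUE, length(ib))
            for (i in ia) {
                d <- colSums((t(b[ib, , drop = FALSE]) - a[i, ])^2)
                d[!avail] <- Inf
                j <- which.min(d)
                newMap[i] <- ib[j]
                avail[j] <- FALSE
            }
        }
        if (all(newMap == mapping)) break
        cand <- .rmsdForMapping(resA, resB, newMap)
        if (cand@rmsd >= best@rmsd - 1e-12) break
        mapping <- newMap
        best <- cand
    }
    list(mapping = mapping, fit = best)
}

#' Minimal RMSD between two sites of the same signature
#'
#' Sites of one 3D-pattern contain the same residue types but their
#' residues come from unrelated sequence positions, so no sequence-based
#' pairing exists. The comparison therefore searches over all
#' type-preserving residue bijections (each residue contributing two
#' points: alpha carbon and side-chain centroid) and returns the
#' correspondence and proper-rotation superposition with minimal RMSD.
#' The search is exhaustive over within-type permutations when the
#' largest same-type group has at most 6 residues; larger groups fall
#' back to an iterated greedy assignment, flagged by
#' \code{exhaustive = FALSE} in the result.
#'
#' @param a,b single site rows (from [findSites()]) with identical
#'   signatures; comparing different 3D-patterns is a contract error.
#' @return a [SuperpositionResult-class]; \code{mapping[i] = j} pairs
#'   residue i of \code{a} (in its stored order) with residue j of
#'   \code{b}, and rotation/translation map \code{a} onto \code{b}.
#' @export
siteRMSD <- function(a, b) {
    resA <- if (is.data.frame(a) && "residues" %in% names(a)) a$residues[[1L]] else a
    resB <- if (is.data.frame(b) && "residues" %in% names(b)) b$residues[[1L]] else b
    sigA <- componentSignature(resA$code1)
    sigB <- componentSignature(resB$code1)
    if (sigA != sigB)
        stop("cannot compare sites of different 3D-patterns ('",
             sigA, "' vs '", sigB, "')")
    groupsA <- split(seq_len(nrow(resA)), resA$code1)
    groupsB <- split(seq_len(nrow(resB)), resB$code1)
    maxGroup <- max(lengths(groupsA))
    if (maxGroup <= 6L) {
        permsByType <- lapply(groupsA, function(i) .perms(length(i)))
        grid <- expand.grid(lapply(permsByType, seq_along))
        best <- NULL
        bestMap <- NULL
        for (r in seq_len(nrow(grid))) {
            mapping <- integer(nrow(resA))
            for (tp in names(groupsA)) {
                perm <- permsByType[[tp]][[grid[r, tp]]]
                mapping[groupsA[[tp]]] <- groupsB[[tp]][perm]
            }
            fit <- .rmsdForMapping(resA, resB, mapping)
            if (is.null(best) || fit@rmsd < best@rmsd) {
                best <- fit
                bestMap <- mapping
            }
        }
        new("SuperpositionResult", rmsd = best@rmsd,
            rotation = best@rotation, translation = best@translation,
            mapping = as.integer(bestMap), exhaustive = TRUE)
    } else {
        g <- .greedyMapping(resA, resB, groupsA, groupsB)
        new("SuperpositionResult", rmsd = g$fit@rmsd,
            rotation = g$fit@rotation, translation = g$fit@translation,
            mapping = as.integer(g$mapping), exhaustive = FALSE)
    }
}
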