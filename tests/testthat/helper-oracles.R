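## Independent oracles used to freeze expected values. These deliberately
## re-derive results by brute force and share no code with the package
## internals beyond the public API they are checking against.

## All permutations of 1..n, own implementation.
oraclePerms <- function(n) {
    if (n == 0L) return(list(integer()))
    if (n == 1L) return(list(1L))
    out <- list()
    for (i in seq_len(n)) {
        rest <- oraclePerms(n - 1L)
        for (r in rest)
            out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
    }
    out
}

## Minimal RMSD over rotations by direct numerical optimisation over Euler
## angles (multi-start), with the optimal translation folded in. Independent
## of the closed-form SVD route.
oracleRotationRMSD <- function(p, q, nStarts = 12) {
    rotFromAngles <- function(a) {
        cx <- cos(a[1]); sx <- sin(a[1])
        cy <- cos(a[2]); sy <- sin(a[2])
        cz <- cos(a[3]); sz <- sin(a[3])
        Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
        Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
        Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
        Rz %*% Ry %*% Rx
    }
    obj <- function(a) {
        R <- rotFromAngles(a)
        t <- colMeans(q) - as.numeric(R %*% colMeans(p))
        resid <- sweep(tcrossprod(p, R), 2, t, "+") - q
        sqrt(mean(rowSums(resid^2)))
    }
    best <- Inf
    set.seed(424242)
    starts <- rbind(c(0, 0, 0),
                    matrix(stats::runif(3 * (nStarts - 1), -pi, pi),
                           ncol = 3))
    for (s in seq_len(nrow(starts))) {
        fit <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                            control = list(maxit = 2000,
                                           reltol = 1e-12))
        best <- min(best, fit$value)
    }
    best
}

## Exhaustive minimal site RMSD: enumerate every type-preserving residue
## bijection with own permutation code, superpose each with kabsch() (itself
## checked against oracleRotationRMSD) and take the minimum.
oracleSiteRMSD <- function(resA, resB) {
    groupsA <- split(seq_len(nrow(resA)), resA$code1)
    groupsB <- split(seq_len(nrow(resB)), resB$code1)
    stopifnot(identical(lengths(groupsA), lengths(groupsB)))
    pts <- function(res)
        rbind(as.matrix(res[, c("cax", "cay", "caz")]),
              as.matrix(res[, c("scx", "scy", "scz")]))
    permSets <- lapply(groupsA, function(g) oraclePerms(length(g)))
    idx <- expand.grid(lapply(permSets, seq_along))
    best <- Inf
    for (r in seq_len(nrow(idx))) {
        mapping <- integer(nrow(resA))
        for (tp in names(groupsA)) {
            perm <- permSets[[tp]][[idx[r, tp]]]
            mapping[groupsA[[tp]]] <- groupsB[[tp]][perm]
        }
        fit <- kabsch(pts(resA), pts(resB[mapping, , drop = FALSE]))
        best <- min(best, fit@rmsd)
    }
    best
}

## Brute-force site enumeration: scan every lattice point of the padded
## bounding box (same declared lattice convention: pad rounded up to whole
## steps), collect residues by direct distance tests (union of the two
## zone spheres when dt > 0), keep groups of >= 4, dedup residue sets.
## Returns the sorted unique residue-key sets.
oracleSiteSets <- function(res, st, rt, dt = 0) {
    pts <- as.matrix(res[, c("scx", "scy", "scz")])
    pad <- ceiling(rt / st - 1e-9) * st
    axes <- lapply(1:3, function(k) {
        lo <- min(pts[, k]); hi <- max(pts[, k])
        n <- floor((hi + pad - (lo - pad)) / st + 1e-9)
        (lo - pad) + st * (0:n)
    })
    dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    sets <- character()
    for (x in axes[[1]]) for (y in axes[[2]]) for (z in axes[[3]]) {
        ctr <- c(x, y, z)
        d <- sqrt(colSums((t(pts) - ctr)^2))
        if (sum(d <= rt + 1e-9) < 4L) next      # retention rule
        members <- which(d <= rt + 1e-9)
        sets <- c(sets, paste(sort(res$key[members]), collapse = "|"))
        if (dt > 0) {
            for (k in seq_len(7L)) {
                c1 <- ctr - dt * dirs[k, ]; c2 <- ctr + dt * dirs[k, ]
                d1 <- sqrt(colSums((t(pts) - c1)^2))
                d2 <- sqrt(colSums((t(pts) - c2)^2))
                mem <- which(d1 <= rt + 1e-9 | d2 <= rt + 1e-9)
                if (length(mem) >= 4L)
                    sets <- c(sets,
                              paste(sort(res$key[mem]), collapse = "|"))
            }
        }
    }
    sort(unique(sets))
}

siteSetsOf <- function(sites) {
    sort(unique(vapply(sites$residues, function(r)
        paste(sort(r$key), collapse = "|"), "")))
}

## Replay verification of the greedy clustering contract: every member is
## within rmsdt of its cluster's reference, and every founder exceeded
## rmsdt against all references of earlier clusters of its signature.
verifyClusteringReplay <- function(sites, clustering, rmsdt) {
    cl <- clustering$clusters
    mem <- clustering$members
    for (i in seq_len(nrow(mem))) {
        ref <- cl$referenceSiteId[cl$clusterId == mem$clusterId[i]]
        r <- siteRMSD(sites[sites$siteId == mem$siteId[i], ],
                      sites[sites$siteId == ref, ])@rmsd
        if (r > rmsdt + 1e-9) return(FALSE)
    }
    for (ci in seq_len(nrow(cl))) {
        founder <- cl$referenceSiteId[ci]
        earlier <- cl[cl$signature == cl$signature[ci] &
                          cl$ordinal < cl$ordinal[ci], ]
        for (ref in earlier$referenceSiteId) {
            r <- siteRMSD(sites[sites$siteId == founder, ],
                          sites[sites$siteId == ref, ])@rmsd
            if (r <= rmsdt) return(FALSE)
        }
    }
    TRUE
}
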