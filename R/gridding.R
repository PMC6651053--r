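#' Construct grid parameters
#'
#' @param st lattice spacing in angstrom (> 0). Smaller values make the
#'   exploration denser: a new virtual reference coordinate every
#'   \code{st} angstrom along each axis.
#' @param rt search radius in angstrom (> 0). Bounds the spatial extent
#'   of the residue arrangements searched: small radii find small sites.
#' @param dt zone displacement in angstrom (>= 0). When positive, each
#'   retained reference coordinate is expanded into seven two-center
#'   elliptical search zones displaced by \code{dt}; 0 keeps only
#'   spherical neighbourhoods.
#' @return a [GridParams-class] object.
#' @export
gridParams <- function(st, rt, dt = 0) {
    if (!is.numeric(st) || !is.numeric(rt) || !is.numeric(dt))
        stop("grid parameters must be numeric")
    new("GridParams", st = as.numeric(st), rt = as.numeric(rt),
        dt = as.numeric(dt))
}

.repPoints <- function(x, chain = NULL) {
    res <- if (is(x, "ProteinStructure")) x@residues else x
    if (!is.null(chain)) res <- res[res$chain == chain, , drop = FALSE]
    as.matrix(res[, c("scx", "scy", "scz")])
}

#' Bounding box of a chain's representative points
#'
#' Componentwise minimum and maximum over the side-chain-centroid
#' representative points; the virtual box from which the lattice of
#' reference coordinates is generated.
#'
#' @param x a [ProteinStructure-class] or a residue table (as returned by
#'   [residueTable()]).
#' @param chain optional chain to restrict to.
#' @return list with numeric(3) components \code{min} and \code{max}.
#' @export
boundingBox <- function(x, chain = NULL) {
    pts <- .repPoints(x, chain)
    if (nrow(pts) == 0L) stop("bounding box of an empty residue set")
    list(min = apply(pts, 2, min), max = apply(pts, 2, max))
}

## Zone displacement directions: the 3 coordinate axes plus the 4 body
## diagonals (unit length), giving the seven two-center zones.
.zoneDirections <- function() {
    d <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
    d / sqrt(rowSums(d^2))
}

#' Expand a reference coordinate into displaced search zones
#'
#' For a positive displacement \code{dt}, a retained reference coordinate
#' spawns seven elliptical (two-center) zones: the pair of virtual centers
#' \code{center - dt*u} and \code{center + dt*u} for each of the three
#' coordinate axes and the four body-diagonal unit vectors. A residue
#' belongs to a zone when its representative point lies within \code{rt}
#' of either center of the pair.
#'
#' @param center numeric(3), the reference coordinate (angstrom).
#' @param dt displacement in angstrom (> 0).
#' @return data.frame with columns zone (1..7), x1, y1, z1, x2, y2, z2 —
#'   the two centers of each pair, symmetric about \code{center}.
#' @examples
#' expandZones(c(0, 0, 0), dt = 2)[1, ]  # axis-x pair: (-2,0,0), (2,0,0)
#' @export
expandZones <- function(center, dt) {
    if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
        stop("'dt' must be a single positive displacement")
    if (length(center) != 3L) stop("'center' must be a 3-vector")
    u <- .zoneDirections()
    c1 <- sweep(-dt * u, 2, center, "+")
    c2 <- sweep(dt * u, 2, center, "+")
    data.frame(zone = seq_len(7L),
               x1 = c1[, 1], y1 = c1[, 2], z1 = c1[, 3],
               x2 = c2[, 1], y2 = c2[, 2], z2 = c2[, 3])
}

## Lattice coordinates along one axis. The pad is rounded up to a whole
## number of steps so that lattices at different rt (and at st/2) are
## nested sublattices anchored at the bounding-box minimum — this makes
## retention monotone in rt and refinement-consistent in st.
.axisCoords <- function(lo, hi, st, rt) {
    pad <- ceiling(rt / st - 1e-9) * st
    n <- floor((hi + pad - (lo - pad)) / st + 1e-9)
    (lo - pad) + st * (0:n)
}

#' Build the grid of virtual coordinates for one chain
#'
#' Fills the padded bounding box of the chain's representative points with
#' lattice reference coordinates spaced \code{st} apart and retains only
#' those with at least four residues within radius \code{rt} (membership
#' by side-chain centroid). The lattice is anchored at the bounding-box
#' minimum corner and padded by \code{ceiling(rt/st)*st} on every axis so
#' that surface sites remain reachable and results are exactly
#' translation-equivariant.
#'
#' @param x a [ProteinStructure-class] (after [filterSidechainless()]).
#' @param params a [GridParams-class].
#' @param chain chain identifier; defaults to the first chain.
#' @return a [VirtualGrid-class] with the retained points sorted by
#'   \code{gridId} (lexicographic over x, y, z lattice steps).
#' @export
buildGrid <- function(x, params, chain = NULL) {
    stopifnot(is(params, "GridParams"))
    validObject(params)
    if (is.null(chain)) chain <- chainIds(x)[1L]
    pts <- .repPoints(x, chain)
    if (nrow(pts) == 0L)
        stop("chain '", chain, "' has no residues")
    grid <- .retainedLattice(pts, params@st, params@rt)
    new("VirtualGrid", structureId = structureId(x), chainId = chain,
        params = params, points = grid)
}

## Core retention computation: counts residues within rt of every lattice
## point by accumulating, per residue, over its local cube of lattice
## indices; retains counts >= 4.
.retainedLattice <- function(pts, st, rt) {
    lo <- apply(pts, 2, min)
    hi <- apply(pts, 2, max)
    ax <- .axisCoords(lo[1], hi[1], st, rt)
    ay <- .axisCoords(lo[2], hi[2], st, rt)
    az <- .axisCoords(lo[3], hi[3], st, rt)
    nx <- length(ax); ny <- length(ay); nz <- length(az)
    counts <- array(0L, dim = c(nx, ny, nz))
    eps <- 1e-9
    for (i in seq_len(nrow(pts))) {
        p <- pts[i, ]
        ix <- which(abs(ax - p[1]) <= rt + eps)
        iy <- which(abs(ay - p[2]) <= rt + eps)
        iz <- which(abs(az - p[3]) <= rt + eps)
        if (!length(ix) || !length(iy) || !length(iz)) next
        dx2 <- (ax[ix] - p[1])^2
        dy2 <- (ay[iy] - p[2])^2
        dz2 <- (az[iz] - p[3])^2
        d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
        hit <- d2 <= rt^2 + eps
        counts[ix, iy, iz] <- counts[ix, iy, iz] + hit
    }
    keep <- which(counts >= 4L, arr.ind = TRUE)
    if (nrow(keep) == 0L)
        return(data.frame(gridId = integer(), x = numeric(), y = numeric(),
                          z = numeric(), nResidues = integer()))
    gridId <- (keep[, 1] - 1) * ny * nz + (keep[, 2] - 1) * nz + keep[, 3]
    ord <- order(gridId)
    keep <- keep[ord, , drop = FALSE]
    data.frame(gridId = as.integer(gridId[ord]),
               x = ax[keep[, 1]], y = ay[keep[, 2]], z = az[keep[, 3]],
               nResidues = as.integer(counts[keep]))
}
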