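## Brute-force validation oracle: 3D point clouds of stacked disc-shaped
## double bilayers and powder-averaged scattering via the Debye equation.

# slab regions (zlo, zhi, contrast, label) of one unit cell, centered on the
# lumen midplane; zero-width slabs are omitted
.unitCellSlabs <- function(geom, con, convention = "symmetric") {
  bnd <- boundaries(geom, convention)
  a <- bnd[["a"]]; b <- bnd[["b"]]; cc <- bnd[["c"]]; d <- bnd[["d"]]
  slabs <- list(
    list(zlo = -d, zhi = d, rho = con@rhoL, label = "lumen"),
    list(zlo = d, zhi = cc, rho = con@rhoH, label = "head"),
    list(zlo = -cc, zhi = -d, rho = con@rhoH, label = "head"),
    list(zlo = cc, zhi = b, rho = con@rhoT, label = "tail"),
    list(zlo = -b, zhi = -cc, rho = con@rhoT, label = "tail"),
    list(zlo = b, zhi = a, rho = con@rhoH, label = "head"),
    list(zlo = -a, zhi = -b, rho = con@rhoH, label = "head"))
  Filter(function(s) s$zhi - s$zlo > 0, slabs)
}

#' Build a disc-shaped double-bilayer unit cell as a point cloud
#'
#' Fills each slab region of one thylakoid unit cell (lumen, head layers,
#' tail layers) of a disc of radius `discRadius` with uniformly random
#' points. Point counts are allocated proportionally to region volume and
#' each point carries a scattering length `b = contrast * volume / count`,
#' so the total scattering length of every region equals its contrast times
#' its volume regardless of how `nPoints` is split. In-plane positions are
#' drawn uniformly in area (radius proportional to the square root of a
#' uniform deviate).
#'
#' @param geom a \linkS4class{BilayerGeometry}
#' @param con a \linkS4class{ContrastProfile}
#' @param nPoints total number of points in the cell, `>= 1`
#' @param discRadius disc radius in Angstrom, `> 0`
#' @param seed optional integer; when given, the RNG is seeded for a
#'   reproducible cloud and the seed recorded in the object
#' @return a \linkS4class{PointCloud} centered on the lumen midplane
#' @examples
#' geom <- BilayerGeometry(dH = 0, dT = 17, dL = 62)
#' con <- ContrastProfile(-1, -1, 0.33)
#' cloud <- buildUnitCell(geom, con, nPoints = 500, discRadius = 1000,
#'                        seed = 1)
#' @export
buildUnitCell <- function(geom, con, nPoints = 10000L, discRadius = 1000,
                          seed = NULL) {
  stopifnot(nPoints >= 1L, discRadius > 0)
  if (!is.null(seed)) set.seed(seed)
  slabs <- .unitCellSlabs(geom, con)
  widths <- vapply(slabs, function(s) s$zhi - s$zlo, numeric(1))
  vols <- pi * discRadius^2 * widths
  # largest-remainder allocation of points to regions
  raw <- nPoints * vols / sum(vols)
  counts <- floor(raw)
  rem <- as.integer(nPoints - sum(counts))
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  counts <- as.integer(counts)

  coords <- matrix(numeric(0), ncol = 3)
  bs <- numeric(0)
  labels <- character(0)
  for (k in seq_along(slabs)) {
    nk <- counts[k]
    if (nk == 0L) next
    r <- discRadius * sqrt(runif(nk))
    phi <- runif(nk, 0, 2 * pi)
    z <- runif(nk, slabs[[k]]$zlo, slabs[[k]]$zhi)
    coords <- rbind(coords, cbind(r * cos(phi), r * sin(phi), z))
    bs <- c(bs, rep(slabs[[k]]$rho * vols[k] / nk, nk))
    labels <- c(labels, rep(slabs[[k]]$label, nk))
  }
  new("PointCloud", coords = coords, b = bs, region = labels,
      discRadius = discRadius, seed = if (is.null(seed)) NA_real_ else seed)
}

#' Stack unit cells along the membrane normal
#'
#' Returns `N` translated copies of a unit-cell cloud at spacing `D` along z.
#' No fluctuations, polydispersity or resolution effects are applied; the
#' stacked cloud is a rigid ideal lattice. A warning is issued when `D` is
#' smaller than the z extent of the unit cell (overlapping membranes).
#'
#' @param cell a \linkS4class{PointCloud} (one unit cell)
#' @param N number of cells, integer `>= 1`
#' @param D repeat distance in Angstrom
#' @return a \linkS4class{PointCloud} with `N * nrow(cell)` points
#' @export
stackCells <- function(cell, N, D) {
  stopifnot(N >= 1)
  N <- as.integer(N)
  if (N == 1L) return(cell)
  zext <- diff(range(cell@coords[, 3]))
  if (D < zext)
    warning(sprintf(
      "repeat distance D = %g A is smaller than the unit-cell thickness %g A; membranes overlap",
      D, zext))
  nc <- nrow(cell@coords)
  coords <- cell@coords[rep(seq_len(nc), N), , drop = FALSE]
  coords[, 3] <- coords[, 3] + rep((seq_len(N) - 1) * D, each = nc)
  new("PointCloud", coords = coords, b = rep(cell@b, N),
      region = rep(cell@region, N), discRadius = cell@discRadius,
      seed = cell@seed)
}

#' Powder-averaged intensity by the Debye equation
#'
#' Computes \deqn{I(q) = \sum_i\sum_j b_i b_j \frac{\sin(q r_{ij})}{q r_{ij}}}
#' over all point pairs (the `i = j` terms contribute `b_i^2`). The Debye
#' sum is the exact orientational average for a rigid assembly, which makes
#' it a brute-force oracle for the analytic model.
#'
#' Two engines are available: `"exact"` evaluates every pair at every q;
#' `"binned"` accumulates pair distances into bins of width `binWidth` and
#' expands the sinc kernel to first order about each bin centre, reducing the
#' cost from `O(n^2 nq)` to `O(n^2 + nbins * nq)` with truncation error far
#' below Monte-Carlo noise for sub-Angstrom bins. `"auto"` picks `"exact"`
#' up to `maxPairsExact` pairs and `"binned"` beyond.
#'
#' @param cloud a non-empty \linkS4class{PointCloud}
#' @param q wavevector grid, Angstrom^-1; default 200 bins in
#'   `[0.005, 0.3]`
#' @param method `"auto"`, `"exact"` or `"binned"`
#' @param binWidth distance bin width (Angstrom) for the binned engine
#' @param maxPairsExact pair-count ceiling for the exact engine; requesting
#'   `method = "exact"` above it is refused with a suggestion to reduce
#'   `nPoints` or use the binned engine
#' @return intensities, same length as `q`
#' @export
debyeIntensity <- function(cloud, q = defaultQGrid(),
                           method = c("auto", "exact", "binned"),
                           binWidth = 0.25, maxPairsExact = 2e7) {
  method <- match.arg(method)
  n <- nrow(cloud@coords)
  if (n == 0L) stop("point cloud is empty")
  stopifnot(all(q > 0))
  pairs <- n * (n - 1) / 2
  if (method == "auto") method <- if (pairs <= maxPairsExact) "exact" else "binned"
  if (method == "exact" && pairs > maxPairsExact)
    stop(sprintf(paste0(
      "exact Debye sum over %.3g pairs exceeds the ceiling of %.3g; ",
      "reduce nPoints or use method = \"binned\""), pairs, maxPairsExact))
  if (method == "exact")
    debyeSumExact(cloud@coords, cloud@b, q)
  else
    debyeSumBinned(cloud@coords, cloud@b, q, binWidth)
}

#' Default simulation q grid
#'
#' 200 equally spaced q bins covering 0.005 to 0.3 Angstrom^-1, the standard
#' small-angle window used throughout the package's simulations.
#'
#' @param n number of bins
#' @param qmin,qmax grid limits, Angstrom^-1
#' @return numeric vector of length `n`
#' @export
defaultQGrid <- function(n = 200L, qmin = 0.005, qmax = 0.3) {
  seq(qmin, qmax, length.out = n)
}
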