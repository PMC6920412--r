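#' @import methods
#' @importFrom stats dnorm integrate median optimize qnorm rnorm runif setNames
#' @importFrom utils modifyList read.table write.table packageVersion
#' @importFrom Rcpp sourceCpp
#' @useDynLib thylakoidSAS, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Parameter value classes
## ---------------------------------------------------------------------------

#' Double-bilayer geometry
#'
#' Cross-sectional geometry of a single thylakoid unit cell: two lipid
#' bilayers (each with headgroup layers of thickness `dH` and a tail region of
#' thickness `2 * dT`) enclosing an aqueous lumen of thickness `dL`. All
#' lengths are in Angstrom. Setting `dH = 0` collapses each membrane to a
#' single box ("single-box membrane" mode used for neutron fits, where
#' headgroup and tailgroup regions are not resolved).
#'
#' @slot dH headgroup layer thickness (one leaflet) in Angstrom; `>= 0`
#' @slot dT tail half-thickness in Angstrom: the tail box of one bilayer
#'   spans `2 * dT`; `> 0`
#' @slot dL lumen thickness in Angstrom; `> 0`
#'
#' @seealso [boundaries()], [doubleBilayerFormFactor()]
#' @export
setClass("BilayerGeometry",
  representation(dH = "numeric", dT = "numeric", dL = "numeric"))

setValidity("BilayerGeometry", function(object) {
  msg <- character()
  for (s in c("dH", "dT", "dL")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@dH < 0) msg <- c(msg, "'dH' must be >= 0")
  if (object@dT <= 0) msg <- c(msg, "'dT' must be > 0")
  if (object@dL <= 0) msg <- c(msg, "'dL' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param dH,dT,dL thicknesses in Angstrom, see slot documentation.
#' @return `BilayerGeometry()` returns a validated \linkS4class{BilayerGeometry}.
#' @examples
#' geom <- BilayerGeometry(dH = 5, dT = 15, dL = 60)
#' boundaries(geom)
#' @rdname BilayerGeometry-class
#' @export
BilayerGeometry <- function(dH = 0, dT, dL) {
  new("BilayerGeometry", dH = as.numeric(dH), dT = as.numeric(dT),
      dL = as.numeric(dL))
}

#' Contrast profile of the double bilayer
#'
#' Scattering-length-density contrasts of the three distinguishable regions
#' relative to the inter-thylakoid (cytoplasmic) liquid, whose contrast is 0
#' by definition. In relative fitting mode the tail contrast is fixed to -1
#' and an overall scale parameter absorbs absolute contrast and concentration.
#'
#' @slot rhoH headgroup contrast (arbitrary units or Angstrom^-2)
#' @slot rhoT tail contrast
#' @slot rhoL lumen contrast
#' @export
setClass("ContrastProfile",
  representation(rhoH = "numeric", rhoT = "numeric", rhoL = "numeric"))

setValidity("ContrastProfile", function(object) {
  ok <- vapply(c("rhoH", "rhoT", "rhoL"),
               function(s) length(slot(object, s)) == 1L &&
                 is.finite(slot(object, s)), logical(1))
  if (all(ok)) TRUE else "all contrasts must be finite scalars"
})

#' @param rhoH,rhoT,rhoL region contrasts, see slot documentation.
#' @rdname ContrastProfile-class
#' @export
ContrastProfile <- function(rhoH = -1, rhoT = -1, rhoL = 0) {
  new("ContrastProfile", rhoH = as.numeric(rhoH), rhoT = as.numeric(rhoT),
      rhoL = as.numeric(rhoL))
}

#' Stack (lattice) parameters
#'
#' Parameters of the one-dimensional lamellar stack: repeat distance `D`
#' (center-to-center spacing of consecutive thylakoids, Angstrom), number of
#' lamellae `N` (may be fractional; intensities are then linearly interpolated
#' between the bracketing integers) and the dimensionless Caille parameter
#' `etaCP` measuring thermal layer fluctuations (0 = rigid flat sheets).
#'
#' @slot D repeat distance in Angstrom, `> 0`
#' @slot N number of lamellae, `>= 1`
#' @slot etaCP Caille parameter, `>= 0`
#' @export
setClass("StackParams",
  representation(D = "numeric", N = "numeric", etaCP = "numeric"))

setValidity("StackParams", function(object) {
  msg <- character()
  for (s in c("D", "N", "etaCP")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@D <= 0) msg <- c(msg, "'D' must be > 0")
  if (object@N < 1) msg <- c(msg, "'N' must be >= 1")
  if (object@etaCP < 0) msg <- c(msg, "'etaCP' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param D,N,etaCP stack parameters, see slot documentation.
#' @rdname StackParams-class
#' @export
StackParams <- function(D, N, etaCP = 0) {
  new("StackParams", D = as.numeric(D), N = as.numeric(N),
      etaCP = as.numeric(etaCP))
}

#' Background parameters
#'
#' Background model `Ib(q) = B + C * q^-n`: a flat incoherent term plus a
#' power law accounting for cell-wall scattering, whose exponent is expected
#' to stay close to 2 (default fit bounds 1.5--2.6). The power-law amplitude
#' is stored in the slot `Camp` (a slot literally named `C` is not portable
#' in S4); the constructor still takes it as `C`.
#'
#' @slot B flat background, `>= 0`
#' @slot Camp power-law amplitude `C`, `>= 0`
#' @slot n power-law exponent (dimensionless)
#' @export
setClass("BackgroundParams",
  representation(B = "numeric", Camp = "numeric", n = "numeric"))

setValidity("BackgroundParams", function(object) {
  msg <- character()
  for (s in c("B", "Camp", "n")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@B < 0) msg <- c(msg, "'B' must be >= 0")
  if (object@Camp < 0) msg <- c(msg, "'C' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param B,C,n background parameters, see slot documentation.
#' @rdname BackgroundParams-class
#' @export
BackgroundParams <- function(B = 0, C = 0, n = 2) {
  new("BackgroundParams", B = as.numeric(B), Camp = as.numeric(C),
      n = as.numeric(n))
}

#' Gaussian polydispersity specification
#'
#' Gaussian size distributions for the lumen thickness (`sigmaL`) and the
#' repeat distance (`sigmaD`), evaluated on a fixed symmetric grid of
#' `nQuad` points truncated at `cutoff` standard deviations. Grid points that
#' would produce invalid geometries are dropped and the weights renormalized.
#'
#' @slot sigmaL std. deviation of the lumen thickness, Angstrom, `>= 0`
#' @slot sigmaD std. deviation of the repeat distance, Angstrom, `>= 0`
#' @slot nQuad odd number of distribution points, `>= 1`
#' @slot cutoff truncation in units of sigma, `> 0`
#' @export
setClass("PolydispersitySpec",
  representation(sigmaL = "numeric", sigmaD = "numeric", nQuad = "integer",
                 cutoff = "numeric"))

setValidity("PolydispersitySpec", function(object) {
  msg <- character()
  if (object@sigmaL < 0) msg <- c(msg, "'sigmaL' must be >= 0")
  if (object@sigmaD < 0) msg <- c(msg, "'sigmaD' must be >= 0")
  if (object@nQuad < 1L || object@nQuad %% 2L == 0L)
    msg <- c(msg, "'nQuad' must be odd and >= 1")
  if (object@cutoff <= 0) msg <- c(msg, "'cutoff' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param sigmaL,sigmaD,nQuad,cutoff see slot documentation.
#' @rdname PolydispersitySpec-class
#' @export
PolydispersitySpec <- function(sigmaL = 0, sigmaD = 0, nQuad = 21L,
                               cutoff = 3) {
  new("PolydispersitySpec", sigmaL = as.numeric(sigmaL),
      sigmaD = as.numeric(sigmaD), nQuad = as.integer(nQuad),
      cutoff = as.numeric(cutoff))
}

#' Instrument resolution specification
#'
#' Gaussian wavevector resolution. `sigmaQ` is either a single relative or
#' absolute width applied everywhere or a per-point vector (typically read
#' from the fourth column of a reduced data file). `sigmaQ = 0` means no
#' smearing.
#'
#' @slot sigmaQ per-point Gaussian std. deviation(s) of q, Angstrom^-1,
#'   all `>= 0`
#' @slot nQuad odd number of quadrature nodes
#' @slot cutoff truncation in units of sigma
#' @export
setClass("ResolutionSpec",
  representation(sigmaQ = "numeric", nQuad = "integer", cutoff = "numeric"))

setValidity("ResolutionSpec", function(object) {
  msg <- character()
  if (length(object@sigmaQ) < 1L || any(!is.finite(object@sigmaQ)) ||
      any(object@sigmaQ < 0))
    msg <- c(msg, "'sigmaQ' must be finite and >= 0")
  if (object@nQuad < 1L || object@nQuad %% 2L == 0L)
    msg <- c(msg, "'nQuad' must be odd and >= 1")
  if (object@cutoff <= 0) msg <- c(msg, "'cutoff' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param sigmaQ,nQuad,cutoff see slot documentation.
#' @rdname ResolutionSpec-class
#' @export
ResolutionSpec <- function(sigmaQ = 0, nQuad = 21L, cutoff = 3) {
  new("ResolutionSpec", sigmaQ = as.numeric(sigmaQ), nQuad = as.integer(nQuad),
      cutoff = as.numeric(cutoff))
}

#' Full stacked double-bilayer scattering model
#'
#' Bundles geometry, contrasts, stack parameters, background, an overall
#' intensity scale and a polydispersity specification into one model object
#' that can be evaluated with [modelIntensity()].
#'
#' @slot geometry a \linkS4class{BilayerGeometry}
#' @slot contrasts a \linkS4class{ContrastProfile}
#' @slot stack a \linkS4class{StackParams}
#' @slot background a \linkS4class{BackgroundParams}
#' @slot scale overall intensity scale, `> 0`
#' @slot poly a \linkS4class{PolydispersitySpec}
#' @export
setClass("StackModel",
  representation(geometry = "BilayerGeometry", contrasts = "ContrastProfile",
                 stack = "StackParams", background = "BackgroundParams",
                 scale = "numeric", poly = "PolydispersitySpec"))

setValidity("StackModel", function(object) {
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    return("'scale' must be a positive finite scalar")
  TRUE
})

#' @param geometry,contrasts,stack,background,scale,poly see slot
#'   documentation.
#' @rdname StackModel-class
#' @export
StackModel <- function(geometry, contrasts = ContrastProfile(),
                       stack, background = BackgroundParams(), scale = 1,
                       poly = PolydispersitySpec()) {
  new("StackModel", geometry = geometry, contrasts = contrasts, stack = stack,
      background = background, scale = as.numeric(scale), poly = poly)
}

## ---------------------------------------------------------------------------
## Data classes
## ---------------------------------------------------------------------------

#' One-dimensional reduced scattering curve
#'
#' A measured or synthetic small-angle scattering curve: strictly increasing
#' wavevector `q` (Angstrom^-1), intensity `I` (absolute or arbitrary units),
#' intensity uncertainty `sigmaI > 0` and optionally a per-point wavevector
#' resolution `sigmaQ`. `metadata` carries free-form provenance (sample label,
#' D2O fraction, ground-truth parameters of synthetic curves, ...).
#'
#' @slot q wavevector values, strictly increasing, all `> 0`
#' @slot intensity measured intensities
#' @slot sigmaI intensity uncertainties, all `> 0`
#' @slot sigmaQ per-point q resolution; `numeric(0)` when absent
#' @slot radiation `"neutron"` or `"xray"`
#' @slot metadata named list
#' @export
setClass("ScatteringCurve",
  representation(q = "numeric", intensity = "numeric", sigmaI = "numeric",
                 sigmaQ = "numeric", radiation = "character",
                 metadata = "list"))

setValidity("ScatteringCurve", function(object) {
  msg <- character()
  n <- length(object@q)
  if (n == 0L) msg <- c(msg, "curve must contain at least one point")
  if (any(object@q <= 0)) msg <- c(msg, "all q must be > 0")
  if (n > 1L && any(diff(object@q) <= 0))
    msg <- c(msg, "q must be strictly increasing")
  if (length(object@intensity) != n)
    msg <- c(msg, "'intensity' must match length of 'q'")
  if (length(object@sigmaI) != n || any(object@sigmaI <= 0))
    msg <- c(msg, "'sigmaI' must match length of 'q' and be > 0")
  if (length(object@sigmaQ) != 0L &&
      (length(object@sigmaQ) != n || any(object@sigmaQ < 0)))
    msg <- c(msg, "'sigmaQ' must be empty or match length of 'q' with values >= 0")
  if (length(object@radiation) != 1L ||
      !object@radiation %in% c("neutron", "xray"))
    msg <- c(msg, "'radiation' must be \"neutron\" or \"xray\"")
  if (length(msg)) msg else TRUE
})

#' @param q,intensity,sigmaI,sigmaQ,radiation,metadata see slot documentation.
#' @rdname ScatteringCurve-class
#' @export
ScatteringCurve <- function(q, intensity, sigmaI, sigmaQ = numeric(0),
                            radiation = "neutron", metadata = list()) {
  new("ScatteringCurve", q = as.numeric(q), intensity = as.numeric(intensity),
      sigmaI = as.numeric(sigmaI), sigmaQ = as.numeric(sigmaQ),
      radiation = radiation, metadata = metadata)
}

#' Labelled 3D point cloud for Debye-equation simulation
#'
#' Random points filling the slab regions of one or more stacked disc-shaped
#' double bilayers, each carrying a scattering length `b` such that the total
#' scattering length of a region equals its contrast times its volume.
#'
#' @slot coords n x 3 matrix of coordinates (Angstrom); z is the stacking
#'   normal
#' @slot b per-point scattering lengths
#' @slot region per-point region label (`"head"`, `"tail"`, `"lumen"`)
#' @slot discRadius disc radius used during construction (Angstrom)
#' @slot seed RNG seed recorded at construction, or `NA`
#' @export
setClass("PointCloud",
  representation(coords = "matrix", b = "numeric", region = "character",
                 discRadius = "numeric", seed = "numeric"))

setValidity("PointCloud", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "'coords' must have 3 columns")
  n <- nrow(object@coords)
  if (length(object@b) != n) msg <- c(msg, "'b' must match rows of 'coords'")
  if (length(object@region) != n)
    msg <- c(msg, "'region' must match rows of 'coords'")
  if (n > 0L) {
    r2 <- object@coords[, 1]^2 + object@coords[, 2]^2
    if (any(r2 > object@discRadius^2 * (1 + 1e-12)))
      msg <- c(msg, "points fall outside the declared disc radius")
  }
  if (length(msg)) msg else TRUE
})

#' Fit result
#'
#' Output of [stagedFit()]: best-fit parameter vector, fixed/free flags,
#' chi-square statistics, profile-likelihood trust intervals (when computed),
#' deduced quantities and a convergence log.
#'
#' @slot par named numeric vector of best-fit parameter values
#' @slot fixed named logical vector; `TRUE` entries were held fixed
#' @slot lower,upper named bound vectors actually used
#' @slot chisq chi-square at the optimum
#' @slot redChisq reduced chi-square (chisq / (nobs - nfree))
#' @slot nobs number of data points used
#' @slot intervals matrix with columns `lower`, `upper` (profile-likelihood
#'   trust region per free parameter), possibly with 0 rows
#' @slot deduced named list of deduced quantities (`dIT`, `dTM`, ...)
#' @slot trace data.frame logging objective values of accepted stages
#' @slot curve the fitted \linkS4class{ScatteringCurve}
#' @slot fittedIntensity model intensity at the data points
#' @export
setClass("FitResult",
  representation(par = "numeric", fixed = "logical", lower = "numeric",
                 upper = "numeric", chisq = "numeric", redChisq = "numeric",
                 nobs = "integer", intervals = "matrix", deduced = "list",
                 trace = "data.frame", curve = "ScatteringCurve",
                 fittedIntensity = "numeric"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "BilayerGeometry", function(object) {
  bnd <- boundaries(object)
  cat("BilayerGeometry: dH =", object@dH, "A, dT =", object@dT,
      "A, dL =", object@dL, "A\n")
  cat("  boundaries a/b/c/d:", sprintf("%.3f", bnd), "A\n")
})

setMethod("show", "StackModel", function(object) {
  cat("StackModel\n")
  cat(sprintf("  geometry : dH=%.3g dT=%.3g dL=%.3g A\n",
              object@geometry@dH, object@geometry@dT, object@geometry@dL))
  cat(sprintf("  contrasts: rhoH=%.3g rhoT=%.3g rhoL=%.3g\n",
              object@contrasts@rhoH, object@contrasts@rhoT,
              object@contrasts@rhoL))
  cat(sprintf("  stack    : D=%.4g A  N=%.3g  etaCP=%.3g\n",
              object@stack@D, object@stack@N, object@stack@etaCP))
  cat(sprintf("  backgrnd : B=%.3g C=%.3g n=%.3g   scale=%.3g\n",
              object@background@B, object@background@Camp, object@background@n,
              object@scale))
  cat(sprintf("  polydisp : sigmaL=%.3g sigmaD=%.3g A (nQuad=%d, cutoff=%g)\n",
              object@poly@sigmaL, object@poly@sigmaD, object@poly@nQuad,
              object@poly@cutoff))
})

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve (%s): %d points, q in [%.4g, %.4g] 1/A%s\n",
              object@radiation, length(object@q), min(object@q),
              max(object@q),
              if (length(object@sigmaQ)) ", with q-resolution column" else ""))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points, disc radius %g A, total b = %.6g\n",
              nrow(object@coords), object@discRadius, sum(object@b)))
  print(table(object@region))
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult\n")
  free <- !object@fixed[names(object@par)]
  for (p in names(object@par)) {
    cat(sprintf("  %-8s %12.6g %s\n", p, object@par[[p]],
                if (object@fixed[[p]]) "(fixed)" else ""))
  }
  cat(sprintf("  chi-square = %.6g, reduced = %.6g (n = %d, free = %d)\n",
              object@chisq, object@redChisq, object@nobs, sum(free)))
  if (length(object@deduced))
    cat("  deduced:",
        paste(sprintf("%s = %.4g", names(object@deduced),
                      unlist(object@deduced)), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Accessors for scattering curves and fit results
#'
#' @param x a \linkS4class{ScatteringCurve} or \linkS4class{FitResult}
#' @return numeric vectors (or named vectors/lists for fit accessors).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setMethod("qValues", "ScatteringCurve", function(x) x@q)

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "ScatteringCurve", function(x) x@intensity)

#' @rdname accessors
#' @export
setGeneric("intensityError", function(x) standardGeneric("intensityError"))
#' @rdname accessors
#' @export
setMethod("intensityError", "ScatteringCurve", function(x) x@sigmaI)

#' @rdname accessors
#' @export
setGeneric("qResolution", function(x) standardGeneric("qResolution"))
#' @rdname accessors
#' @export
setMethod("qResolution", "ScatteringCurve", function(x) x@sigmaQ)

#' @rdname accessors
#' @export
setGeneric("curveMetadata", function(x) standardGeneric("curveMetadata"))
#' @rdname accessors
#' @export
setMethod("curveMetadata", "ScatteringCurve", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("bestFit", function(x) standardGeneric("bestFit"))
#' @rdname accessors
#' @export
setMethod("bestFit", "FitResult", function(x) x@par)

#' @rdname accessors
#' @export
setGeneric("chiSquareValue", function(x) standardGeneric("chiSquareValue"))
#' @rdname accessors
#' @export
setMethod("chiSquareValue", "FitResult", function(x) x@chisq)

#' @rdname accessors
#' @export
setGeneric("deducedQuantities", function(x) standardGeneric("deducedQuantities"))
#' @rdname accessors
#' @export
setMethod("deducedQuantities", "FitResult", function(x) x@deduced)

#' @rdname accessors
#' @export
setGeneric("trustIntervals", function(x) standardGeneric("trustIntervals"))
#' @rdname accessors
#' @export
setMethod("trustIntervals", "FitResult", function(x) x@intervals)
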