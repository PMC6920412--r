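## Analytic scattering model for a stack of double bilayers:
## box-profile form factor, finite-N Caille structure factor, combined
## powder-averaged lamellar intensity and the flat + power-law background.

# Euler-Mascheroni constant used in the Caille fluctuation term
.EULER_GAMMA <- 0.5772156649

#' Region boundaries of the double-bilayer profile
#'
#' Converts the thicknesses of a \linkS4class{BilayerGeometry} into the four
#' half-profile boundary distances `a > b > c > d > 0` (Angstrom) measured
#' from the lumen midplane: the lumen spans `|z| < d`, the inner headgroups
#' `d < |z| < c`, the tails `c < |z| < b` and the outer headgroups
#' `b < |z| < a`.
#'
#' The default `"symmetric"` convention uses `c = dL/2 + dH`, which makes both
#' headgroup regions `dH` wide and the tail region `2*dT` wide (so
#' `a - b = c - d = dH` and `b - c = 2*dT`). The alternative
#' `convention = "printed"` reproduces a published variant with
#' `c = dL + dH`; it breaks that symmetry (the tail width then depends on
#' `dL`) and is provided for comparison only.
#'
#' @param geom a \linkS4class{BilayerGeometry}
#' @param convention `"symmetric"` (default) or `"printed"`, see Details
#' @return named numeric vector `c(a =, b =, c =, d =)` in Angstrom
#' @examples
#' boundaries(BilayerGeometry(dH = 5, dT = 15, dL = 60))
#' @export
boundaries <- function(geom, convention = c("symmetric", "printed")) {
  convention <- match.arg(convention)
  validObject(geom)
  dH <- geom@dH; dT <- geom@dT; dL <- geom@dL
  d <- dL / 2
  cc <- if (convention == "symmetric") dL / 2 + dH else dL + dH
  b <- dL / 2 + 2 * dT + dH
  a <- dL / 2 + 2 * dT + 2 * dH
  c(a = a, b = b, c = cc, d = d)
}

#' Scattering amplitude of a single box
#'
#' One-dimensional Fourier amplitude of a centered box of half-width `delta`
#' and uniform contrast `deltaRho`: `A(q) = (deltaRho / q) * 2 * sin(q *
#' delta)`, with the small-q limit `2 * deltaRho * delta` substituted where
#' `q * delta` underflows. Squaring gives the box form factor.
#'
#' @param q wavevector(s), Angstrom^-1, `>= 0`
#' @param delta box half-width, Angstrom
#' @param deltaRho box contrast
#' @return amplitude, same length as `q`
#' @export
boxAmplitude <- function(q, delta, deltaRho = 1) {
  stopifnot(all(q >= 0), delta >= 0)
  out <- numeric(length(q))
  tiny <- q * delta < 1e-8
  out[tiny] <- 2 * deltaRho * delta
  out[!tiny] <- (deltaRho / q[!tiny]) * 2 * sin(q[!tiny] * delta)
  out
}

# Fourier amplitude of the full symmetric double-bilayer profile (the
# quantity whose square, times 4/q^2 folding, is the form factor).
.profileAmplitudeSum <- function(q, bnd, con) {
  con@rhoH * (sin(q * bnd[["a"]]) - sin(q * bnd[["b"]]) +
                sin(q * bnd[["c"]]) - sin(q * bnd[["d"]])) +
    con@rhoT * (sin(q * bnd[["b"]]) - sin(q * bnd[["c"]])) +
    con@rhoL * sin(q * bnd[["d"]])
}

#' Double-bilayer form factor
#'
#' Form factor of a single thylakoid unit cell built from symmetric boxes
#' (outer headgroups, tails, inner headgroups, lumen), relative to the
#' inter-thylakoid liquid:
#' \deqn{P(q) = \frac{4}{q^2}\left[\Delta\rho_H(\sin qa - \sin qb + \sin qc -
#'   \sin qd) + \Delta\rho_T(\sin qb - \sin qc) +
#'   \Delta\rho_L \sin qd\right]^2}
#' At `q = 0` the analytic limit
#' `4 * (2 dH rhoH + 2 dT rhoT + dL/2 rhoL)^2` is returned.
#'
#' @param q wavevector(s), Angstrom^-1, `>= 0`
#' @param geom a \linkS4class{BilayerGeometry}
#' @param con a \linkS4class{ContrastProfile}
#' @param convention boundary convention passed to [boundaries()]
#' @return `P(q) >= 0`, same length as `q`
#' @examples
#' geom <- BilayerGeometry(dH = 5, dT = 15, dL = 60)
#' con <- ContrastProfile(rhoH = -1, rhoT = -1, rhoL = 0.3)
#' doubleBilayerFormFactor(c(0.01, 0.05), geom, con)
#' @export
doubleBilayerFormFactor <- function(q, geom, con,
                                    convention = c("symmetric", "printed")) {
  stopifnot(all(q >= 0))
  bnd <- boundaries(geom, match.arg(convention))
  out <- numeric(length(q))
  tiny <- q * bnd[["a"]] < 1e-7
  if (any(tiny)) {
    amp0 <- con@rhoH * (bnd[["a"]] - bnd[["b"]] + bnd[["c"]] - bnd[["d"]]) +
      con@rhoT * (bnd[["b"]] - bnd[["c"]]) + con@rhoL * bnd[["d"]]
    out[tiny] <- 4 * amp0^2
  }
  qq <- q[!tiny]
  out[!tiny] <- (4 / qq^2) * .profileAmplitudeSum(qq, bnd, con)^2
  out
}

#' Caille fluctuation exponent
#'
#' Layer-displacement correlation term of the modified Caille structure
#' factor: `alpha(n) = etaCP / (4 pi^2) * (log(pi * n) + gammaE)` with
#' `gammaE` the Euler-Mascheroni constant. `etaCP = 0` corresponds to
#' perfectly ordered rigid flat sheets.
#'
#' @param n layer separation index (positive integer(s))
#' @param etaCP Caille parameter, `>= 0`
#' @return alpha(n), same length as `n`
#' @export
cailleAlpha <- function(n, etaCP) {
  if (any(n < 1)) stop("'n' must be >= 1")
  stopifnot(etaCP >= 0)
  etaCP / (4 * pi^2) * (log(pi * n) + .EULER_GAMMA)
}

# Structure factor at a single integer N (vectorized over q)
.structureFactorInt <- function(q, D, N, etaCP) {
  s <- rep(1, length(q))
  if (N >= 2L) {
    for (n in seq_len(N - 1L)) {
      an <- cailleAlpha(n, etaCP)
      s <- s + 2 * (1 - n / N) * cos(n * q * D) * exp(-q^2 * D^2 * an)
    }
  }
  s
}

#' Finite-stack Caille structure factor
#'
#' Structure factor of a finite stack of `N` lamellae with repeat distance
#' `D`, assuming Gaussian fluctuations of each layer around its lattice
#' position:
#' \deqn{S(q) = 1 + 2\sum_{n=1}^{N-1}\left(1 - \frac{n}{N}\right)
#'   \cos(nqD)\,e^{-q^2 D^2 \alpha(n)}}
#' For non-integer `N` the two bracketing integer stacks are evaluated and
#' the results interpolated linearly by the fractional part, which keeps the
#' fit surface continuous in `N`.
#'
#' @param q wavevector(s), Angstrom^-1
#' @param sp a \linkS4class{StackParams}
#' @return `S(q) > 0`, same length as `q`
#' @examples
#' structureFactor(2 * pi / 600, StackParams(D = 600, N = 4, etaCP = 0))
#' @export
structureFactor <- function(q, sp) {
  validObject(sp)
  Nlo <- floor(sp@N)
  frac <- sp@N - Nlo
  s <- .structureFactorInt(q, sp@D, as.integer(Nlo), sp@etaCP)
  if (frac > 0) {
    shi <- .structureFactorInt(q, sp@D, as.integer(Nlo) + 1L, sp@etaCP)
    s <- (1 - frac) * s + frac * shi
  }
  s
}

#' Background intensity
#'
#' Evaluates `Ib(q) = B + C * q^-n`.
#'
#' @param q wavevector(s), Angstrom^-1, `> 0`
#' @param bg a \linkS4class{BackgroundParams}
#' @return background intensity, same length as `q`
#' @export
backgroundIntensity <- function(q, bg) {
  validObject(bg)
  bg@B + bg@Camp * q^(-bg@n)
}

#' Powder-averaged lamellar intensity
#'
#' Monodisperse model intensity of the stacked double-bilayer system,
#' \deqn{I(q) = \mathrm{scale}\cdot\frac{2\pi P(q) S(q)}{D q^2} + B + Cq^{-n}}
#' combining the unit-cell form factor [doubleBilayerFormFactor()], the
#' stack structure factor [structureFactor()] and the background.
#'
#' @param q wavevector(s), Angstrom^-1, `> 0`
#' @param geom a \linkS4class{BilayerGeometry}
#' @param con a \linkS4class{ContrastProfile}
#' @param sp a \linkS4class{StackParams}
#' @param bg a \linkS4class{BackgroundParams}
#' @param scale overall intensity scale
#' @param convention boundary convention passed to [boundaries()]
#' @return intensity, same length as `q`
#' @export
lamellarIntensity <- function(q, geom, con, sp, bg = BackgroundParams(),
                              scale = 1,
                              convention = c("symmetric", "printed")) {
  if (any(q <= 0)) stop("'q' must be > 0")
  validObject(sp)
  if (sp@D <= 0) stop("'D' must be > 0")
  p <- doubleBilayerFormFactor(q, geom, con, convention = match.arg(convention))
  s <- structureFactor(q, sp)
  scale * 2 * pi * p * s / (sp@D * q^2) + backgroundIntensity(q, bg)
}
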