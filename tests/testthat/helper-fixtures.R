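# shared fixtures and independent oracles used across test files

refGeometry <- function() BilayerGeometry(dH = 5, dT = 15, dL = 60)
refContrasts <- function() ContrastProfile(rhoH = -0.8, rhoT = -1, rhoL = 0.3)

# independent quadrature oracle for the double-bilayer form factor: numerical
# cosine transform of the piecewise contrast profile, integrated region by
# region with stats::integrate (never touches the analytic sine closed form)
formFactorQuadrature <- function(q, geom, con) {
  bnd <- boundaries(geom)
  regions <- list(
    list(lo = 0, hi = bnd[["d"]], rho = con@rhoL),
    list(lo = bnd[["d"]], hi = bnd[["c"]], rho = con@rhoH),
    list(lo = bnd[["c"]], hi = bnd[["b"]], rho = con@rhoT),
    list(lo = bnd[["b"]], hi = bnd[["a"]], rho = con@rhoH))
  vapply(q, function(qq) {
    # symmetric profile: A(q) = 2 * int_0^a rho(z) cos(qz) dz
    amp <- 2 * sum(vapply(regions, function(r) {
      if (r$hi <= r$lo) return(0)
      r$rho * integrate(function(z) cos(qq * z), r$lo, r$hi,
                        rel.tol = 1e-12, subdivisions = 400L)$value
    }, numeric(1)))
    amp^2
  }, numeric(1))
}

# naive R double-loop Debye sum (reference implementation for the C++ kernel)
debyeReference <- function(coords, b, q) {
  n <- nrow(coords)
  out <- numeric(length(q))
  for (k in seq_along(q)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) {
          acc <- acc + b[i]^2
        } else {
          r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
          acc <- acc + b[i] * b[j] * sin(q[k] * r) / (q[k] * r)
        }
      }
    }
    out[k] <- acc
  }
  out
}

randomGeometry <- function() {
  BilayerGeometry(dH = runif(1, 1, 10), dT = runif(1, 8, 25),
                  dL = runif(1, 40, 120))
}

randomContrasts <- function() {
  ContrastProfile(rhoH = runif(1, -1.5, 1.5), rhoT = runif(1, -1.5, -0.2),
                  rhoL = runif(1, -1, 1))
}
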