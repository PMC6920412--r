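## Readers and writers for the columnar ASCII formats: reduced scattering
## curves (q, I, sigmaI[, sigmaQ]), model curves with parameter headers and
## structured-text fit reports.

#' Read a reduced scattering curve
#'
#' Reads whitespace-delimited columnar ASCII with 3 or 4 numeric columns
#' (q, I, sigmaI and optionally sigmaQ), the de facto reduced small-angle
#' scattering convention. Lines starting with `commentChar` are skipped;
#' rows that are malformed (non-numeric or short) and rows with non-positive
#' q or sigmaI are dropped, each with a warning reporting the count.
#'
#' @param path file path
#' @param radiation `"neutron"` or `"xray"`
#' @param commentChar comment prefix character (default `#`)
#' @param columns integer positions of the q, I, sigmaI and (optionally)
#'   sigmaQ columns, to cover dialect variants
#' @param metadata named list attached to the curve
#' @return a \linkS4class{ScatteringCurve}
#' @export
readScatteringCurve <- function(path, radiation = "neutron",
                                commentChar = "#",
                                columns = c(q = 1L, I = 2L, sigmaI = 3L,
                                            sigmaQ = 4L),
                                metadata = list()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, commentChar)]
  if (!length(lines)) stop("empty data file: ", path)
  fields <- strsplit(lines, "[ \t,]+")
  needed <- max(columns[c("q", "I", "sigmaI")])
  parsed <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  ok <- vapply(parsed, function(v)
    length(v) >= needed && !anyNA(v[seq_len(needed)]), logical(1))
  nBad <- sum(!ok)
  if (nBad > 0)
    warning(sprintf("dropped %d malformed row(s) from %s", nBad, path))
  parsed <- parsed[ok]
  if (!length(parsed)) stop("no valid data rows in ", path)
  if (length(unlist(lapply(fields[1], length))) < 3 && needed > 3)
    stop("fewer than 3 columns in ", path)
  getCol <- function(i) vapply(parsed, function(v)
    if (length(v) >= i) v[i] else NA_real_, numeric(1))
  q <- getCol(columns[["q"]])
  i <- getCol(columns[["I"]])
  si <- getCol(columns[["sigmaI"]])
  sq <- if (!is.na(columns["sigmaQ"])) getCol(columns[["sigmaQ"]]) else
    rep(NA_real_, length(q))
  keep <- q > 0 & si > 0
  if (any(!keep))
    warning(sprintf("dropped %d row(s) with non-positive q or sigmaI",
                    sum(!keep)))
  q <- q[keep]; i <- i[keep]; si <- si[keep]; sq <- sq[keep]
  if (!length(q)) stop("no usable data rows in ", path)
  ord <- order(q)
  sigmaQ <- if (all(is.na(sq))) numeric(0) else {
    sq[is.na(sq)] <- 0
    sq[ord]
  }
  ScatteringCurve(q = q[ord], intensity = i[ord], sigmaI = si[ord],
                  sigmaQ = sigmaQ, radiation = radiation,
                  metadata = metadata)
}

#' Write a scattering curve as columnar ASCII
#'
#' Full-precision (`%.17g`) whitespace-separated columns
#' `q I sigmaI [sigmaQ]` with a deterministic `#`-prefixed header echoing the
#' package version, radiation type and scalar metadata entries in sorted key
#' order. Round-trips through [readScatteringCurve()] exactly.
#'
#' @param curve a \linkS4class{ScatteringCurve}
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeScatteringCurve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thylakoidSAS %s scattering curve",
                     as.character(packageVersion("thylakoidSAS"))), con)
  writeLines(sprintf("# radiation: %s", curve@radiation), con)
  md <- curveMetadata(curve)
  for (key in sort(names(md))) {
    v <- md[[key]]
    if (is.atomic(v))
      writeLines(sprintf("# %s: %s", key,
                         paste(format(v, digits = 17), collapse = " ")), con)
  }
  hasSq <- length(curve@sigmaQ) > 0
  writeLines(paste0("# columns: q I sigmaI", if (hasSq) " sigmaQ"), con)
  if (hasSq)
    writeLines(sprintf("%.17g %.17g %.17g %.17g", curve@q, curve@intensity,
                       curve@sigmaI, curve@sigmaQ), con)
  else
    writeLines(sprintf("%.17g %.17g %.17g", curve@q, curve@intensity,
                       curve@sigmaI), con)
  invisible(path)
}

# deterministic "key: value" header block for a StackModel
.modelHeader <- function(model, extra = list()) {
  pars <- list(
    B = model@background@B, C = model@background@Camp,
    D = model@stack@D, N = model@stack@N,
    cutoff = model@poly@cutoff, dH = model@geometry@dH,
    dL = model@geometry@dL, dT = model@geometry@dT,
    etaCP = model@stack@etaCP, n = model@background@n,
    nQuad = model@poly@nQuad, rhoH = model@contrasts@rhoH,
    rhoL = model@contrasts@rhoL, rhoT = model@contrasts@rhoT,
    scale = model@scale, sigmaD = model@poly@sigmaD,
    sigmaL = model@poly@sigmaL)
  pars <- c(pars, extra)
  pars <- pars[sort(names(pars))]
  sprintf("# %s: %s", names(pars),
          vapply(pars, function(v) paste(format(v, digits = 17),
                                         collapse = " "), character(1)))
}

#' Write an analytic model curve
#'
#' Evaluates a \linkS4class{StackModel} on a q grid and writes two-column
#' ASCII (q, I) preceded by a header listing every model parameter in
#' deterministic (sorted) key order.
#'
#' @param model a \linkS4class{StackModel}
#' @param path output file path
#' @param q evaluation grid
#' @param resolution optional \linkS4class{ResolutionSpec}
#' @return `path`, invisibly
#' @export
writeModelCurve <- function(model, path, q = defaultQGrid(),
                            resolution = NULL) {
  i <- modelIntensity(q, model, resolution)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thylakoidSAS %s model curve",
                     as.character(packageVersion("thylakoidSAS"))), con)
  writeLines(.modelHeader(model), con)
  writeLines("# columns: q I", con)
  writeLines(sprintf("%.17g %.17g", q, i), con)
  invisible(path)
}

#' Write a structured-text fit report
#'
#' Human- and machine-readable report of a \linkS4class{FitResult}:
#' package version, best-fit parameters with fixed flags and bounds,
#' chi-square statistics, profile-likelihood intervals when present, deduced
#' quantities and a full `q I_data sigma_I I_model residual` table.
#'
#' @param result a \linkS4class{FitResult}
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeFitReport <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# thylakoidSAS %s fit report",
    as.character(packageVersion("thylakoidSAS")))
  w("[parameters]")
  for (p in names(result@par))
    w("%s = %.10g  # %s, bounds [%g, %g]", p, result@par[[p]],
      if (result@fixed[[p]]) "fixed" else "free",
      result@lower[[p]], result@upper[[p]])
  w("[statistics]")
  w("chisq = %.10g", result@chisq)
  w("reduced_chisq = %.10g", result@redChisq)
  w("n_points = %d", result@nobs)
  if (nrow(result@intervals)) {
    w("[trust_intervals]")
    for (i in seq_len(nrow(result@intervals)))
      w("%s = [%.10g, %.10g]", rownames(result@intervals)[i],
        result@intervals[i, 1], result@intervals[i, 2])
  }
  w("[deduced]")
  for (nm in names(result@deduced))
    w("%s = %s", nm, format(result@deduced[[nm]]))
  w("[data]")
  w("# q I_data sigma_I I_model residual")
  r <- (intensities(result@curve) - result@fittedIntensity) /
    intensityError(result@curve)
  writeLines(sprintf("%.10g %.10g %.10g %.10g %.10g", qValues(result@curve),
                     intensities(result@curve),
                     intensityError(result@curve), result@fittedIntensity,
                     r), con)
  invisible(path)
}
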