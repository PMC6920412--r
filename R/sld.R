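## Scattering-length-density composition, relative-contrast normalization and
## the coupled neutron/X-ray scenario solver for lumenal protein content.

#' Default component SLD table
#'
#' Editable table of component scattering length densities used by the
#' contrast scenario solver. Units are 1e-6 Angstrom^-2 throughout. For
#' protein components the `sld` column is the neutron value with no labile
#' H-D exchange and `sldExchanged` the value with all labile hydrogens
#' exchanged; neutron SLDs at intermediate exchange are interpolated linearly
#' by [proteinSLD()]. X-ray SLDs do not depend on exchange.
#'
#' Default values are standard literature compositions (heavy/light water,
#' galactolipid head and unsaturated tail groups, globular and
#' phycobiliprotein protein densities), chosen to be consistent with typical
#' cyanobacterial inter-thylakoid SLDs (about 3.6-4.4e-6 neutron and
#' 11.2-11.9e-6 X-ray). They are deliberately exposed as data so measured or
#' sequence-derived values can be substituted.
#'
#' @return data.frame with columns `component`, `radiation` (`"neutron"` or
#'   `"xray"`), `sld`, `sldExchanged` (NA where not applicable)
#' @examples
#' defaultSLDTable()
#' @export
defaultSLDTable <- function() {
  data.frame(
    component = rep(c("D2O", "H2O", "lipid_tail", "lipid_head",
                      "membrane_protein", "phycobilisome", "plastocyanin"),
                    each = 2),
    radiation = rep(c("neutron", "xray"), times = 7),
    sld = c(6.36, 9.42,      # D2O
            -0.56, 9.47,     # H2O
            -0.39, 8.10,     # lipid tails (unsaturated acyl chains)
            1.86, 13.40,     # lipid heads (galactosides)
            2.78, 12.40,     # membrane protein, 0% labile exchange
            2.30, 12.40,     # phycobilisome, 0% labile exchange
            2.10, 12.40),    # plastocyanin, 0% labile exchange
    sldExchanged = c(NA, NA, NA, NA, NA, NA, NA, NA,
                     4.20, NA,  # membrane protein, full labile exchange
                     4.10, NA,  # phycobilisome, full labile exchange
                     3.90, NA), # plastocyanin, full labile exchange
    stringsAsFactors = FALSE)
}

# single table lookup with validation
.sldEntry <- function(table, component, radiation) {
  row <- table[table$component == component & table$radiation == radiation, ]
  if (nrow(row) != 1L)
    stop(sprintf("SLD table has no unique entry for %s/%s",
                 component, radiation))
  row
}

#' Component SLD at a given labile H-D exchange level
#'
#' Looks up a component SLD in an SLD table. For neutron entries with an
#' `sldExchanged` value, the SLD at exchange fraction `exchange` (fraction of
#' labile hydrogens replaced by deuterium, in `[0, 1]`) is interpolated
#' linearly between the unexchanged and fully exchanged values. X-ray SLDs
#' ignore `exchange`.
#'
#' @param table an SLD table, see [defaultSLDTable()]
#' @param component component name
#' @param radiation `"neutron"` or `"xray"`
#' @param exchange labile H-D exchange fraction in `[0, 1]`
#' @return SLD in the table's units
#' @export
proteinSLD <- function(table, component, radiation = "neutron",
                       exchange = 0) {
  stopifnot(exchange >= 0, exchange <= 1)
  row <- .sldEntry(table, component, radiation)
  if (radiation == "neutron" && !is.na(row$sldExchanged))
    row$sld + exchange * (row$sldExchanged - row$sld)
  else
    row$sld
}

#' Volume-weighted mixture SLD
#'
#' SLD of a homogeneous mixture: `sum(fractions * slds)`. Volume fractions
#' must sum to 1 (tolerance 1e-9).
#'
#' @param slds component SLDs
#' @param fractions volume fractions, same length as `slds`
#' @return mixture SLD
#' @examples
#' mixtureSLD(c(6.36, -0.56), c(0.9, 0.1))  # 90/10 D2O/H2O
#' @export
mixtureSLD <- function(slds, fractions) {
  stopifnot(length(slds) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("volume fractions must sum to 1")
  sum(fractions * slds)
}

#' Water SLD at a given D2O fraction
#'
#' @param table an SLD table, see [defaultSLDTable()]
#' @param fD2O D2O volume fraction of the water, in `[0, 1]`
#' @param radiation `"neutron"` or `"xray"`
#' @return SLD of the D2O/H2O mixture
#' @export
waterSLD <- function(table, fD2O, radiation = "neutron") {
  stopifnot(fD2O >= 0, fD2O <= 1)
  mixtureSLD(c(.sldEntry(table, "D2O", radiation)$sld,
               .sldEntry(table, "H2O", radiation)$sld),
             c(fD2O, 1 - fD2O))
}

#' Protein-averaged region SLD
#'
#' SLD of a membrane region (tail or head layer) containing a volume fraction
#' `proteinFraction` of membrane protein and `1 - proteinFraction` of the
#' corresponding lipid component.
#'
#' @param table an SLD table, see [defaultSLDTable()]
#' @param region `"tail"` or `"head"`
#' @param proteinFraction protein volume fraction in `[0, 1]` (0.7 is the
#'   canonical thylakoid protein/lipid ratio)
#' @param radiation `"neutron"` or `"xray"`
#' @param exchange labile H-D exchange fraction of the membrane protein
#' @return region SLD
#' @export
proteinAveragedSLD <- function(table, region = c("tail", "head"),
                               proteinFraction = 0.7, radiation = "neutron",
                               exchange = 0) {
  region <- match.arg(region)
  stopifnot(proteinFraction >= 0, proteinFraction <= 1)
  lipid <- .sldEntry(table, paste0("lipid_", region), radiation)$sld
  prot <- proteinSLD(table, "membrane_protein", radiation, exchange)
  mixtureSLD(c(prot, lipid), c(proteinFraction, 1 - proteinFraction))
}

#' Single-box membrane SLD
#'
#' When headgroup and tailgroup regions cannot be distinguished (the neutron
#' case), the whole membrane is described as one box whose SLD is the mean of
#' the protein-averaged tail and head SLDs:
#' `SLD_TM = 0.5 * (sldTail + sldHead)`.
#'
#' @param sldTail protein-averaged tail-region SLD
#' @param sldHead protein-averaged head-region SLD
#' @return membrane box SLD, same units as the inputs
#' @examples
#' membraneSLD(1.832, 1.327)  # 1.5795 (x 1e-6 1/A^2)
#' @export
membraneSLD <- function(sldTail, sldHead) {
  0.5 * (sldTail + sldHead)
}

#' @rdname membraneSLD
#' @param table an SLD table, see [defaultSLDTable()]
#' @param proteinFraction protein volume fraction of the membrane
#' @param radiation `"neutron"` or `"xray"`
#' @param exchange labile H-D exchange fraction of the membrane protein
#' @export
membraneSLDFromTable <- function(table, proteinFraction = 0.7,
                                 radiation = "neutron", exchange = 0) {
  membraneSLD(
    proteinAveragedSLD(table, "tail", proteinFraction, radiation, exchange),
    proteinAveragedSLD(table, "head", proteinFraction, radiation, exchange))
}

#' Absolute/relative contrast conversion
#'
#' The fitting convention anchors the contrast scale on the membrane: the
#' inter-thylakoid liquid maps to 0 and the membrane to -1, so an absolute
#' SLD `x` maps to `(sldIT - x) / (sldTM - sldIT)`. `fromRelative()` is the
#' exact inverse, `x = sldIT + rel * (sldIT - sldTM)`.
#'
#' @param sld absolute SLD value(s)
#' @param rel relative contrast value(s)
#' @param sldIT absolute SLD of the inter-thylakoid liquid
#' @param sldTM absolute SLD of the membrane (reference that maps to -1)
#' @return relative contrast(s) resp. absolute SLD(s)
#' @examples
#' toRelative(4.30, sldIT = 3.61, sldTM = 1.58)   # ~0.34
#' fromRelative(0.34, sldIT = 3.61, sldTM = 1.58) # ~4.30
#' @export
toRelative <- function(sld, sldIT, sldTM) {
  if (sldTM == sldIT) stop("'sldTM' and 'sldIT' must differ")
  (sldIT - sld) / (sldTM - sldIT)
}

#' @rdname toRelative
#' @export
fromRelative <- function(rel, sldIT, sldTM) {
  if (sldTM == sldIT) stop("'sldTM' and 'sldIT' must differ")
  sldIT + rel * (sldIT - sldTM)
}

#' Deduced structural parameters
#'
#' From fitted repeat distance `D`, lumen thickness `dL` and tail
#' half-thickness `dT` (single-box membrane convention), the inter-thylakoid
#' gap height is `dIT = D - dL - 4 * dT` and the membrane thickness
#' `dTM = 2 * dT`. A non-positive `dIT` marks a geometrically impossible
#' (unphysical) fit.
#'
#' @param D repeat distance, Angstrom
#' @param dL lumen thickness, Angstrom
#' @param dT tail half-thickness, Angstrom
#' @return list with `dIT`, `dTM` and logical `physical`
#' @examples
#' deducedParameters(D = 677.8, dL = 62.13, dT = 16.89)  # dIT ~ 548.1
#' @export
deducedParameters <- function(D, dL, dT) {
  dIT <- D - dL - 4 * dT
  if (dIT <= 0)
    warning("deduced inter-thylakoid spacing is non-positive; unphysical fit")
  list(dIT = dIT, dTM = 2 * dT, physical = dIT > 0)
}

#' Lumen composition scenario search
#'
#' Solves the coupled neutron/X-ray contrast system for the lumenal protein
#' volume fraction under a grid of inter-thylakoid (IT) composition
#' scenarios. For each IT scenario (phycobilisome volume fraction
#' `phiPhyco`, labile H-D exchange `w` of the phycobilisomes, D2O fraction
#' `fD2O` of the IT water) the absolute IT SLDs are composed from the table;
#' the fitted relative lumen contrasts are mapped to absolute lumen SLDs via
#' [fromRelative()] (anchored on `sldTM` for neutrons and `sldTX` for
#' X-rays); and the lumen composition (plastocyanin-equivalent protein
#' fraction, lumen water D2O fraction `fD2Oprime <= fD2O`, lumen protein
#' exchange `wPrime`) is solved separately from the neutron and the X-ray
#' branch. Scenarios are ranked by `|phiN - phiX|` ascending: the scenario in
#' which the two independent radiations imply the same lumen protein content
#' is the most likely.
#'
#' @param table an SLD table, see [defaultSLDTable()]
#' @param contrastN fitted relative lumen contrast, neutron branch
#' @param contrastX fitted relative lumen contrast, X-ray branch
#' @param sldTM absolute neutron SLD of the single-box membrane
#'   (1e-6 Angstrom^-2)
#' @param sldTX absolute X-ray SLD of the tail region (the X-ray contrast
#'   anchor)
#' @param phiPhycoGrid grid of IT phycobilisome volume fractions
#' @param wGrid grid of IT (phycobilisome) labile-exchange fractions
#' @param fD2OGrid grid of IT water D2O fractions
#' @param wPrimeGrid grid of lumen-protein labile-exchange fractions
#' @param fD2OPrimeGrid grid of lumen water D2O fractions (candidates above
#'   the scenario's `fD2O` are excluded: lumen water exchanges with the
#'   cytoplasm, so its D2O level can be at most the IT level)
#' @return data.frame of scenarios ranked by `score = |phiN - phiX|`
#'   ascending, with the composed SLDs and the per-branch lumen protein
#'   fractions; zero rows (with a message) when no scenario admits volume
#'   fractions in `[0, 1]`
#' @examples
#' top <- scenarioSearch(defaultSLDTable())[1, ]
#' top$phiLumenProteinX < top$phiPhyco
#' @export
scenarioSearch <- function(table = defaultSLDTable(),
                           contrastN = 0.34, contrastX = -0.175,
                           sldTM = 1.58, sldTX = 11.2,
                           phiPhycoGrid = seq(0.60, 0.85, by = 0.05),
                           wGrid = seq(0, 0.9, by = 0.1),
                           fD2OGrid = c(0.8, 0.9, 1.0),
                           wPrimeGrid = seq(0, 0.9, by = 0.1),
                           fD2OPrimeGrid = c(0.8, 0.9, 1.0)) {
  stopifnot(length(phiPhycoGrid) > 0, length(wGrid) > 0, length(fD2OGrid) > 0,
            length(wPrimeGrid) > 0, length(fD2OPrimeGrid) > 0)
  phycoX <- proteinSLD(table, "phycobilisome", "xray")
  plcX <- proteinSLD(table, "plastocyanin", "xray")

  rows <- list()
  for (phiP in phiPhycoGrid) for (w in wGrid) for (fD2O in fD2OGrid) {
    sldITn <- mixtureSLD(
      c(waterSLD(table, fD2O, "neutron"),
        proteinSLD(table, "phycobilisome", "neutron", w)),
      c(1 - phiP, phiP))
    sldITx <- mixtureSLD(
      c(waterSLD(table, fD2O, "xray"), phycoX), c(1 - phiP, phiP))
    sldLn <- fromRelative(contrastN, sldITn, sldTM)
    sldLx <- fromRelative(contrastX, sldITx, sldTX)

    # lumen sub-scenarios: solve each branch for the protein fraction
    best <- NULL
    for (fp in fD2OPrimeGrid[fD2OPrimeGrid <= fD2O + 1e-12]) {
      watX <- waterSLD(table, fp, "xray")
      phiX <- (sldLx - watX) / (plcX - watX)
      if (is.na(phiX) || phiX < 0 || phiX > 1) next
      watN <- waterSLD(table, fp, "neutron")
      for (wp in wPrimeGrid) {
        plcN <- proteinSLD(table, "plastocyanin", "neutron", wp)
        phiN <- (sldLn - watN) / (plcN - watN)
        if (is.na(phiN) || phiN < 0 || phiN > 1) next
        sc <- abs(phiN - phiX)
        if (is.null(best) || sc < best$score)
          best <- list(score = sc, phiN = phiN, phiX = phiX, wp = wp, fp = fp)
      }
    }
    if (is.null(best)) next
    rows[[length(rows) + 1L]] <- data.frame(
      phiPhyco = phiP, wExchange = w, fD2O = fD2O,
      sldITn = sldITn, sldITx = sldITx, sldLn = sldLn, sldLx = sldLx,
      phiLumenProteinN = best$phiN, phiLumenProteinX = best$phiX,
      wPrime = best$wp, fD2OPrime = best$fp, score = best$score)
  }
  if (!length(rows)) {
    message("no scenario yields lumen protein fractions in [0, 1]")
    return(data.frame(
      phiPhyco = numeric(0), wExchange = numeric(0), fD2O = numeric(0),
      sldITn = numeric(0), sldITx = numeric(0), sldLn = numeric(0),
      sldLx = numeric(0), phiLumenProteinN = numeric(0),
      phiLumenProteinX = numeric(0), wPrime = numeric(0),
      fD2OPrime = numeric(0), score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$phiPhyco, out$wExchange, out$fD2O), ]
  rownames(out) <- NULL
  out
}

#' Read or write an SLD table as columnar text
#'
#' Plain whitespace-separated text with a header line
#' (`component radiation sld sldExchanged`), `#` comments allowed.
#'
#' @param path file path
#' @param table an SLD table data.frame
#' @return `readSLDTable()` returns the table; `writeSLDTable()` returns
#'   `path` invisibly.
#' @export
readSLDTable <- function(path) {
  tab <- read.table(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("component", "radiation", "sld", "sldExchanged")
  if (!all(need %in% names(tab)))
    stop("SLD table must contain columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname readSLDTable
#' @export
writeSLDTable <- function(table, path) {
  write.table(table, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
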