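#' @include AllClasses.R
NULL

.ELEMENTARY_CHARGE <- 1.602176634e-19  # C

# Compartment codes: 1 INTRA (below the F87 plane), 2 FILTER (F87..G63),
# 3 EXTRA (above the G63 plane).
.compartment <- function(z, f87, g63) {
  ifelse(z < f87, 1L, ifelse(z > g63, 3L, 2L))
}

#' Detect complete permeation events
#'
#' Scans per-ion axial traces (relative to the T59 reference) with a
#' three-compartment scheme: INTRA below the F87 plane, FILTER between the
#' F87 and G63 planes, EXTRA above the G63 plane. An outward event is the
#' ordered visit INTRA -> FILTER -> EXTRA by one ion without returning to
#' INTRA in between; inward is the mirror image. Incomplete excursions
#' (INTRA -> FILTER -> INTRA) count nothing. A per-frame displacement with
#' `|dz| > boxZ/2` is treated as a periodic wrap: the ion moved through the
#' bulk across the box boundary, so any transit in progress is abandoned
#' (this prevents phantom events when an ion wraps) and, if the ion lands
#' in the filter, its origin is unknown and no event can be credited until
#' it next reaches a bulk compartment.
#'
#' @param traces numeric matrix frames x ions of axial coordinates
#'   (Angstrom, relative to T59), or a single numeric vector.
#' @param f87Plane,g63Plane compartment boundaries (Angstrom relative to
#'   T59); either scalars or per-frame vectors.
#' @param boxZ box length along z (Angstrom); `Inf` disables wrap handling.
#' @param species optional character vector naming each ion's species.
#' @param frameIndices optional frame indices (must be strictly
#'   increasing).
#' @return data.frame with columns `particle`, `species`, `direction`
#'   (+1 outward, -1 inward), `entry_frame`, `exit_frame`.
#' @export
detectEvents <- function(traces, f87Plane, g63Plane, boxZ = Inf,
                         species = NULL, frameIndices = NULL) {
  if (is.vector(traces)) traces <- matrix(traces, ncol = 1)
  nf <- nrow(traces)
  if (is.null(frameIndices)) frameIndices <- seq_len(nf)
  if (length(frameIndices) != nf || is.unsorted(frameIndices,
                                                strictly = TRUE))
    stop("frame indices must be strictly increasing")
  f87 <- rep_len(f87Plane, nf)
  g63 <- rep_len(g63Plane, nf)
  if (is.null(species)) species <- rep(NA_character_, ncol(traces))
  out <- list()
  if (nf < 2L)
    return(data.frame(particle = integer(), species = character(),
                      direction = integer(), entry_frame = integer(),
                      exit_frame = integer()))
  for (ion in seq_len(ncol(traces))) {
    z <- traces[, ion]
    comp <- .compartment(z, f87, g63)
    wrap <- c(FALSE, abs(diff(z)) > boxZ / 2)
    origin <- if (comp[1] != 2L) comp[1] else NA_integer_
    entry <- NA_integer_
    for (t in 2:nf) {
      if (comp[t] == comp[t - 1L] && !wrap[t]) next
      if (wrap[t]) {
        origin <- if (comp[t] != 2L) comp[t] else NA_integer_
        entry <- NA_integer_
        next
      }
      if (comp[t] == 2L) {                      # entered the filter
        if (comp[t - 1L] != 2L) {
          origin <- comp[t - 1L]
          entry <- frameIndices[t - 1L]
        }
      } else if (comp[t - 1L] == 2L) {          # left the filter
        if (!is.na(origin) && comp[t] != origin) {
          out[[length(out) + 1L]] <- data.frame(
            particle = ion, species = species[ion],
            direction = if (comp[t] == 3L) 1L else -1L,
            entry_frame = entry, exit_frame = frameIndices[t])
        }
        origin <- comp[t]
        entry <- NA_integer_
      } else {                                  # bulk-to-bulk jump
        origin <- comp[t]
        entry <- NA_integer_
      }
    }
    }
  if (!length(out))
    return(data.frame(particle = integer(), species = character(),
                      direction = integer(), entry_frame = integer(),
                      exit_frame = integer()))
  do.call(rbind, out)
}

#' Transmembrane voltage from an applied field
#'
#' `V = E_z * box_z` in mV; positive voltage drives cations outward (+z).
#'
#' @param field a [FieldSpec-class], or the field strength in mV/Angstrom.
#' @param boxZ box length (Angstrom), required when `field` is numeric.
#' @return voltage in mV.
#' @export
voltageFromField <- function(field, boxZ = NULL) {
  if (is(field, "FieldSpec")) return(field@Ez * field@boxZ)
  if (is.null(boxZ) || boxZ <= 0) stop("boxZ must be a positive scalar")
  field * boxZ
}

#' Convert net permeation counts to a single-channel current
#'
#' `I (pA) = (n_outward - n_inward) * e / simTime`, with e the elementary
#' charge; the sign is positive for net outward flow.
#'
#' @param events data.frame from [detectEvents()], or a list with integer
#'   entries `n_outward` and `n_inward`.
#' @param simTimeNs simulated time in ns (> 0).
#' @param voltage voltage label in mV.
#' @return a [CurrentEstimate-class]
#' @export
computeCurrent <- function(events, simTimeNs, voltage = NA_real_) {
  if (simTimeNs <= 0) stop("simTimeNs must be positive")
  if (is.data.frame(events)) {
    nOut <- sum(events$direction == 1L)
    nIn <- sum(events$direction == -1L)
  } else {
    nOut <- events$n_outward
    nIn <- events$n_inward
  }
  pA <- (nOut - nIn) * .ELEMENTARY_CHARGE / (simTimeNs * 1e-9) * 1e12
  new("CurrentEstimate", nOutward = as.integer(nOut), nInward = as.integer(nIn),
      simTime = simTimeNs, current = pA, voltage = voltage)
}

#' Rectification ratio |I(-V)| / |I(+V)|
#'
#' Both currents must be computed at equal absolute voltage. A perfect
#' inward rectifier (zero outward current, non-zero inward) returns `Inf`
#' with a warning; both currents zero is undefined and returns `NaN` with
#' a warning.
#'
#' @param currentNeg,currentPos [CurrentEstimate-class] objects or currents
#'   in pA at -V and +V.
#' @return dimensionless ratio (>1 indicates inward rectification).
#' @export
rectificationRatio <- function(currentNeg, currentPos) {
  iNeg <- if (is(currentNeg, "CurrentEstimate")) currentNeg@current else currentNeg
  iPos <- if (is(currentPos, "CurrentEstimate")) currentPos@current else currentPos
  if (iPos == 0) {
    if (iNeg == 0) {
      warning("both currents are zero; rectification ratio undefined")
      return(NaN)
    }
    warning("zero outward current: perfect inward rectifier")
    return(Inf)
  }
  abs(iNeg) / abs(iPos)
}

#' Write a permeation event list as TSV
#'
#' @param events data.frame from [detectEvents()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEventsTSV <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
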