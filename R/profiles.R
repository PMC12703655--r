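#' @include AllClasses.R pore-model.R
NULL

#' Axial number-density profile relative to T59
#'
#' For every frame, particles of each species within `radialCutoff` of the
#' instantaneous pore axis and inside `zRange` are histogrammed by their
#' axial coordinate relative to the T59 carbonyl reference. Raw counts and
#' the per-frame mean are both stored (the figure-style normalisation is
#' not uniquely defined, so both are emitted).
#'
#' @param traj an [IonTrajectory-class]
#' @param spec a [PoreSpec-class]
#' @param radialCutoff cylinder radius, Angstrom (default 8: covers the
#'   cavity, F87 and E92 regions).
#' @param binWidth bin width, Angstrom (> 0).
#' @param zRange axial interval (Angstrom relative to T59), low to high.
#' @param species optional subset of species labels.
#' @return a [DensityProfile-class]
#' @export
axialDensity <- function(traj, spec, radialCutoff = 8, binWidth = 0.5,
                         zRange = c(-25, 5), species = NULL) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (diff(zRange) <= 0) stop("empty z range")
  edges <- seq(zRange[1], zRange[2], by = binWidth)
  if (length(edges) < 2L) stop("empty z range")
  part <- spec@particles
  if (!is.null(species)) part <- part[part$species %in% species, ]
  levels <- sort(unique(part$species))
  counts <- matrix(0, length(edges) - 1L, length(levels),
                   dimnames = list(NULL, levels))
  nf <- nFrames(traj)
  for (f in seq_len(nf)) {
    coords <- traj@coords[, , f]
    g <- .geomCore(coords, spec)
    ar <- .axialRadial(coords, g, part$atom)
    keep <- ar$r < radialCutoff & ar$z >= zRange[1] & ar$z < zRange[2]
    if (!any(keep)) next
    bin <- findInterval(ar$z[keep], edges, rightmost.closed = FALSE)
    sp <- match(part$species[keep], levels)
    for (i in seq_along(bin))
      counts[bin[i], sp[i]] <- counts[bin[i], sp[i]] + 1
  }
  new("DensityProfile", binEdges = edges, counts = counts,
      perFrame = counts / nf, frames = as.integer(nf),
      radialCutoff = radialCutoff)
}

#' Lower-gate distance (opposing F97 C-alpha atoms)
#'
#' Per-frame distances of the two cross-pore diagonals (chains 1-3 and
#' 2-4 in the chain order of `spec`) and their mean.
#'
#' @param traj an [IonTrajectory-class]
#' @param spec a [PoreSpec-class] with F97 C-alpha atoms in at least 4
#'   chains.
#' @return a [GateMetric-class]
#' @export
gateDistance <- function(traj, spec) {
  ca <- spec@rings$f97_ca
  if (length(ca) < 4L || anyNA(ca[1:4]))
    stop("gate distance requires F97 C-alpha atoms in 4 chains")
  nf <- nFrames(traj)
  d13 <- numeric(nf)
  d24 <- numeric(nf)
  for (f in seq_len(nf)) {
    coords <- traj@coords[, , f]
    d13[f] <- sqrt(sum((coords[ca[1], ] - coords[ca[3], ])^2))
    d24[f] <- sqrt(sum((coords[ca[2], ] - coords[ca[4], ])^2))
  }
  new("GateMetric",
      distances = data.frame(frame = seq_len(nf), d13 = d13, d24 = d24,
                             mean = (d13 + d24) / 2),
      chains = spec@chains[1:4])
}

#' RMSD time series and per-residue RMSF
#'
#' Each frame is rigid-body superposed onto the reference over
#' `fitSelection`, then the RMSD is computed over `selection`. The RMSF is
#' the per-atom root-mean-square deviation from the time-averaged structure
#' after fitting, aggregated per residue (root mean square over the
#' residue's selected atoms). The RMSD of the reference against itself is
#' exactly 0, and both metrics are invariant to a global rigid-body motion
#' of every frame.
#'
#' @param traj an [IonTrajectory-class]
#' @param reference n_atoms x 3 matrix (default: first frame).
#' @param selection integer atom indices to measure (default: all protein
#'   atoms).
#' @param fitSelection integer atom indices for the superposition (default:
#'   `selection`).
#' @return a [FlexibilityMetric-class]
#' @export
rmsdRmsf <- function(traj, reference = NULL, selection = NULL,
                     fitSelection = NULL) {
  atoms <- traj@atoms
  if (is.null(selection))
    selection <- which(atoms$type == "ATOM")
  if (!length(selection)) stop("empty selection")
  if (is.null(fitSelection)) fitSelection <- selection
  if (is.null(reference)) reference <- traj@coords[, , 1]
  if (nrow(reference) != nrow(atoms))
    stop("reference and trajectory atom counts differ")
  refXyz <- as.numeric(t(reference))
  xyz <- .arrayToXyz(traj@coords)
  xyzInds <- function(idx) as.numeric(rbind((idx - 1) * 3 + 1,
                                            (idx - 1) * 3 + 2,
                                            (idx - 1) * 3 + 3))
  fitted <- bio3d::fit.xyz(fixed = refXyz, mobile = xyz,
                           fixed.inds = xyzInds(fitSelection),
                           mobile.inds = xyzInds(fitSelection))
  selXyz <- xyzInds(selection)
  rmsd <- bio3d::rmsd(refXyz[selXyz], fitted[, selXyz, drop = FALSE],
                      fit = FALSE)
  rmsfAtom <- bio3d::rmsf(fitted[, selXyz, drop = FALSE])
  atomTab <- data.frame(chain = atoms$chain[selection],
                        resno = atoms$resno[selection],
                        elety = atoms$elety[selection],
                        rmsf = rmsfAtom)
  res <- stats::aggregate(rmsf ~ chain + resno, atomTab,
                          function(v) sqrt(mean(v^2)))
  new("FlexibilityMetric", rmsd = as.numeric(rmsd), rmsfAtom = atomTab,
      rmsfResidue = res[order(res$chain, res$resno), ])
}

#' Write a density profile as TSV
#'
#' Columns: bin centre plus one raw-count and one per-frame-mean column per
#' species.
#'
#' @param profile a [DensityProfile-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileTSV <- function(profile, path) {
  centres <- (profile@binEdges[-1] + utils::head(profile@binEdges, -1)) / 2
  df <- data.frame(bin_center = centres, profile@counts,
                   check.names = FALSE)
  pf <- profile@perFrame
  colnames(pf) <- paste0(colnames(pf), "_per_frame")
  utils::write.table(cbind(df, pf), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
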