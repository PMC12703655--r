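#' @include AllClasses.R pore-model.R
NULL

.SPECIES_LETTER <- c(K = "K", NH4 = "N", WAT = "W", EMPTY = "O")

.asGeomList <- function(geom) {
  if (is(geom, "FrameGeometry"))
    list(origin = geom@axisOrigin, axis = geom@axisDirection,
         planes = geom@planes, siteIntervals = geom@siteIntervals)
  else geom
}

# Core per-frame assignment. Boundary ties (z exactly on a plane) resolve to
# the site above: membership is lo <= z < hi. Returns a plain list.
.assignCore <- function(coords, geom, spec) {
  geom <- .asGeomList(geom)
  part <- spec@particles
  ar <- .axialRadial(coords, geom, part$atom)
  z <- ar$z
  r <- ar$r
  cut <- spec@cutoffs
  si <- geom$siteIntervals
  occSpecies <- c(S1 = "EMPTY", S2 = "EMPTY", S3 = "EMPTY", S4 = "EMPTY",
                  Scav = "EMPTY")
  occId <- c(S1 = NA_integer_, S2 = NA_integer_, S3 = NA_integer_,
             S4 = NA_integer_, Scav = NA_integer_)
  extra <- list()
  for (s in .SITES) {
    rad <- if (s == "Scav") cut[["scav_radial"]] else cut[["sf_radial"]]
    cand <- which(z >= si[s, "lo"] & z < si[s, "hi"] & r < rad)
    if (!length(cand)) next
    if (length(cand) > 1L) {
      mid <- (si[s, "lo"] + si[s, "hi"]) / 2
      cand <- cand[order(abs(z[cand] - mid), part$id[cand])]
      extra[[s]] <- data.frame(site = s, particle = part$id[cand[-1]])
    }
    occSpecies[s] <- part$species[cand[1]]
    occId[s] <- part$id[cand[1]]
  }
  isCa <- part$species == "CA"
  caF87 <- any(isCa & z >= si["Scav", "lo"] & z < si["Scav", "hi"] &
                 r < cut[["f87_radial"]])
  caE92 <- FALSE
  if (length(spec@rings$e92_o) && any(isCa)) {
    eO <- coords[spec@rings$e92_o, , drop = FALSE]
    caXyz <- coords[part$atom[isCa], , drop = FALSE]
    for (i in seq_len(nrow(caXyz))) {
      d2 <- rowSums(sweep(eO, 2, caXyz[i, ])^2)
      if (any(d2 < cut[["e92_contact"]]^2)) { caE92 <- TRUE; break }
    }
  }
  list(occupants = occSpecies, occupantIds = occId,
       extra = if (length(extra)) do.call(rbind, extra) else
         data.frame(site = character(), particle = integer()),
       caF87 = caF87, caE92 = caE92)
}

#' Assign particles to pore sites for one frame
#'
#' A particle occupies an SF site (S1-S4) when its axial coordinate lies in
#' the site interval and its radial distance from the axis is below the SF
#' radial cutoff; the cavity site Scav uses its own cutoff. Water is
#' represented by its oxygen and ammonium by its nitrogen. If two particles
#' satisfy one site, the one nearer the interval midpoint is recorded as
#' the occupant and the remainder as extra occupants. The Ca2+ flags test
#' the F87 region (Scav axial slab, F87 radial cutoff) and contact with the
#' E92 carboxylate oxygens. An empty filter is a valid outcome.
#'
#' @param coords n_atoms x 3 coordinate matrix for one frame.
#' @param geometry a [FrameGeometry-class] for this frame.
#' @param spec a [PoreSpec-class]
#' @param frameIndex integer label stored in the result.
#' @return a [SiteAssignment-class]
#' @export
assignFrame <- function(coords, geometry, spec, frameIndex = 1L) {
  a <- .assignCore(coords, geometry, spec)
  new("SiteAssignment", frameIndex = as.integer(frameIndex),
      occupants = a$occupants, occupantIds = a$occupantIds,
      extraOccupants = a$extra, caF87 = a$caF87, caE92 = a$caE92)
}

#' Encode a site assignment as a 4-letter state string
#'
#' Letters for S1..S4 in that order: K = K+, N = NH4+, W = water,
#' O = empty (Scav is excluded from the code). Any other occupant species
#' is encoded as X.
#'
#' @param assignment a [SiteAssignment-class], or a character vector of
#'   species labels for S1..S4.
#' @return single 4-character string.
#' @export
encodeState <- function(assignment) {
  occ <- if (is(assignment, "SiteAssignment"))
    assignment@occupants[c("S1", "S2", "S3", "S4")]
  else assignment[seq_len(4)]
  letters <- .SPECIES_LETTER[occ]
  letters[is.na(letters)] <- "X"
  paste(letters, collapse = "")
}

#' Assign every frame of a trajectory
#'
#' Recomputes the pore geometry and the site assignment independently on
#' each frame and returns a per-frame table.
#'
#' @param traj an [IonTrajectory-class]
#' @param spec a [PoreSpec-class]
#' @return data.frame with columns `frame`, `S1`..`S4`, `Scav` (species or
#'   EMPTY), `code`, `caF87`, `caE92`, `nExtra`.
#' @export
assignTrajectory <- function(traj, spec) {
  nf <- nFrames(traj)
  occ <- matrix("EMPTY", nf, 5L, dimnames = list(NULL, .SITES))
  caF <- logical(nf)
  caE <- logical(nf)
  nx <- integer(nf)
  for (f in seq_len(nf)) {
    coords <- traj@coords[, , f]
    a <- .assignCore(coords, .geomCore(coords, spec), spec)
    occ[f, ] <- a$occupants
    caF[f] <- a$caF87
    caE[f] <- a$caE92
    nx[f] <- nrow(a$extra)
  }
  letters <- matrix(.SPECIES_LETTER[occ[, 1:4]], nf, 4L)
  letters[is.na(letters)] <- "X"
  data.frame(frame = seq_len(nf), occ,
             code = paste0(letters[, 1], letters[, 2], letters[, 3],
                           letters[, 4]),
             caF87 = caF, caE92 = caE, nExtra = nx,
             stringsAsFactors = FALSE)
}

#' Label frames by Ca2+ bound below the SF
#'
#' The conditioning label used for occupancy statistics is the F87-site
#' flag only: a Ca2+ ion at the E92 glutamate ring does not block the pore
#' and does not set the label.
#'
#' @param assignments a data.frame from [assignTrajectory()], or a list of
#'   [SiteAssignment-class] objects.
#' @return logical vector, one per frame.
#' @export
labelCaBound <- function(assignments) {
  if (is.data.frame(assignments)) return(assignments$caF87)
  vapply(assignments, function(a) a@caF87, logical(1))
}

.emptyOccupancyTable <- function(voltage, condition, speciesLevels) {
  new("OccupancyTable",
      siteFractions = matrix(numeric(), 0, length(speciesLevels),
                             dimnames = list(NULL, speciesLevels)),
      stateFreq = numeric(), nFrames = 0L, voltage = voltage,
      condition = condition)
}

.buildOccupancyTable <- function(occ, codes, voltage, condition,
                                 speciesLevels) {
  n <- nrow(occ)
  if (n == 0L) return(.emptyOccupancyTable(voltage, condition, speciesLevels))
  frac <- matrix(0, length(.SITES), length(speciesLevels),
                 dimnames = list(.SITES, speciesLevels))
  for (s in .SITES) {
    tab <- table(factor(occ[, s], levels = speciesLevels))
    frac[s, ] <- as.numeric(tab) / n
  }
  sf <- table(codes) / n
  new("OccupancyTable", siteFractions = frac,
      stateFreq = stats::setNames(as.numeric(sf), names(sf)),
      nFrames = as.integer(n), voltage = voltage, condition = condition)
}

#' Aggregate occupancy statistics by Ca condition
#'
#' Splits the per-frame assignments into Ca-bound and Ca-free frames (F87
#' flag) and returns one normalised [OccupancyTable-class] per condition.
#' Water fractions are reported per site alongside the ion fractions. A
#' condition that never occurs yields an empty table with zero frames;
#' zero frames overall is an error.
#'
#' @param assignments data.frame from [assignTrajectory()].
#' @param voltage voltage label, mV.
#' @param labels optional logical conditioning labels (default: the F87
#'   Ca flag of `assignments`).
#' @return list with elements `ca_bound` and `ca_free`.
#' @export
aggregateOccupancy <- function(assignments, voltage = NA_real_,
                               labels = labelCaBound(assignments)) {
  if (nrow(assignments) == 0L) stop("zero frames: nothing to aggregate")
  if (length(labels) != nrow(assignments))
    stop("labels must have one entry per frame")
  speciesLevels <- sort(unique(c("K", "NH4", "WAT", "CA", "EMPTY",
                                 unlist(assignments[, .SITES]))))
  occ <- as.matrix(assignments[, .SITES])
  list(
    ca_bound = .buildOccupancyTable(occ[labels, , drop = FALSE],
                                    assignments$code[labels], voltage,
                                    "ca_bound", speciesLevels),
    ca_free = .buildOccupancyTable(occ[!labels, , drop = FALSE],
                                   assignments$code[!labels], voltage,
                                   "ca_free", speciesLevels)
  )
}

#' Write a per-frame state table as TSV
#'
#' Columns: frame, code, ca_f87, ca_e92.
#'
#' @param assignments data.frame from [assignTrajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStateTable <- function(assignments, path) {
  utils::write.table(
    data.frame(frame = assignments$frame, code = assignments$code,
               ca_f87 = assignments$caF87, ca_e92 = assignments$caE92),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write occupancy tables as JSON, keyed by voltage and condition
#'
#' @param tables nested list: `tables[[voltageLabel]][[condition]]` of
#'   [OccupancyTable-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOccupancyJSON <- function(tables, path) {
  out <- lapply(tables, function(byCond) {
    lapply(byCond, function(tab) list(
      n_frames = tab@nFrames,
      voltage_mV = tab@voltage,
      condition = tab@condition,
      site_fractions = if (tab@nFrames > 0)
        as.data.frame(tab@siteFractions) else NULL,
      state_freq = as.list(tab@stateFreq)
    ))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
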