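#' @include AllClasses.R
NULL

#' Number of frames in a trajectory
#' @param x an [IonTrajectory-class]
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "IonTrajectory", function(x) dim(x@coords)[3])

#' Atom table accessor
#' @param x an [IonTrajectory-class] or [PoreSpec-class]
#' @return data.frame of atoms
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname atomData
#' @export
setMethod("atomData", "IonTrajectory", function(x) x@atoms)

#' @rdname atomData
#' @export
setMethod("atomData", "PoreSpec", function(x) x@atoms)

#' Coordinates of one frame
#' @param x an [IonTrajectory-class]
#' @param i frame index
#' @return n_atoms x 3 matrix
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "IonTrajectory", function(x, i) {
  x@coords[, , i, drop = TRUE]
})

#' Particle table accessor
#' @param x a [PoreSpec-class]
#' @return data.frame (atom, species, id)
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))

#' @rdname particles
#' @export
setMethod("particles", "PoreSpec", function(x) x@particles)

#' Site intervals accessor
#' @param x a [FrameGeometry-class]
#' @return 5 x 2 matrix of axial site boundaries (S1..S4, Scav)
#' @export
setGeneric("siteIntervals", function(x) standardGeneric("siteIntervals"))

#' @rdname siteIntervals
#' @export
setMethod("siteIntervals", "FrameGeometry", function(x) x@siteIntervals)

#' State-string frequencies accessor
#' @param x an [OccupancyTable-class]
#' @return named numeric
#' @export
setGeneric("stateFreq", function(x) standardGeneric("stateFreq"))

#' @rdname stateFreq
#' @export
setMethod("stateFreq", "OccupancyTable", function(x) x@stateFreq)

#' Per-site occupancy fractions accessor
#' @param x an [OccupancyTable-class] or [StationaryOccupancy-class]
#' @return matrix sites x species
#' @export
setGeneric("siteFractions", function(x) standardGeneric("siteFractions"))

#' @rdname siteFractions
#' @export
setMethod("siteFractions", "OccupancyTable", function(x) x@siteFractions)

#' @rdname siteFractions
#' @export
setMethod("siteFractions", "StationaryOccupancy", function(x) x@siteProbs)

#' Ground-truth state strings accessor
#' @param x a [SyntheticGroundTruth-class]
#' @return character vector
#' @export
setGeneric("trueStates", function(x) standardGeneric("trueStates"))

#' @rdname trueStates
#' @export
setMethod("trueStates", "SyntheticGroundTruth", function(x) x@states)

#' Ground-truth event log accessor
#' @param x a [SyntheticGroundTruth-class]
#' @return data.frame event log
#' @export
setGeneric("trueEvents", function(x) standardGeneric("trueEvents"))

#' @rdname trueEvents
#' @export
setMethod("trueEvents", "SyntheticGroundTruth", function(x) x@events)

setMethod("show", "PoreSpec", function(object) {
  cat("PoreSpec:", length(object@chains), "chains (",
      paste(object@chains, collapse = ","), "); SF",
      paste(object@sfLabels, collapse = "-"), "\n")
  cat("  particles:", nrow(object@particles), "(",
      paste(sprintf("%s=%d", names(table(object@particles$species)),
                    table(object@particles$species)), collapse = ", "),
      ")\n")
  cat("  cutoffs:", paste(sprintf("%s=%.2f", names(object@cutoffs),
                                  object@cutoffs), collapse = ", "), "\n")
})

setMethod("show", "FrameGeometry", function(object) {
  cat("FrameGeometry (axial coordinates relative to T59-O, Angstrom)\n")
  print(round(object@siteIntervals, 3))
})

setMethod("show", "SiteAssignment", function(object) {
  cat(sprintf("SiteAssignment frame %d: [%s] caF87=%s caE92=%s\n",
              object@frameIndex,
              paste(sprintf("%s=%s", names(object@occupants),
                            object@occupants), collapse = " "),
              object@caF87, object@caE92))
})

setMethod("show", "OccupancyTable", function(object) {
  cat(sprintf("OccupancyTable: %d frames, %g mV, %s\n", object@nFrames,
              object@voltage, object@condition))
  if (object@nFrames > 0L) {
    print(round(object@siteFractions, 3))
    top <- sort(object@stateFreq, decreasing = TRUE)
    top <- top[seq_len(min(5, length(top)))]
    cat("  top states:", paste(sprintf("%s=%.3f", names(top), top),
                               collapse = " "), "\n")
  }
})

setMethod("show", "CurrentEstimate", function(object) {
  cat(sprintf("CurrentEstimate: %+.4g pA at %g mV (%d out, %d in, %g ns)\n",
              object@current, object@voltage, object@nOutward,
              object@nInward, object@simTime))
})

setMethod("show", "IonTrajectory", function(object) {
  cat(sprintf("IonTrajectory: %d atoms x %d frames", nrow(object@atoms),
              nFrames(object)))
  if (!is.null(object@frameIntervalNs))
    cat(sprintf(", dt=%g ns", object@frameIntervalNs))
  if (!is.null(object@boxZ)) cat(sprintf(", boxZ=%g A", object@boxZ))
  cat("\n")
})

setMethod("show", "KineticModelParams", function(object) {
  cat(sprintf("KineticModelParams: V=%g mV, t=%g ns, dt=%g ns, jitter=%g A\n",
              object@voltage, object@tTotalNs, object@frameIntervalNs,
              object@jitterSigma))
  cat("  ions:", paste(sprintf("%s=%d", names(object@nIons), object@nIons),
                       collapse = " "),
      sprintf("| block=%s", object@blockRule), "\n")
})

setMethod("show", "SyntheticGroundTruth", function(object) {
  cat(sprintf(
    "SyntheticGroundTruth: %d frames, %d outward / %d inward events (frame-resolved)\n",
    length(object@states), object@nOutward, object@nInward))
  cat(sprintf("  exact continuous-time transits: %d outward / %d inward\n",
              object@nOutwardExact, object@nInwardExact))
})

setMethod("show", "StationaryOccupancy", function(object) {
  cat(sprintf("StationaryOccupancy over %d states; P(Ca@F87)=%.4f P(Ca@E92)=%.4f\n",
              object@nStates, object@caF87Prob, object@caE92Prob))
  print(round(object@siteProbs, 4))
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf("DensityProfile: %d bins x %d species, %d frames, r < %g A\n",
              nrow(object@counts), ncol(object@counts), object@frames,
              object@radialCutoff))
})

setMethod("show", "GateMetric", function(object) {
  m <- object@distances$mean
  cat(sprintf("GateMetric: %d frames, mean gate distance %.3f A (sd %.3f)\n",
              nrow(object@distances), mean(m), stats::sd(m)))
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport:", length(object@occupancy), "voltage conditions\n")
  if (nrow(object@iv)) print(object@iv)
})
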