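#' @include AllClasses.R
NULL

# bio3d xyz matrices are frames x 3N; reshape to n_atoms x 3 x n_frames.
.xyzToArray <- function(xyz) {
  xyz <- as.matrix(xyz)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  a <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf)) a[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  a
}

.arrayToXyz <- function(coords) {
  nf <- dim(coords)[3]
  t(vapply(seq_len(nf), function(f) as.numeric(t(coords[, , f])),
           numeric(dim(coords)[1] * 3L)))
}

#' Read a topology (single-model PDB)
#'
#' @param path PDB file path.
#' @return a bio3d `pdb` object.
#' @export
readTopology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
}

#' Read a trajectory
#'
#' Multi-model PDB is the mandatory interchange format; a DCD coordinate
#' file may be supplied instead together with a PDB topology.
#'
#' @param path multi-model PDB path, or DCD path when `topology` is given.
#' @param topology optional PDB topology path (required for DCD input).
#' @param boxZ optional box length along z (Angstrom).
#' @param frameIntervalNs optional sampling interval (ns).
#' @return an [IonTrajectory-class]
#' @export
readTrajectory <- function(path, topology = NULL, boxZ = NULL,
                           frameIntervalNs = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(topology))
      stop("a PDB topology is required to read a DCD trajectory")
    pdb <- readTopology(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    atoms <- pdb$atom
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    atoms <- pdb$atom
  }
  new("IonTrajectory", atoms = atoms, coords = .xyzToArray(xyz),
      boxZ = boxZ, frameIntervalNs = frameIntervalNs)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj an [IonTrajectory-class]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path) {
  stopifnot(is(traj, "IonTrajectory"))
  pdb <- .atomsToPdb(traj@atoms, traj@coords[, , 1, drop = TRUE])
  bio3d::write.pdb(pdb, file = path,
                   xyz = bio3d::as.xyz(.arrayToXyz(traj@coords)))
  invisible(path)
}

#' Write the first frame as a single-model PDB topology
#'
#' @inheritParams writeTrajectoryPDB
#' @return `path`, invisibly.
#' @export
writeTopologyPDB <- function(traj, path) {
  stopifnot(is(traj, "IonTrajectory"))
  pdb <- .atomsToPdb(traj@atoms, traj@coords[, , 1, drop = TRUE])
  bio3d::write.pdb(pdb, file = path)
  invisible(path)
}

# Minimal bio3d pdb object from an atom table + one coordinate frame.
.atomsToPdb <- function(atoms, coords) {
  atoms$x <- coords[, 1]
  atoms$y <- coords[, 2]
  atoms$z <- coords[, 3]
  pdb <- list(atom = atoms,
              xyz = bio3d::as.xyz(matrix(as.numeric(t(coords)), nrow = 1)),
              calpha = atoms$elety == "CA" & atoms$type == "ATOM")
  class(pdb) <- "pdb"
  pdb
}
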