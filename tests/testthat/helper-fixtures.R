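# Shared fixtures and independent oracles. Fixtures are built in code; the
# generator's scaffold doubles as the standard toy topology.

# A small synthetic run; memoised per parameter signature to keep the suite
# fast while letting several tests share one trajectory.
.fixtureCache <- new.env(parent = emptyenv())

fixtureRun <- function(voltage = 0, tTotalNs = 200, jitterSigma = 0,
                       seed = 101, ...) {
  key <- paste(voltage, tTotalNs, jitterSigma, seed,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  p <- kineticParams(voltage = voltage, tTotalNs = tTotalNs,
                     jitterSigma = jitterSigma, ...)
  res <- simulateTrajectory(p, seed = seed)
  .fixtureCache[[key]] <- res
  res
}

fixtureSpec <- function() {
  if (is.null(.fixtureCache$spec))
    .fixtureCache$spec <- fixtureRun(tTotalNs = 10)$spec
  .fixtureCache$spec
}

# Scaffold-only topology written to a PDB file, optionally mutilated.
scaffoldPDB <- function(path = tempfile(fileext = ".pdb"),
                        dropChain = NULL, dropResno = NULL,
                        dropChainResno = NULL) {
  run <- fixtureRun(tTotalNs = 10)
  traj <- run$trajectory
  atoms <- traj@atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(dropChain)) keep <- keep & atoms$chain != dropChain
  if (!is.null(dropResno)) keep <- keep & atoms$resno != dropResno
  if (!is.null(dropChainResno))
    keep <- keep & !(atoms$chain == dropChainResno[[1]] &
                       atoms$resno == as.integer(dropChainResno[[2]]))
  sub <- new("IonTrajectory", atoms = atoms[keep, , drop = FALSE],
             coords = traj@coords[keep, , 1, drop = FALSE],
             boxZ = traj@boxZ, frameIntervalNs = traj@frameIntervalNs)
  writeTopologyPDB(sub, path)
  path
}

# Independent brute-force site assignment: tests every particle against
# every site region directly from first principles (no shared code with
# assignFrame beyond the geometry object handed to both).
bruteForceAssign <- function(coords, geom, spec) {
  part <- spec@particles
  origin <- geom@axisOrigin
  ax <- geom@axisDirection
  si <- geom@siteIntervals
  cut <- spec@cutoffs
  occ <- c(S1 = "EMPTY", S2 = "EMPTY", S3 = "EMPTY", S4 = "EMPTY",
           Scav = "EMPTY")
  extra <- 0L
  for (s in rownames(si)) {
    rad <- if (s == "Scav") cut[["scav_radial"]] else cut[["sf_radial"]]
    hits <- c()
    zs <- c()
    for (i in seq_len(nrow(part))) {
      v <- coords[part$atom[i], ] - origin
      z <- sum(v * ax)
      r <- sqrt(max(sum(v * v) - z^2, 0))
      if (z >= si[s, "lo"] && z < si[s, "hi"] && r < rad) {
        hits <- c(hits, i); zs <- c(zs, z)
      }
    }
    if (length(hits)) {
      mid <- mean(si[s, ])
      ord <- order(abs(zs - mid), part$id[hits])
      occ[s] <- part$species[hits[ord[1]]]
      extra <- extra + length(hits) - 1L
    }
  }
  caF <- FALSE
  caE <- FALSE
  for (i in which(part$species == "CA")) {
    v <- coords[part$atom[i], ] - origin
    z <- sum(v * ax)
    r <- sqrt(max(sum(v * v) - z^2, 0))
    if (z >= si["Scav", "lo"] && z < si["Scav", "hi"] &&
        r < cut[["f87_radial"]]) caF <- TRUE
    for (j in spec@rings$e92_o)
      if (sqrt(sum((coords[part$atom[i], ] - coords[j, ])^2)) <
            cut[["e92_contact"]]) caE <- TRUE
  }
  list(occupants = occ, caF87 = caF, caE92 = caE, nExtra = extra)
}

# Independent permeation oracle: compartment sequence scan with explicit
# bookkeeping of the last bulk compartment visited, wraps as barriers.
bruteForceNetFlux <- function(z, f87, g63, boxZ = Inf) {
  comp <- ifelse(z < f87, 1L, ifelse(z > g63, 3L, 2L))
  nOut <- 0L
  nIn <- 0L
  lastBulk <- if (comp[1] != 2L) comp[1] else NA_integer_
  for (t in seq_along(comp)[-1]) {
    if (abs(z[t] - z[t - 1]) > boxZ / 2) {
      lastBulk <- if (comp[t] != 2L) comp[t] else NA_integer_
      next
    }
    if (comp[t] != 2L) {
      if (!is.na(lastBulk) && comp[t] != lastBulk && comp[t - 1] == 2L) {
        if (comp[t] == 3L) nOut <- nOut + 1L else nIn <- nIn + 1L
      }
      lastBulk <- comp[t]
    }
  }
  c(out = nOut, `in` = nIn)
}

# Random rigid-body transform
randomRigidTransform <- function(seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  list(R = Rx %*% Ry %*% Rz, t = runif(3, -20, 20))
}

applyTransform <- function(coords, tr) {
  sweep(coords %*% t(tr$R), 2, -tr$t)
}
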