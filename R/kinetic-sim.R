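#' @include AllClasses.R kinetic-params.R trajectory-io.R
NULL

.SP_CODE <- c(K = 1L, NH4 = 2L, CA = 3L, WAT = 4L, CL = 5L)
.SP_NAME <- names(.SP_CODE)
.CODE_LETTER <- c("O", "K", "N", "X", "W", "X")  # index = species code + 1

# ---------------------------------------------------------------------------
# Scaffold: a minimal protein frame consistent with loadPoreSpec() --
# SF carbonyl/hydroxyl oxygen rings, an F87 ring-centroid pseudo-atom, E92 and
# E96 carboxylate oxygens, and F97 C-alpha at the corners of a square of side
# gateWidth. All coordinates in Angstrom; the T59 carbonyl ring is at z = 0.
.buildScaffold <- function(params) {
  chains <- c("A", "B", "C", "D")
  azim <- (c(45, 135, 225, 315)) * pi / 180
  rows <- list()
  add <- function(chain, resno, resid, elety, x, y, z, elesy) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "ATOM", elety = elety, resid = resid, chain = chain,
      resno = resno, x = x, y = y, z = z, elesy = elesy)
  }
  ring <- function(resno, resid, elety, radius, z, elesy = "O",
                   azimOffset = 0) {
    for (i in seq_along(chains)) {
      a <- azim[i] + azimOffset
      add(chains[i], resno, resid, elety, radius * cos(a), radius * sin(a),
          z, elesy)
    }
  }
  ring(59, "THR", "O", 2.8, 0.0)
  ring(59, "THR", "OG1", 2.8, -2.5)
  ring(60, "VAL", "O", 2.8, 3.1)
  ring(61, "GLY", "O", 2.8, 6.2)
  ring(62, "TYR", "O", 2.8, 9.3)
  ring(63, "GLY", "O", 2.8, 12.4)
  ring(87, "PHE", "CZ", 6.0, -12.0, "C")
  ring(92, "GLU", "OE1", 4.0, -16.5, azimOffset = 8 * pi / 180)
  ring(92, "GLU", "OE2", 4.0, -16.5, azimOffset = -8 * pi / 180)
  ring(96, "GLU", "OE1", 7.0, -20.5, azimOffset = 8 * pi / 180)
  ring(96, "GLU", "OE2", 7.0, -20.5, azimOffset = -8 * pi / 180)
  ring(97, "PHE", "CA", params@gateWidth / sqrt(2), -20.0, "C")
  df <- do.call(rbind, rows)
  df <- df[order(match(df$chain, chains), df$resno, df$elety), ]
  atoms <- data.frame(
    type = df$type, eleno = seq_len(nrow(df)), elety = df$elety,
    alt = NA_character_, resid = df$resid, chain = df$chain,
    resno = df$resno, insert = NA_character_, x = df$x, y = df$y, z = df$z,
    o = 1, b = 0, segid = NA_character_, elesy = df$elesy,
    charge = NA_character_, stringsAsFactors = FALSE)
  atoms
}

# Representative coordinates of the ladder sites (bound Ca sits off-axis at
# F87, within the F87 radial cutoff but outside the Scav cutoff).
.siteXYZ <- function(params) {
  z <- params@siteCenters
  rbind(POOL_IN = c(NA, NA, NA),
        E92 = c(0, 0, z[["E92"]]),
        F87 = c(4 * cos(pi / 4), 4 * sin(pi / 4), z[["F87"]]),
        Scav = c(0, 0, z[["Scav"]]),
        S4 = c(0, 0, z[["S4"]]),
        S3 = c(0, 0, z[["S3"]]),
        S2 = c(0, 0, z[["S2"]]),
        S1 = c(0, 0, z[["S1"]]),
        POOL_OUT = c(NA, NA, NA))
}

.poolDraw <- function(pool, params) {
  zr <- if (pool == 1L) c(-28, -22) else c(20, 26)
  c(stats::runif(1, -12, 12), stats::runif(1, -12, 12),
    stats::runif(1, zr[1], zr[2]))
}

# ---------------------------------------------------------------------------
# Continuous-time Markov simulation (exact stochastic simulation, direct
# method). Returns the move log and exact transit counts.
.simulateCTMC <- function(params) {
  sp <- rep(.SP_CODE, params@nIons[.SP_NAME])
  P <- length(sp)
  pos <- integer(P)
  for (s in .SP_NAME) {
    idx <- which(sp == .SP_CODE[[s]])
    if (!length(idx)) next
    pos[idx] <- if (s == "CA") 1L else rep_len(c(1L, 9L), length(idx))
  }
  init <- pos
  mobile <- sp %in% c(1L, 2L, 3L) | (sp == 4L & params@waterSfRate > 0)
  occSp <- integer(9)   # species code occupying pore sites 2..8 (0 empty)
  occId <- integer(9)

  V <- params@voltage
  kT <- params@kT_mV
  nu <- params@prefactors
  dSf <- params@deltaPerHop                   # each of the 4 SF hops
  dBd <- (1 - 4 * dSf) / 2                    # the two boundary hops
  vK <- exp(V * dSf / (2 * kT))               # per-SF-hop +z factor, q = +1
  vB <- exp(V * dBd / (2 * kT))
  vCa <- exp(2 * V * params@deltaCa / (2 * kT))
  caR <- params@caRates
  nuEntry <- nu[["entry"]]; nuSf <- nu[["sf"]]; nuBulk <- nu[["bulk"]]
  e92on <- caR[["e92_on"]]; e92off <- caR[["e92_off"]]
  f87on <- caR[["f87_on"]]; f87off <- caR[["f87_off"]]
  E <- c(0, 0, 0, params@energies, 0)   # by site index 1..9 (pools, E92, F87 = 0)
  cRep <- c(0, 0, 0, params@caCoupling, 0)
  W <- params@pairRepulsion
  upNbr <- c(NA, NA, NA, NA, 6L, 7L, 8L, NA, NA)
  dnNbr <- c(NA, NA, NA, NA, NA, 5L, 6L, 7L, NA)

  # energy change when a permeant ion moves a -> b
  dU <- function(a, b) {
    caB <- occSp[3L] == 3L
    u <- E[b] - E[a] + if (caB) cRep[b] - cRep[a] else 0
    if (W != 0) {
      nb <- function(s, excl) {
        n <- 0L
        for (x in c(upNbr[s], dnNbr[s]))
          if (!is.na(x) && x != excl && (occSp[x] == 1L || occSp[x] == 2L))
            n <- n + 1L
        n
      }
      if (b >= 5L && b <= 8L) u <- u + W * nb(b, a)
      if (a >= 5L && a <= 8L) u <- u - W * nb(a, b)
    }
    u
  }

  tEnd <- params@tTotalNs
  cap <- 4096L
  mT <- numeric(cap); mP <- integer(cap); mFrom <- integer(cap)
  mTo <- integer(cap); nm <- 0L
  logMove <- function(t, p, from, to) {
    if (nm == cap) {
      cap <<- cap * 2L
      length(mT) <<- cap; length(mP) <<- cap
      length(mFrom) <<- cap; length(mTo) <<- cap
    }
    nm <<- nm + 1L
    mT[nm] <<- t; mP[nm] <<- p; mFrom[nm] <<- from; mTo[nm] <<- to
  }

  entrySide <- integer(P)   # pool an ion last entered the pore from
  nOutExact <- 0L; nInExact <- 0L
  wr <- params@waterSfRate
  hasK <- params@nIons[["K"]] > 0L
  hasN <- params@nIons[["NH4"]] > 0L
  hasCa <- params@nIons[["CA"]] > 0L
  hasW <- params@nIons[["WAT"]] > 0L && wr > 0

  # Moves available in the current occupancy pattern, with per-particle unit
  # rates; pool moves are later multiplied by the pool count of the species.
  buildMoves <- function() {
    from <- integer(0); to <- integer(0); spc <- integer(0); unit <- numeric(0)
    addMove <- function(a, b, s, r) {
      from[length(from) + 1L] <<- a; to[length(to) + 1L] <<- b
      spc[length(spc) + 1L] <<- s; unit[length(unit) + 1L] <<- r
    }
    blocked <- params@blockRule && occSp[3L] == 3L
    for (s in c(if (hasK) 1L, if (hasN) 2L)) {    # permeant cations
      addMove(1L, 9L, s, nuBulk)
      addMove(9L, 1L, s, nuBulk)
      if (occSp[4L] == 0L && !blocked)
        addMove(1L, 4L, s, nuEntry * exp(-dU(1L, 4L) / 2) * vB)
      if (occSp[8L] == 0L)
        addMove(9L, 8L, s, nuEntry * exp(-dU(9L, 8L) / 2) / vB)
      for (a in 4:8) {
        if (occSp[a] != s) next
        if (a == 4L) {
          if (!blocked)
            addMove(4L, 1L, s, nuEntry * exp(-dU(4L, 1L) / 2) / vB)
          if (occSp[5L] == 0L)
            addMove(4L, 5L, s, nuSf * exp(-dU(4L, 5L) / 2) * vK)
        } else if (a == 8L) {
          if (occSp[7L] == 0L)
            addMove(8L, 7L, s, nuSf * exp(-dU(8L, 7L) / 2) / vK)
          addMove(8L, 9L, s, nuEntry * exp(-dU(8L, 9L) / 2) * vB)
        } else {
          if (occSp[a + 1L] == 0L)
            addMove(a, a + 1L, s, nuSf * exp(-dU(a, a + 1L) / 2) * vK)
          dn <- if (a == 5L) 4L else a - 1L
          if (occSp[dn] == 0L)
            addMove(a, dn, s, nuSf * exp(-dU(a, dn) / 2) / vK)
        }
      }
    }
    if (hasCa) {
      if (occSp[2L] == 0L) addMove(1L, 2L, 3L, e92on)
      if (occSp[2L] == 3L) addMove(2L, 1L, 3L, e92off)
      if (occSp[3L] == 0L)
        addMove(1L, 3L, 3L,
                f87on * vCa * exp(-.caInteraction(params, occSp) / 2))
      if (occSp[3L] == 3L) {
        off <- f87off * exp(.caInteraction(params, occSp) / 2)
        if (params@caOffVoltageDependent) off <- off / vCa
        addMove(3L, 1L, 3L, off)
      }
    }
    if (hasW) {
      addMove(1L, 9L, 4L, nuBulk)
      addMove(9L, 1L, 4L, nuBulk)
      if (occSp[5L] == 0L) addMove(1L, 5L, 4L, wr)
      if (occSp[5L] == 4L) addMove(5L, 1L, 4L, wr)
      if (occSp[8L] == 0L) addMove(9L, 8L, 4L, wr)
      if (occSp[8L] == 4L) addMove(8L, 9L, 4L, wr)
    }
    list(from = from, to = to, spc = spc, unit = unit,
         inMove = from == 1L, outMove = from == 9L)
  }

  pw <- c(1L, 5L, 25L, 125L, 625L, 3125L, 15625L)  # base-5 digit of sites 2..8
  cache <- vector("list", 5L^7L)
  key <- 0L
  cntIn <- integer(5); cntOut <- integer(5)
  for (p in seq_len(P)) {
    if (pos[p] == 1L) cntIn[sp[p]] <- cntIn[sp[p]] + 1L
    else cntOut[sp[p]] <- cntOut[sp[p]] + 1L
  }
  t <- 0
  repeat {
    mv <- cache[[key + 1L]]
    if (is.null(mv)) {
      mv <- buildMoves()
      cache[[key + 1L]] <- mv
    }
    if (!length(mv$from)) {
      if (any(mobile) && t == 0)
        stop("zero total rate with mobile particles present")
      break
    }
    rates <- mv$unit
    rates[mv$inMove] <- rates[mv$inMove] * cntIn[mv$spc[mv$inMove]]
    rates[mv$outMove] <- rates[mv$outMove] * cntOut[mv$spc[mv$outMove]]
    R <- sum(rates)
    if (R <= 0) {
      if (any(mobile) && t == 0)
        stop("zero total rate with mobile particles present")
      break
    }
    t <- t + stats::rexp(1, R)
    if (t > tEnd) break
    u <- stats::runif(1, 0, R)
    i <- 1L
    acc <- rates[1L]
    while (acc < u && i < length(rates)) { i <- i + 1L; acc <- acc + rates[i] }
    from <- mv$from[i]; to <- mv$to[i]; spc <- mv$spc[i]
    if (from >= 2L && from <= 8L) {
      p <- occId[from]
      occSp[from] <- 0L; occId[from] <- 0L
      key <- key - spc * pw[from - 1L]
    } else {
      ids <- which(pos == from & sp == spc)
      p <- ids[1L + floor(stats::runif(1) * length(ids))]
      if (from == 1L) cntIn[spc] <- cntIn[spc] - 1L
      else cntOut[spc] <- cntOut[spc] - 1L
    }
    if (to >= 2L && to <= 8L) {
      occSp[to] <- spc; occId[to] <- p
      key <- key + spc * pw[to - 1L]
    } else {
      if (to == 1L) cntIn[spc] <- cntIn[spc] + 1L
      else cntOut[spc] <- cntOut[spc] + 1L
    }
    pos[p] <- to
    logMove(t, p, from, to)
    if (spc <= 2L) {                          # exact transit bookkeeping
      if ((from == 1L || from == 9L) && to >= 4L && to <= 8L)
        entrySide[p] <- from
      if (to == 1L || to == 9L) {
        if (from >= 4L && from <= 8L && entrySide[p] != 0L &&
            entrySide[p] != to) {
          if (to == 9L) nOutExact <- nOutExact + 1L
          else nInExact <- nInExact + 1L
        }
        entrySide[p] <- 0L
      }
    }
  }
  list(species = sp,
       init = init,
       moves = list(time = mT[seq_len(nm)], particle = mP[seq_len(nm)],
                    from = mFrom[seq_len(nm)], to = mTo[seq_len(nm)]),
       nOutExact = nOutExact, nInExact = nInExact)
}

# Per-particle site index at each frame time, from the move log.
.framePositions <- function(sim, frameTimes) {
  P <- length(sim$species)
  out <- matrix(0L, length(frameTimes), P)
  for (p in seq_len(P)) {
    sel <- which(sim$moves$particle == p)
    sites <- c(sim$init[p], sim$moves$to[sel])
    seg <- findInterval(frameTimes, sim$moves$time[sel]) + 1L
    out[, p] <- sites[seg]
  }
  out
}

# Independent frame-resolved permeation scan used for the ground-truth event
# log: split each axial trace at periodic wraps, collapse compartments, and
# count ordered bulk-filter-bulk triples.
.replayEvents <- function(zTraces, f87, g63, boxZ, species) {
  out <- list()
  for (ion in seq_len(ncol(zTraces))) {
    z <- zTraces[, ion]
    comp <- ifelse(z < f87, 1L, ifelse(z > g63, 3L, 2L))
    cuts <- which(abs(diff(z)) > boxZ / 2)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, length(z))
    for (ch in seq_along(starts)) {
      idx <- starts[ch]:ends[ch]
      r <- rle(comp[idx])
      if (length(r$values) < 3L) next
      bounds <- cumsum(r$lengths)
      for (j in seq_len(length(r$values) - 2L)) {
        a <- r$values[j]; m <- r$values[j + 1L]; b <- r$values[j + 2L]
        if (m == 2L && a != 2L && b != 2L && a != b) {
          out[[length(out) + 1L]] <- data.frame(
            particle = ion, species = species[ion],
            direction = if (b == 3L) 1L else -1L,
            entry_frame = idx[bounds[j]],
            exit_frame = idx[bounds[j + 1L] + 1L])
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(particle = integer(), species = character(),
                      direction = integer(), entry_frame = integer(),
                      exit_frame = integer()))
  do.call(rbind, out)
}

#' Simulate a synthetic ion-channel trajectory
#'
#' Runs the continuous-time kinetic Monte Carlo model of
#' [kineticParams()], samples frames every `frameIntervalNs`, places
#' particles at their site centres (bulk particles in slabs beyond the
#' pore) with isotropic Gaussian jitter, and emits a minimal protein
#' scaffold compatible with [loadPoreSpec()]. The exact ground truth --
#' per-frame states, Ca-binding flags, and the permeation event log -- is
#' returned alongside.
#'
#' The event log in the ground truth is frame-resolved: it contains the
#' complete transits observable at the sampling interval (computed from the
#' true, jitter-free coordinates by an independent compartment scan);
#' transits faster than one frame interval are additionally counted in the
#' exact continuous-time totals `nOutwardExact`/`nInwardExact`.
#'
#' @param params a [KineticModelParams-class]
#' @param seed integer RNG seed; seeded runs are bit-reproducible.
#' @param coordinates build the coordinate trajectory (set `FALSE` for long
#'   occupancy-only oracle runs).
#' @param topologyPath,trajectoryPath optional PDB output paths.
#' @param groundTruthPath optional JSON output path for the ground truth.
#' @param paramsPath optional YAML output path for the parameter echo.
#' @return list with elements `trajectory` ([IonTrajectory-class] or
#'   `NULL`), `truth` ([SyntheticGroundTruth-class]) and `spec`
#'   (a [PoreSpec-class] bound to the scaffold topology, when coordinates
#'   are built).
#' @export
simulateTrajectory <- function(params, seed = 1L, coordinates = TRUE,
                               topologyPath = NULL, trajectoryPath = NULL,
                               groundTruthPath = NULL, paramsPath = NULL) {
  stopifnot(is(params, "KineticModelParams"))
  validObject(params)
  set.seed(as.integer(seed))
  sim <- .simulateCTMC(params)
  nf <- floor(params@tTotalNs / params@frameIntervalNs) + 1L
  frameTimes <- (seq_len(nf) - 1L) * params@frameIntervalNs
  posM <- .framePositions(sim, frameTimes)
  sp <- sim$species
  P <- length(sp)

  # per-frame true site occupants (species codes) for S1..S4, Scav
  siteIdx <- c(S1 = 8L, S2 = 7L, S3 = 6L, S4 = 5L, Scav = 4L)
  occCode <- sapply(siteIdx, function(s)
    as.integer((posM == s) %*% sp))
  states <- apply(matrix(.CODE_LETTER[occCode[, 1:4] + 1L], nf, 4L), 1,
                  paste, collapse = "")
  spLab <- c("K", "NH4", "CA", "WAT", "CL")
  occLab <- matrix("EMPTY", nf, 5L, dimnames = list(NULL, names(siteIdx)))
  occLab[occCode > 0L] <- spLab[occCode[occCode > 0L]]
  caF87 <- as.logical((posM == 3L) %*% (sp == 3L))
  caE92 <- as.logical((posM == 2L) %*% (sp == 3L))

  # base coordinates per residence segment (pool residences get one draw)
  sxyz <- .siteXYZ(params)
  baseX <- matrix(0, nf, P); baseY <- matrix(0, nf, P); baseZ <- matrix(0, nf, P)
  for (p in seq_len(P)) {
    sel <- which(sim$moves$particle == p)
    sites <- c(sim$init[p], sim$moves$to[sel])
    segBase <- matrix(0, length(sites), 3L)
    for (i in seq_along(sites)) {
      segBase[i, ] <- if (sites[i] %in% c(1L, 9L))
        .poolDraw(sites[i], params) else sxyz[sites[i], ]
    }
    seg <- findInterval(frameTimes, sim$moves$time[sel]) + 1L
    baseX[, p] <- segBase[seg, 1L]
    baseY[, p] <- segBase[seg, 2L]
    baseZ[, p] <- segBase[seg, 3L]
  }

  permeant <- which(sp <= 2L)
  events <- .replayEvents(baseZ[, permeant, drop = FALSE],
                          f87 = -12, g63 = 12.4, boxZ = params@boxZ,
                          species = spLab[sp[permeant]])
  truth <- new("SyntheticGroundTruth",
               states = states, siteOccupants = occLab,
               caF87 = caF87, caE92 = caE92, events = events,
               nOutward = sum(events$direction == 1L),
               nInward = sum(events$direction == -1L),
               nOutwardExact = sim$nOutExact, nInwardExact = sim$nInExact,
               params = params, seed = as.integer(seed))

  traj <- NULL
  spec <- NULL
  if (coordinates) {
    scaffold <- .buildScaffold(params)
    S <- nrow(scaffold)
    partAtoms <- if (P == 0L) scaffold[0, ] else data.frame(
      type = "HETATM", eleno = S + seq_len(P),
      elety = c("K", "N", "CA", "O", "CL")[sp],
      alt = NA_character_,
      resid = c("K", "NH4", "CA", "HOH", "CL")[sp],
      chain = "X", resno = 200L + seq_len(P), insert = NA_character_,
      x = 0, y = 0, z = 0, o = 1, b = 0, segid = NA_character_,
      elesy = c("K", "N", "CA", "O", "CL")[sp],
      charge = NA_character_, stringsAsFactors = FALSE)
    atoms <- rbind(scaffold, partAtoms)
    coords <- array(0, c(S + P, 3L, nf))
    scaffBase <- as.matrix(scaffold[, c("x", "y", "z")])
    sig <- params@jitterSigma
    for (f in seq_len(nf)) {
      fr <- rbind(scaffBase, cbind(baseX[f, ], baseY[f, ], baseZ[f, ]))
      if (sig > 0) fr <- fr + matrix(stats::rnorm(length(fr), 0, sig),
                                     nrow(fr), 3L)
      coords[, , f] <- fr
    }
    traj <- new("IonTrajectory", atoms = atoms, coords = coords,
                boxZ = params@boxZ,
                frameIntervalNs = params@frameIntervalNs)
    spec <- loadPoreSpec(.atomsToPdb(atoms, coords[, , 1]))
    if (!is.null(topologyPath)) writeTopologyPDB(traj, topologyPath)
    if (!is.null(trajectoryPath)) writeTrajectoryPDB(traj, trajectoryPath)
  }
  if (!is.null(groundTruthPath)) writeGroundTruthJSON(truth, groundTruthPath)
  if (!is.null(paramsPath)) writeParamsYAML(params, paramsPath)
  list(trajectory = traj, truth = truth, spec = spec)
}

#' Write generator ground truth as JSON
#'
#' @param truth a [SyntheticGroundTruth-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruthJSON <- function(truth, path) {
  jsonlite::write_json(
    list(seed = truth@seed,
         n_outward = truth@nOutward, n_inward = truth@nInward,
         n_outward_exact = truth@nOutwardExact,
         n_inward_exact = truth@nInwardExact,
         states = truth@states, ca_f87 = truth@caF87, ca_e92 = truth@caE92,
         events = truth@events),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write generator parameters as YAML
#'
#' @param params a [KineticModelParams-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeParamsYAML <- function(params, path) {
  sl <- methods::slotNames(params)
  vals <- lapply(sl, function(s) {
    v <- methods::slot(params, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}
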