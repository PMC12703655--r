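test_that("a single particle lands in the right density bin", {
  run <- fixtureRun(tTotalNs = 10)
  spec <- run$spec
  traj <- run$trajectory
  coords <- traj@coords[, , 1]
  part <- spec@particles
  coords[part$atom, ] <- matrix(rep(c(50, 50, 0), nrow(part)),
                                ncol = 3, byrow = TRUE)
  kAtom <- part$atom[part$species == "K"][1]
  coords[kAtom, ] <- c(0, 0, -5.2)
  t1 <- new("IonTrajectory", atoms = traj@atoms,
            coords = array(coords, c(nrow(coords), 3, 1)),
            boxZ = traj@boxZ, frameIntervalNs = NULL)
  prof <- axialDensity(t1, spec, radialCutoff = 8, binWidth = 0.5,
                       zRange = c(-25, 5))
  centres <- (prof@binEdges[-1] + head(prof@binEdges, -1)) / 2
  hit <- which(prof@counts[, "K"] > 0)
  expect_length(hit, 1L)
  expect_true(prof@binEdges[hit] <= -5.2 && prof@binEdges[hit + 1] > -5.2)
  expect_identical(sum(prof@counts[, "K"]), 1)
})

test_that("histogram mass equals the mean in-region particle count", {
  run <- fixtureRun(voltage = 0, tTotalNs = 100, jitterSigma = 0.3, seed = 9)
  prof <- axialDensity(run$trajectory, run$spec, radialCutoff = 8,
                       binWidth = 0.5, zRange = c(-25, 5))
  # recount independently
  spec <- run$spec
  part <- spec@particles
  total <- 0
  nf <- nFrames(run$trajectory)
  for (f in seq_len(nf)) {
    coords <- run$trajectory@coords[, , f]
    geom <- frameGeometry(coords, spec)
    for (i in seq_len(nrow(part))) {
      v <- coords[part$atom[i], ] - geom@axisOrigin
      z <- sum(v * geom@axisDirection)
      r <- sqrt(max(sum(v^2) - z^2, 0))
      if (r < 8 && z >= -25 && z < 5) total <- total + 1
    }
  }
  expect_lt(abs(sum(prof@counts) - total), 1e-9)
  expect_lt(abs(sum(prof@perFrame) - total / nf), 1e-9)
})

test_that("uniform placements give a flat profile within Poisson bounds", {
  run <- fixtureRun(tTotalNs = 10)
  spec <- run$spec
  traj <- run$trajectory
  base <- traj@coords[, , 1]
  part <- spec@particles
  kAtoms <- part$atom[part$species == "K"]
  set.seed(31)
  nf <- 2500L   # 4 K ions x 2500 frames = 1e4 placements
  coords <- array(rep(base, nf), c(nrow(base), 3, nf))
  for (f in seq_len(nf)) {
    # uniform in the cylinder r < 8, z in [-25, 5)
    rr <- 8 * sqrt(runif(4)); th <- runif(4, 0, 2 * pi)
    coords[kAtoms, 1, f] <- rr * cos(th)
    coords[kAtoms, 2, f] <- rr * sin(th)
    coords[kAtoms, 3, f] <- runif(4, -25, 5)
  }
  tU <- new("IonTrajectory", atoms = traj@atoms, coords = coords,
            boxZ = NULL, frameIntervalNs = NULL)
  prof <- axialDensity(tU, spec, radialCutoff = 8, binWidth = 1,
                       zRange = c(-25, 5), species = "K")
  counts <- prof@counts[, "K"]
  expected <- sum(counts) / length(counts)
  expect_true(all(abs(counts - expected) < 3 * sqrt(expected) + 1))
})

test_that("Ca2+ density peaks at the F87 plane only under positive bias", {
  pos <- fixtureRun(voltage = 300, tTotalNs = 150, jitterSigma = 0.3,
                    seed = 13)
  neg <- fixtureRun(voltage = -300, tTotalNs = 150, jitterSigma = 0.3,
                    seed = 13)
  pPos <- axialDensity(pos$trajectory, pos$spec, species = "CA")
  pNeg <- axialDensity(neg$trajectory, neg$spec, species = "CA")
  centres <- (pPos@binEdges[-1] + head(pPos@binEdges, -1)) / 2
  nearF87 <- abs(centres - (-11.5)) <= 1
  # sharp peak present under +V, absent under -V
  expect_gt(sum(pPos@perFrame[nearF87, "CA"]), 0.5)
  expect_lt(sum(pNeg@perFrame[nearF87, "CA"]), 0.05)
})

test_that("gate distances follow square geometry and chain relabeling", {
  run <- fixtureRun(tTotalNs = 10)
  gm <- gateDistance(run$trajectory, run$spec)
  # side 18 A -> diagonals 18 * sqrt(2)
  expect_equal(mean(gm@distances$d13), 18 * sqrt(2), tolerance = 1e-6)
  expect_equal(mean(gm@distances$d24), 18 * sqrt(2), tolerance = 1e-6)

  # displace one CA outward along its diagonal by 2 A
  traj <- run$trajectory
  spec <- run$spec
  ca <- spec@rings$f97_ca
  coords <- traj@coords[, , 1]
  dir <- coords[ca[1], ] - coords[ca[3], ]
  dir <- dir / sqrt(sum(dir^2))
  coords[ca[1], ] <- coords[ca[1], ] + 2 * dir
  t1 <- new("IonTrajectory", atoms = traj@atoms,
            coords = array(coords, c(nrow(coords), 3, 1)), boxZ = NULL,
            frameIntervalNs = NULL)
  g1 <- gateDistance(t1, spec)
  expect_equal(g1@distances$d13, 18 * sqrt(2) + 2, tolerance = 1e-6)
  expect_equal(g1@distances$d24, 18 * sqrt(2), tolerance = 1e-6)
})

test_that("generator gate widths are recovered from the trajectories", {
  a <- fixtureRun(tTotalNs = 150, jitterSigma = 0.3, seed = 21,
                  gateWidth = 18)
  b <- fixtureRun(tTotalNs = 150, jitterSigma = 0.3, seed = 22,
                  gateWidth = 16)
  da <- mean(gateDistance(a$trajectory, a$spec)@distances$mean)
  db <- mean(gateDistance(b$trajectory, b$spec)@distances$mean)
  expect_equal(da - db, 2 * sqrt(2), tolerance = 0.1)
})

test_that("RMSD is zero against itself and after pure translation", {
  run <- fixtureRun(tTotalNs = 10)
  traj <- run$trajectory
  ref <- traj@coords[, , 1]
  nrep <- 5L
  coords <- array(rep(ref, nrep), c(nrow(ref), 3, nrep))
  tSame <- new("IonTrajectory", atoms = traj@atoms, coords = coords,
               boxZ = NULL, frameIntervalNs = NULL)
  fm <- rmsdRmsf(tSame, reference = ref)
  expect_equal(fm@rmsd, rep(0, nrep), tolerance = 1e-7)
  expect_equal(fm@rmsfAtom$rmsf, rep(0, nrow(fm@rmsfAtom)), tolerance = 1e-7)

  # translate the reference: fitting removes it exactly
  fm2 <- rmsdRmsf(tSame, reference = sweep(ref, 2, c(-3, -4, 0)))
  expect_equal(fm2@rmsd, rep(0, nrep), tolerance = 1e-7)
})

test_that("RMSF approaches sigma * sqrt(3) under isotropic jitter", {
  run <- fixtureRun(tTotalNs = 10)
  traj <- run$trajectory
  ref <- traj@coords[, , 1]
  protein <- which(traj@atoms$type == "ATOM")
  sigma <- 0.5
  nf <- 10000L
  set.seed(8)
  coords <- array(rep(ref, nf), c(nrow(ref), 3, nf))
  coords <- coords + array(rnorm(length(coords), 0, sigma), dim(coords))
  tJ <- new("IonTrajectory", atoms = traj@atoms, coords = coords,
            boxZ = NULL, frameIntervalNs = NULL)
  fm <- rmsdRmsf(tJ, reference = ref, selection = protein)
  expect_equal(mean(fm@rmsfAtom$rmsf), sigma * sqrt(3), tolerance = 0.05)
  expect_true(all(fm@rmsd >= 0))
})

test_that("RMSF is invariant to a global rigid-body motion of every frame", {
  run <- fixtureRun(tTotalNs = 40, jitterSigma = 0.3)
  traj <- run$trajectory
  protein <- which(traj@atoms$type == "ATOM")
  fm0 <- rmsdRmsf(traj, selection = protein)
  tr <- randomRigidTransform(4)
  coords <- traj@coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- applyTransform(coords[, , f], tr)
  fm1 <- rmsdRmsf(new("IonTrajectory", atoms = traj@atoms, coords = coords,
                      boxZ = NULL, frameIntervalNs = NULL),
                  reference = traj@coords[, , 1], selection = protein)
  expect_equal(fm1@rmsfAtom$rmsf, fm0@rmsfAtom$rmsf, tolerance = 1e-6)
})

test_that("empty z range and bad bins are rejected", {
  run <- fixtureRun(tTotalNs = 10)
  expect_error(axialDensity(run$trajectory, run$spec, zRange = c(5, 5)),
               "empty z range")
  expect_error(axialDensity(run$trajectory, run$spec, binWidth = 0),
               "positive")
})
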