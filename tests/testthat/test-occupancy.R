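# Helpers to plant particles at chosen cylindrical positions in a scaffold
# frame and run the assignment.
plantedFrame <- function(run, at = list()) {
  coords <- run$trajectory@coords[, , 1]
  part <- run$spec@particles
  # park every particle far outside all regions first
  coords[part$atom, ] <- matrix(rep(c(50, 50, 0), nrow(part)),
                                ncol = 3, byrow = TRUE)
  for (a in at) {
    i <- which(part$species == a$species)[a$nth %||% 1]
    coords[part$atom[i], ] <- a$xyz
  }
  coords
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("single-ion placements land in the intended sites", {
  run <- fixtureRun(tTotalNs = 10)
  spec <- run$spec
  # one K+ at the S3 midpoint (z = 1.55, on axis)
  coords <- plantedFrame(run, list(list(species = "K", xyz = c(0, 0, 1.55))))
  a <- assignFrame(coords, frameGeometry(coords, spec), spec)
  expect_identical(unname(a@occupants[c("S1", "S2", "S3", "S4", "Scav")]),
                   c("EMPTY", "EMPTY", "K", "EMPTY", "EMPTY"))
  expect_identical(encodeState(a), "OOKO")
  expect_false(a@caF87)

  # K+ at S1, S3, S4 midpoints plus a Ca2+ in the F87 region
  coords <- plantedFrame(run, list(
    list(species = "K", xyz = c(0, 0, 7.75)),
    list(species = "K", xyz = c(0, 0, 1.55), nth = 2),
    list(species = "K", xyz = c(0, 0, -1.25), nth = 3),
    list(species = "CA", xyz = c(4 / sqrt(2), 4 / sqrt(2), -11.5))))
  a <- assignFrame(coords, frameGeometry(coords, spec), spec)
  expect_identical(encodeState(a), "KOKK")
  expect_true(a@caF87)
  expect_identical(nrow(a@extraOccupants), 0L)
})

test_that("state encoding matches the published letter codes", {
  expect_identical(encodeState(c("K", "EMPTY", "K", "EMPTY")), "KOKO")
  expect_identical(encodeState(c("K", "K", "EMPTY", "K")), "KKOK")
  expect_identical(encodeState(rep("EMPTY", 4)), "OOOO")
  expect_identical(encodeState(c("NH4", "WAT", "EMPTY", "K")), "NWOK")
})

test_that("ties inside one site go to the particle nearer the midpoint", {
  run <- fixtureRun(tTotalNs = 10)
  spec <- run$spec
  # two K+ 0.3 A either side of the S2 midpoint (4.65), one slightly nearer
  coords <- plantedFrame(run, list(
    list(species = "K", xyz = c(0, 0, 4.65 + 0.30)),
    list(species = "K", xyz = c(0, 0, 4.65 - 0.25), nth = 2)))
  geom <- frameGeometry(coords, spec)
  a <- assignFrame(coords, geom, spec)
  part <- spec@particles
  nearer <- part$id[which(part$species == "K")[2]]
  expect_identical(unname(a@occupantIds["S2"]), nearer)
  expect_identical(nrow(a@extraOccupants), 1L)
  # and the brute-force oracle agrees
  bf <- bruteForceAssign(coords, geom, spec)
  expect_identical(bf$occupants, a@occupants)
  expect_identical(bf$nExtra, 1L)
})

test_that("Ca2+ below the SF sets the conditioning label, E92 does not", {
  run <- fixtureRun(tTotalNs = 10)
  spec <- run$spec
  geomOf <- function(coords) frameGeometry(coords, spec)
  # Ca at the F87 position
  c1 <- plantedFrame(run, list(
    list(species = "CA", xyz = c(4 / sqrt(2), 4 / sqrt(2), -11.5))))
  a1 <- assignFrame(c1, geomOf(c1), spec)
  expect_true(a1@caF87)
  # Ca only at the E92 ring centre
  c2 <- plantedFrame(run, list(list(species = "CA", xyz = c(0, 0, -16.5))))
  a2 <- assignFrame(c2, geomOf(c2), spec)
  expect_false(a2@caF87)
  expect_true(a2@caE92)
  expect_false(labelCaBound(list(a2)))
  # no Ca anywhere
  c3 <- plantedFrame(run, list())
  a3 <- assignFrame(c3, geomOf(c3), spec)
  expect_false(a3@caF87 || a3@caE92)
})

test_that("per-frame assignment equals brute force on randomized frames", {
  run <- fixtureRun(tTotalNs = 10)
  spec <- run$spec
  base <- run$trajectory@coords[, , 1]
  part <- spec@particles
  set.seed(2024)
  for (f in 1:200) {
    coords <- base
    coords[part$atom, 1] <- runif(nrow(part), -10, 10)
    coords[part$atom, 2] <- runif(nrow(part), -10, 10)
    coords[part$atom, 3] <- runif(nrow(part), -20, 16)
    geom <- frameGeometry(coords, spec)
    a <- assignFrame(coords, geom, spec)
    bf <- bruteForceAssign(coords, geom, spec)
    expect_identical(a@occupants, bf$occupants)
    expect_identical(a@caF87, bf$caF87)
    expect_identical(a@caE92, bf$caE92)
  }
})

test_that("occupancy aggregation counts states and normalises", {
  df <- data.frame(frame = 1:100,
                   S1 = "K", S2 = c(rep("EMPTY", 50), rep("K", 50)),
                   S3 = c(rep("K", 50), rep("EMPTY", 50)),
                   S4 = c(rep("EMPTY", 50), rep("K", 50)),
                   Scav = "EMPTY",
                   code = c(rep("KOKO", 50), rep("KKOK", 50)),
                   caF87 = FALSE, caE92 = FALSE, nExtra = 0L,
                   stringsAsFactors = FALSE)
  tabs <- aggregateOccupancy(df, voltage = 0)
  free <- tabs$ca_free
  expect_identical(free@nFrames, 100L)
  expect_equal(unname(stateFreq(free)[c("KOKO", "KKOK")]), c(0.5, 0.5))
  expect_equal(unname(siteFractions(free)["S2", "K"]), 0.5)
  expect_equal(unname(siteFractions(free)["S1", "K"]), 1.0)
  expect_equal(rowSums(siteFractions(free)), rep(1, 5),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(stateFreq(free)), 1, tolerance = 1e-12)
  # all labels false: bound table must be the zero-frame table
  bound <- tabs$ca_bound
  expect_identical(bound@nFrames, 0L)
  expect_length(stateFreq(bound), 0L)
})

test_that("a constant all-free stream yields unit fractions", {
  df <- data.frame(frame = 1:100, S1 = "K", S2 = "EMPTY", S3 = "K",
                   S4 = "EMPTY", Scav = "EMPTY", code = "KOKO",
                   caF87 = FALSE, caE92 = FALSE, nExtra = 0L,
                   stringsAsFactors = FALSE)
  tabs <- aggregateOccupancy(df, voltage = 0)
  sf <- siteFractions(tabs$ca_free)
  expect_equal(unname(sf[c("S1", "S3"), "K"]), c(1, 1))
  expect_equal(unname(sf[c("S2", "S4"), "K"]), c(0, 0))
  expect_equal(unname(stateFreq(tabs$ca_free)[["KOKO"]]), 1)
})

test_that("zero frames overall is an error", {
  df <- data.frame(frame = integer(), S1 = character(), S2 = character(),
                   S3 = character(), S4 = character(), Scav = character(),
                   code = character(), caF87 = logical(), caE92 = logical(),
                   nExtra = integer(), stringsAsFactors = FALSE)
  expect_error(aggregateOccupancy(df), "zero frames")
})

test_that("single-file exclusion means no extra occupants on generator data", {
  run <- fixtureRun(voltage = 300, tTotalNs = 150, jitterSigma = 0.3,
                    seed = 5)
  df <- assignTrajectory(run$trajectory, run$spec)
  expect_true(all(df$nExtra == 0L))
})

test_that("state table TSV round-trips", {
  run <- fixtureRun(tTotalNs = 20)
  df <- assignTrajectory(run$trajectory, run$spec)
  path <- tempfile(fileext = ".tsv")
  writeStateTable(df, path)
  back <- read.delim(path)
  expect_identical(nrow(back), nrow(df))
  expect_identical(back$code, df$code)
})
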