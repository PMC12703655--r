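#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Pore specification
#'
#' Binds a parsed channel topology to the residue roles the analysis needs:
#' the TVGYG selectivity-filter (SF) residues per chain, the auxiliary
#' residues below the filter (F87, E92, E96, F97), the mobile particles
#' (ions and water) with their species labels, and the geometric cutoffs.
#' Create with [loadPoreSpec()].
#'
#' @slot atoms data.frame of topology atoms (bio3d column layout plus a
#'   `species` column; protein atoms carry species `NA`).
#' @slot chains character vector of protein chain identifiers, in the order
#'   used for ring construction and gate diagonals.
#' @slot rings named list of integer vectors of atom indices: one entry per
#'   oxygen ring (`t59_o`, `t59_og1`, `v60_o`, `g61_o`, `y62_o`, `g63_o`),
#'   plus `f97_ca` and `e92_o`; `f87_ring` is a list of per-chain index
#'   vectors whose centroids define the F87 plane.
#' @slot sfLabels character labels of the SF residues (e.g. `"T59"`).
#' @slot particles data.frame with columns `atom` (row index into `atoms`),
#'   `species` (K, NH4, CA, CL, WAT or other) and `id`.
#' @slot cutoffs named numeric: `sf_radial`, `scav_radial`, `f87_radial`
#'   (distances from the pore axis, Angstrom) and `e92_contact` (distance
#'   from an E92 carboxylate oxygen, Angstrom).
#' @slot speciesMap named character mapping residue names to species labels.
#' @export
setClass("PoreSpec", representation(
  atoms = "data.frame",
  chains = "character",
  rings = "list",
  sfLabels = "character",
  particles = "data.frame",
  cutoffs = "numeric",
  speciesMap = "character"
))

setValidity("PoreSpec", function(object) {
  msg <- character()
  if (length(object@chains) < 3)
    msg <- c(msg, "fewer than 3 chains")
  if (length(object@sfLabels) != 5L)
    msg <- c(msg, "sfLabels must name exactly 5 SF residues")
  need <- c("t59_o", "t59_og1", "v60_o", "g61_o", "y62_o", "g63_o",
            "f87_ring", "e92_o", "f97_ca")
  if (!all(need %in% names(object@rings)))
    msg <- c(msg, paste("rings must contain:", paste(need, collapse = ", ")))
  needCut <- c("sf_radial", "scav_radial", "f87_radial", "e92_contact")
  if (!all(needCut %in% names(object@cutoffs)) ||
      any(object@cutoffs[needCut] <= 0))
    msg <- c(msg, "cutoffs must be positive and complete")
  if (length(msg)) msg else TRUE
})

#' Per-frame pore geometry
#'
#' Instantaneous geometric frame of the pore: the principal axis of the SF
#' backbone-oxygen set (signed so that +z points extracellular), the origin
#' at the centroid of the four T59 carbonyl oxygens, and the axial planes
#' and site intervals derived from the symmetry-equivalent oxygen rings.
#' All plane/interval coordinates are axial positions relative to the T59
#' carbonyl reference (Angstrom), so the T59-O plane is 0 by construction.
#'
#' @slot axisOrigin numeric(3), centroid of the T59 carbonyl oxygens.
#' @slot axisDirection numeric(3), unit vector along the pore, +z toward the
#'   extracellular side.
#' @slot planes named numeric of ring planes relative to the reference:
#'   `G63`, `Y62`, `G61`, `V60`, `T59O` (= 0), `T59OG1`, `F87`.
#' @slot siteIntervals 5 x 2 matrix (rows S1, S2, S3, S4, Scav; columns
#'   `lo`, `hi`) of axial site boundaries.
#' @slot cutoffs named numeric, copied from the [PoreSpec-class].
#' @export
setClass("FrameGeometry", representation(
  axisOrigin = "numeric",
  axisDirection = "numeric",
  planes = "numeric",
  siteIntervals = "matrix",
  cutoffs = "numeric"
))

setValidity("FrameGeometry", function(object) {
  msg <- character()
  if (length(object@axisOrigin) != 3L || length(object@axisDirection) != 3L)
    msg <- c(msg, "axisOrigin and axisDirection must be length-3")
  if (abs(sqrt(sum(object@axisDirection^2)) - 1) > 1e-8)
    msg <- c(msg, "axisDirection must be a unit vector")
  si <- object@siteIntervals
  if (!identical(rownames(si), c("S1", "S2", "S3", "S4", "Scav")))
    msg <- c(msg, "siteIntervals rows must be S1, S2, S3, S4, Scav")
  if (any(si[, "hi"] <= si[, "lo"]))
    msg <- c(msg, "every site interval must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Single-frame site assignment
#'
#' Mapping of particles to the five pore sites for one trajectory frame,
#' together with the divalent-binding flags used to condition occupancy
#' statistics. At most one occupant is recorded per site; when two
#' particles fall inside one site's region the one nearer the axial
#' midpoint wins and the rest are listed in `extraOccupants`.
#'
#' @slot frameIndex integer frame number.
#' @slot occupants named character (S1, S2, S3, S4, Scav): species label or
#'   `"EMPTY"`.
#' @slot occupantIds named integer particle ids (NA when empty).
#' @slot extraOccupants data.frame with columns `site` and `particle`.
#' @slot caF87 logical: a Ca2+ ion occupies the F87 region below the filter.
#' @slot caE92 logical: a Ca2+ ion is in contact with the E92 glutamate ring.
#' @export
setClass("SiteAssignment", representation(
  frameIndex = "integer",
  occupants = "character",
  occupantIds = "integer",
  extraOccupants = "data.frame",
  caF87 = "logical",
  caE92 = "logical"
))

#' Aggregated occupancy statistics
#'
#' Normalised per-site occupancy fractions and state-string frequencies for
#' one voltage and one Ca-binding condition. Produced by
#' [aggregateOccupancy()].
#'
#' @slot siteFractions matrix (sites x species incl. EMPTY); each row sums
#'   to 1 when `nFrames > 0`.
#' @slot stateFreq named numeric of 4-letter state-string frequencies,
#'   summing to 1 when `nFrames > 0`.
#' @slot nFrames integer number of frames in the condition.
#' @slot voltage numeric voltage label (mV).
#' @slot condition character, `"ca_bound"` or `"ca_free"`.
#' @export
setClass("OccupancyTable", representation(
  siteFractions = "matrix",
  stateFreq = "numeric",
  nFrames = "integer",
  voltage = "numeric",
  condition = "character"
))

setValidity("OccupancyTable", function(object) {
  if (object@nFrames > 0L) {
    rs <- rowSums(object@siteFractions)
    if (any(abs(rs - 1) > 1e-9))
      return("site fractions must sum to 1 per site")
    if (abs(sum(object@stateFreq) - 1) > 1e-9)
      return("state frequencies must sum to 1")
  }
  TRUE
})

#' Applied-field specification
#'
#' Uniform external electric field along the pore (z) axis, as used in
#' voltage-biased simulations. The transmembrane voltage is
#' `V = E_z * box_z` (mV), positive voltage driving cations outward.
#'
#' @slot Ez numeric field strength, mV/Angstrom, signed along +z.
#' @slot boxZ numeric box length along z, Angstrom (> 0).
#' @export
setClass("FieldSpec", representation(Ez = "numeric", boxZ = "numeric"))

setValidity("FieldSpec", function(object) {
  if (length(object@boxZ) != 1L || object@boxZ <= 0)
    return("boxZ must be a positive scalar")
  TRUE
})

#' Single-channel current estimate
#'
#' Net permeation count converted to a current:
#' `I = (n_outward - n_inward) * e / T`, reported in pA with positive sign
#' for net outward flow.
#'
#' @slot nOutward,nInward integer event counts.
#' @slot simTime numeric simulated time, ns.
#' @slot current numeric current, pA.
#' @slot voltage numeric applied voltage, mV.
#' @export
setClass("CurrentEstimate", representation(
  nOutward = "integer",
  nInward = "integer",
  simTime = "numeric",
  current = "numeric",
  voltage = "numeric"
))

#' Axial density profile
#'
#' Binned axial number density of each species inside a cylinder around the
#' pore axis, with coordinates relative to the T59 carbonyl reference.
#' Both raw bin counts and the per-frame mean are stored.
#'
#' @slot binEdges numeric bin edges, Angstrom relative to T59.
#' @slot counts matrix bins x species, raw counts summed over frames.
#' @slot perFrame matrix bins x species, `counts / frames`.
#' @slot frames integer number of frames.
#' @slot radialCutoff numeric cylinder radius, Angstrom.
#' @export
setClass("DensityProfile", representation(
  binEdges = "numeric",
  counts = "matrix",
  perFrame = "matrix",
  frames = "integer",
  radialCutoff = "numeric"
))

#' Lower-gate metric
#'
#' Per-frame distances between opposing F97 C-alpha atoms (the two
#' cross-pore diagonals) and their mean, a measure of lower-gate opening.
#'
#' @slot distances data.frame with columns `frame`, `d13`, `d24`, `mean`.
#' @slot chains character(4), chain order used for the diagonals
#'   (1-3 and 2-4).
#' @export
setClass("GateMetric", representation(
  distances = "data.frame",
  chains = "character"
))

#' Flexibility metric
#'
#' RMSD time series against a reference structure after rigid-body
#' superposition, and per-atom / per-residue RMSF about the time-averaged
#' structure.
#'
#' @slot rmsd numeric per-frame RMSD, Angstrom.
#' @slot rmsfAtom data.frame with columns `chain`, `resno`, `elety`, `rmsf`.
#' @slot rmsfResidue data.frame with columns `chain`, `resno`, `rmsf`.
#' @export
setClass("FlexibilityMetric", representation(
  rmsd = "numeric",
  rmsfAtom = "data.frame",
  rmsfResidue = "data.frame"
))

#' In-memory ion-channel trajectory
#'
#' Atom table plus a coordinate array for a multi-frame trajectory.
#' Constructed by [readTrajectory()] or by the kinetic generator
#' [simulateTrajectory()].
#'
#' @slot atoms data.frame in bio3d atom layout.
#' @slot coords numeric array `n_atoms x 3 x n_frames`.
#' @slot boxZ numeric box length along z (Angstrom) or `NULL`.
#' @slot frameIntervalNs numeric time between frames (ns) or `NULL`.
#' @export
setClass("IonTrajectory", representation(
  atoms = "data.frame",
  coords = "array",
  boxZ = "numericOrNULL",
  frameIntervalNs = "numericOrNULL"
))

setValidity("IonTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@atoms))
    return("coords first dimension must match the atom table")
  TRUE
})

#' Kinetic ion-hopping model parameters
#'
#' Parameters of the continuous-time Markov (kinetic Monte Carlo) generator
#' of single-file ion-hopping trajectories. Permeant cations (K+, NH4+)
#' hop along the ladder bulk_in - Scav - S4 - S3 - S2 - S1 - bulk_out under
#' site exclusion; Ca2+ binds the F87 site (voltage-dependent on-rate) and
#' the E92 ring (voltage-independent) and, while seated at F87, blocks the
#' bulk_in - Scav passage. See [kineticParams()] for defaults and units.
#'
#' @slot voltage numeric applied voltage, mV.
#' @slot nIons named integer counts: K, NH4, CA, CL, WAT.
#' @slot siteCenters named numeric axial centers (Angstrom, T59-O = 0).
#' @slot energies named numeric site free energies for permeant ions (kT).
#' @slot prefactors named numeric hop-attempt prefactors (1/ns).
#' @slot pairRepulsion numeric adjacent-pair penalty inside the SF (kT).
#' @slot caCoupling named numeric interaction energy (kT) between an F87-
#'   bound Ca2+ and a permeant ion at each pore site.
#' @slot caRates named numeric Ca2+ binding/unbinding rates (1/ns).
#' @slot deltaPerHop numeric fractional electrical distance per permeant hop.
#' @slot deltaCa numeric fractional electrical distance for Ca2+ binding
#'   at F87.
#' @slot caOffVoltageDependent logical, apply the inverse voltage factor to
#'   the F87 off-rate.
#' @slot blockRule logical, enable the F87 Ca2+ check-valve block.
#' @slot kT_mV numeric thermal energy in mV units (kT/e at 310 K).
#' @slot jitterSigma numeric coordinate jitter s.d., Angstrom.
#' @slot gateWidth numeric F97 C-alpha square side, Angstrom.
#' @slot boxZ numeric box length along z, Angstrom.
#' @slot frameIntervalNs numeric trajectory sampling interval, ns.
#' @slot tTotalNs numeric simulated time, ns.
#' @slot waterSfRate numeric attempt rate for transient water visits to the
#'   outer sites S1/S4 (1/ns; 0 disables).
#' @export
setClass("KineticModelParams", representation(
  voltage = "numeric",
  nIons = "integer",
  siteCenters = "numeric",
  energies = "numeric",
  prefactors = "numeric",
  pairRepulsion = "numeric",
  caCoupling = "numeric",
  caRates = "numeric",
  deltaPerHop = "numeric",
  deltaCa = "numeric",
  caOffVoltageDependent = "logical",
  blockRule = "logical",
  kT_mV = "numeric",
  jitterSigma = "numeric",
  gateWidth = "numeric",
  boxZ = "numeric",
  frameIntervalNs = "numeric",
  tTotalNs = "numeric",
  waterSfRate = "numeric"
))

setValidity("KineticModelParams", function(object) {
  msg <- character()
  if (any(object@prefactors < 0) || any(object@caRates < 0))
    msg <- c(msg, "rates must be non-negative")
  if (object@deltaPerHop <= 0 || object@deltaPerHop > 0.25)
    msg <- c(msg, "deltaPerHop must lie in (0, 0.25]")
  if (object@jitterSigma < 0) msg <- c(msg, "jitterSigma must be >= 0")
  if (object@boxZ <= 0) msg <- c(msg, "boxZ must be positive")
  if (object@frameIntervalNs <= 0 || object@tTotalNs <= 0)
    msg <- c(msg, "time parameters must be positive")
  sc <- object@siteCenters[c("Scav", "S4", "S3", "S2", "S1")]
  if (any(diff(sc) <= 0))
    msg <- c(msg, "site centers must be strictly ordered along z")
  if (length(msg)) msg else TRUE
})

#' Generator ground truth
#'
#' Exact log of a kinetic Monte Carlo run: true per-frame site occupancies
#' and state strings, per-frame Ca-binding flags, the permeation event log
#' at frame resolution, and the exact continuous-time transit counts.
#'
#' @slot states character per-frame 4-letter state strings.
#' @slot siteOccupants matrix frames x sites (S1..S4, Scav) of species
#'   labels or `"EMPTY"`.
#' @slot caF87,caE92 logical per-frame flags.
#' @slot events data.frame (particle, species, direction, entry_frame,
#'   exit_frame): complete transits resolvable at the sampling interval.
#' @slot nOutward,nInward integer counts consistent with `events`.
#' @slot nOutwardExact,nInwardExact integer exact continuous-time transit
#'   counts (include transits faster than one frame interval).
#' @slot params the [KineticModelParams-class] echo.
#' @slot seed integer seed used.
#' @export
setClass("SyntheticGroundTruth", representation(
  states = "character",
  siteOccupants = "matrix",
  caF87 = "logical",
  caE92 = "logical",
  events = "data.frame",
  nOutward = "integer",
  nInward = "integer",
  nOutwardExact = "integer",
  nInwardExact = "integer",
  params = "KineticModelParams",
  seed = "integer"
))

#' Stationary occupancy solution
#'
#' Exact stationary distribution of the kinetic hopping model, obtained by
#' enumerating the exclusion state space and solving the global balance
#' equations. Serves as the independent oracle for occupancy-recovery
#' tests.
#'
#' @slot siteProbs matrix sites x species of occupation probabilities.
#' @slot stateProbs named numeric stationary probability of each 4-letter
#'   SF state string.
#' @slot condStateProbs list with elements `ca_bound` and `ca_free`:
#'   state-string distributions conditional on F87 Ca occupancy.
#' @slot caF87Prob,caE92Prob numeric stationary Ca-binding probabilities.
#' @slot nStates integer size of the enumerated state space.
#' @export
setClass("StationaryOccupancy", representation(
  siteProbs = "matrix",
  stateProbs = "numeric",
  condStateProbs = "list",
  caF87Prob = "numeric",
  caE92Prob = "numeric",
  nStates = "integer"
))

#' Pipeline run report
#'
#' Machine-readable results of an end-to-end run: occupancy tables per
#' voltage and Ca condition, the I-V table with rectification ratios,
#' density profiles, gate summaries, and provenance.
#'
#' @slot occupancy list, per voltage label: list(ca_bound=, ca_free=) of
#'   [OccupancyTable-class] objects.
#' @slot iv data.frame I-V table.
#' @slot rectification data.frame of |I(-V)|/|I(+V)| ratios.
#' @slot profiles list of [DensityProfile-class] per voltage.
#' @slot gate list of gate-distance summaries per voltage.
#' @slot provenance list: config hash, package version, seed.
#' @export
setClass("RunReport", representation(
  occupancy = "list",
  iv = "data.frame",
  rectification = "data.frame",
  profiles = "list",
  gate = "list",
  provenance = "list"
))
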