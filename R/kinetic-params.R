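#' @include AllClasses.R
NULL

# kB * 310 K / e, in mV
.KT_MV_310 <- 1.380649e-23 * 310 / 1.602176634e-19 * 1e3

# Ladder site indices used by the generator
.KM_SITES <- c(POOL_IN = 1L, E92 = 2L, F87 = 3L, Scav = 4L, S4 = 5L,
               S3 = 6L, S2 = 7L, S1 = 8L, POOL_OUT = 9L)

#' Kinetic hopping-model parameters
#'
#' Constructor for [KineticModelParams-class], the configuration of the
#' continuous-time Markov generator of synthetic ion-channel trajectories.
#'
#' The model is a single-file hopping ladder. Permeant cations (K+, NH4+)
#' hop bulk_in - Scav - S4 - S3 - S2 - S1 - bulk_out under at-most-one-ion-
#' per-site exclusion, with an additional slow bulk_in - bulk_out exchange
#' representing diffusion around the periodic boundary. Ca2+ binds two
#' sites below the filter: the F87 site (on-rate multiplied by the voltage
#' factor `exp(q V delta_Ca / 2kT)`, q = 2) and the E92 glutamate ring
#' (voltage-independent). While a Ca2+ ion is seated at F87 the
#' bulk_in - Scav passage is closed in both directions (check-valve
#' block), and the F87-bound Ca2+ interacts repulsively with permeant
#' ions in the pore (`caCoupling`, kT per site), which also feeds back
#' into the Ca2+ on/off rates, so inward-moving ions destabilise the
#' seated ball.
#'
#' Hop rates follow a symmetric Arrhenius split of the configuration
#' energy: `k = nu * exp(-dU/2) * exp(+- q V delta / 2kT)`, where `U` sums
#' the per-site free energies of occupied sites, a nearest-neighbour pair
#' penalty inside the SF, and the Ca-ion interaction. The fractional
#' electrical distance per permeant hop is uniform (`deltaPerHop`, default
#' 1/6 over the six hops spanning the membrane); `kT` corresponds to 310 K.
#'
#' Default site energies and rates are calibrated (via the exact
#' stationary solver [stationaryOccupancy()]) so that the model reproduces
#' the qualitative occupancy phenomenology of voltage-biased channel
#' simulations: KOKO dominant at negative/zero voltage, KKOK gaining under
#' positive voltage and when Ca2+ is bound below the filter, very little
#' F87 Ca2+ binding under negative voltage, and a Ca2+ block of outward
#' but not inward current.
#'
#' @param voltage applied voltage, mV.
#' @param nK,nNH4,nCA,nCL,nWAT particle counts.
#' @param energies named numeric site free energies (kT) for permeant ions
#'   at Scav, S4, S3, S2, S1 (pools are the zero reference).
#' @param prefactors named numeric attempt rates (1/ns): `entry`
#'   (pool-Scav and S1-pool hops), `sf` (intra-filter hops), `bulk`
#'   (pool-pool exchange).
#' @param pairRepulsion nearest-neighbour penalty for adjacent occupied SF
#'   sites, kT.
#' @param caCoupling named numeric interaction (kT) between F87-bound Ca2+
#'   and a permeant ion at Scav, S4, S3, S2, S1.
#' @param caRates named numeric: `f87_on`, `f87_off`, `e92_on`, `e92_off`
#'   (1/ns, per ion).
#' @param deltaPerHop fractional electrical distance of each of the four
#'   intra-filter hops; the two boundary hops split the remaining
#'   `(1 - 4 * deltaPerHop) / 2` each, so the total drop is always 1. The
#'   default 1/6 distributes the drop uniformly over all six hops.
#' @param deltaCa fractional electrical distance for Ca2+ binding at F87.
#' @param caOffVoltageDependent apply the inverse voltage factor to the F87
#'   off-rate.
#' @param blockRule enable the F87 check-valve block.
#' @param jitterSigma isotropic Gaussian coordinate jitter, Angstrom.
#' @param gateWidth F97 C-alpha square side, Angstrom.
#' @param boxZ box length along z, Angstrom.
#' @param frameIntervalNs trajectory sampling interval, ns.
#' @param tTotalNs simulated time, ns.
#' @param waterSfRate attempt rate for transient water visits to S1/S4
#'   (1/ns; 0 disables).
#' @param kT_mV thermal energy in mV (default: 310 K).
#' @return a [KineticModelParams-class]
#' @export
kineticParams <- function(voltage = 0,
                          nK = 4L, nNH4 = 0L, nCA = 2L, nCL = 2L,
                          nWAT = 4L,
                          energies = c(Scav = -1.0, S4 = -1.0, S3 = -3.2,
                                       S2 = -1.5, S1 = -3.2),
                          prefactors = c(entry = 0.5, sf = 2.0, bulk = 1.0),
                          pairRepulsion = 2.0,
                          caCoupling = c(Scav = 3.0, S4 = -1.2, S3 = 1.2,
                                         S2 = -0.8, S1 = 0.0),
                          caRates = c(f87_on = 0.04, f87_off = 0.02,
                                      e92_on = 0.05, e92_off = 0.02),
                          deltaPerHop = 1 / 6,
                          deltaCa = 0.5,
                          caOffVoltageDependent = FALSE,
                          blockRule = TRUE,
                          jitterSigma = 0.3,
                          gateWidth = 18,
                          boxZ = 60,
                          frameIntervalNs = 0.2,
                          tTotalNs = 1000,
                          waterSfRate = 0,
                          kT_mV = .KT_MV_310) {
  centers <- c(POOL_IN = -25, E92 = -16.5, F87 = -11.5, Scav = -7.25,
               S4 = -1.25, S3 = 1.55, S2 = 4.65, S1 = 7.75, POOL_OUT = 23)
  new("KineticModelParams",
      voltage = voltage,
      nIons = c(K = as.integer(nK), NH4 = as.integer(nNH4),
                CA = as.integer(nCA), CL = as.integer(nCL),
                WAT = as.integer(nWAT)),
      siteCenters = centers,
      energies = energies[c("Scav", "S4", "S3", "S2", "S1")],
      prefactors = prefactors[c("entry", "sf", "bulk")],
      pairRepulsion = pairRepulsion,
      caCoupling = caCoupling[c("Scav", "S4", "S3", "S2", "S1")],
      caRates = caRates[c("f87_on", "f87_off", "e92_on", "e92_off")],
      deltaPerHop = deltaPerHop,
      deltaCa = deltaCa,
      caOffVoltageDependent = caOffVoltageDependent,
      blockRule = blockRule,
      kT_mV = kT_mV,
      jitterSigma = jitterSigma,
      gateWidth = gateWidth,
      boxZ = boxZ,
      frameIntervalNs = frameIntervalNs,
      tTotalNs = tTotalNs,
      waterSfRate = waterSfRate)
}

# Configuration energy terms shared by the simulator and used in the rate
# law. occ: integer vector indexed by site (2..8), 0 = empty, else species
# code (1 K, 2 NH4, 4 WAT). caAtF87: logical.
.configEnergy <- function(params, occ, caAtF87) {
  permeant <- occ[4:8] == 1L | occ[4:8] == 2L  # Scav,S4,S3,S2,S1
  u <- sum(params@energies[permeant])
  sf <- occ[5:8] == 1L | occ[5:8] == 2L        # S4,S3,S2,S1
  u <- u + params@pairRepulsion * sum(sf[-1] & sf[-4])
  if (caAtF87) u <- u + sum(params@caCoupling[permeant])
  u
}

# Interaction energy between an F87-bound Ca and the current permeant
# configuration (used for Ca on/off rates).
.caInteraction <- function(params, occ) {
  permeant <- occ[4:8] == 1L | occ[4:8] == 2L
  sum(params@caCoupling[permeant])
}
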