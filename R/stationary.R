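#' @include AllClasses.R kinetic-params.R
NULL

#' Exact stationary occupancy of the kinetic hopping model
#'
#' Enumerates the full exclusion state space of the model behind
#' [simulateTrajectory()] (species-resolved occupancy of Scav, S4, S3, S2,
#' S1, the pool splits of every mobile species, and the Ca2+ occupancy of
#' E92 and F87), builds the continuous-time Markov generator from the same
#' rate law, and solves the global balance equations for the stationary
#' distribution. This is an independent oracle for the trajectory
#' simulator: state enumeration and balance solving share no code with the
#' sampling loop.
#'
#' @param params a [KineticModelParams-class]
#' @param maxStates enumeration cap; exceeding it is an error.
#' @return a [StationaryOccupancy-class]
#' @export
stationaryOccupancy <- function(params, maxStates = 20000L) {
  stopifnot(is(params, "KineticModelParams"))
  n <- params@nIons
  useWat <- params@waterSfRate > 0 && n[["WAT"]] > 0L
  siteSpecies <- c(0L, if (n[["K"]] > 0L) 1L, if (n[["NH4"]] > 0L) 2L,
                   if (useWat) 4L)

  # --- enumerate states -----------------------------------------------------
  # a state: occ[5] species codes for (Scav,S4,S3,S2,S1), pool-in counts of
  # K/NH4/WAT (pool-out implied), e92/f87 Ca flags
  grid <- expand.grid(rep(list(siteSpecies), 5L))
  states <- list()
  for (g in seq_len(nrow(grid))) {
    occ <- as.integer(grid[g, ])
    if (useWat && any(occ[c(1, 3, 4)] == 4L)) next  # water only at S4/S1
    nK <- sum(occ == 1L); nN <- sum(occ == 2L); nW <- sum(occ == 4L)
    if (nK > n[["K"]] || nN > n[["NH4"]] || nW > n[["WAT"]]) next
    for (kIn in 0:(n[["K"]] - nK))
      for (nIn in 0:(n[["NH4"]] - nN))
        for (wIn in if (useWat) 0:(n[["WAT"]] - nW) else n[["WAT"]] - nW)
          for (e92 in 0:min(1L, n[["CA"]]))
            for (f87 in 0:min(1L, n[["CA"]] - e92)) {
              states[[length(states) + 1L]] <-
                c(occ, kIn, nIn, wIn, e92, f87)
            }
  }
  S <- do.call(rbind, states)
  nS <- nrow(S)
  if (nS > maxStates)
    stop("state space too large to enumerate (", nS, " states)")
  key <- apply(S, 1, paste, collapse = ",")

  # --- transition rates (same rate law, independent enumeration) -----------
  V <- params@voltage
  kT <- params@kT_mV
  nu <- params@prefactors
  vK <- exp(V * params@deltaPerHop / (2 * kT))
  vB <- exp(V * (1 - 4 * params@deltaPerHop) / 2 / (2 * kT))
  vCa <- exp(2 * V * params@deltaCa / (2 * kT))
  caR <- params@caRates
  occFull <- function(st) {
    o <- integer(9)
    o[4:8] <- st[1:5]
    o[2] <- if (st[9] == 1L) 3L else 0L
    o[3] <- if (st[10] == 1L) 3L else 0L
    o
  }
  U <- function(st) .configEnergy(params, occFull(st), st[10] == 1L)

  Q <- matrix(0, nS, nS)
  addRate <- function(i, st2, rate) {
    j <- match(paste(st2, collapse = ","), key)
    if (is.na(j)) stop("internal: transition to unenumerated state")
    Q[i, j] <<- Q[i, j] + rate
  }
  # ladder positions within st[1:5]: 1 Scav, 2 S4, 3 S3, 4 S2, 5 S1
  for (i in seq_len(nS)) {
    st <- S[i, ]
    u0 <- U(st)
    blocked <- params@blockRule && st[10] == 1L
    for (spc in c(1L, 2L)) {                 # K, NH4
      nTot <- n[[if (spc == 1L) "K" else "NH4"]]
      if (nTot == 0L) next
      poolIn <- st[5L + spc]
      poolOut <- nTot - sum(st[1:5] == spc) - poolIn
      # pool exchange
      if (poolIn > 0L) {
        st2 <- st; st2[5L + spc] <- st2[5L + spc] - 1L
        addRate(i, st2, poolIn * nu[["bulk"]])
      }
      if (poolOut > 0L) {
        st2 <- st; st2[5L + spc] <- st2[5L + spc] + 1L
        addRate(i, st2, poolOut * nu[["bulk"]])
      }
      # entry pool_in -> Scav
      if (poolIn > 0L && st[1] == 0L && !blocked) {
        st2 <- st; st2[1] <- spc; st2[5L + spc] <- st2[5L + spc] - 1L
        addRate(i, st2, poolIn * nu[["entry"]] * exp(-(U(st2) - u0) / 2) * vB)
      }
      # Scav -> pool_in
      if (st[1] == spc && !blocked) {
        st2 <- st; st2[1] <- 0L; st2[5L + spc] <- st2[5L + spc] + 1L
        addRate(i, st2, nu[["entry"]] * exp(-(U(st2) - u0) / 2) / vB)
      }
      # entry pool_out -> S1
      if (poolOut > 0L && st[5] == 0L) {
        st2 <- st; st2[5] <- spc
        addRate(i, st2, poolOut * nu[["entry"]] * exp(-(U(st2) - u0) / 2) / vB)
      }
      # S1 -> pool_out
      if (st[5] == spc) {
        st2 <- st; st2[5] <- 0L
        addRate(i, st2, nu[["entry"]] * exp(-(U(st2) - u0) / 2) * vB)
      }
      # intra-ladder hops Scav..S1
      for (a in 1:4) {
        if (st[a] == spc && st[a + 1L] == 0L) {
          st2 <- st; st2[a] <- 0L; st2[a + 1L] <- spc
          addRate(i, st2, nu[["sf"]] * exp(-(U(st2) - u0) / 2) * vK)
        }
        if (st[a + 1L] == spc && st[a] == 0L) {
          st2 <- st; st2[a + 1L] <- 0L; st2[a] <- spc
          addRate(i, st2, nu[["sf"]] * exp(-(U(st2) - u0) / 2) / vK)
        }
      }
    }
    # water visits to S4 (from pool_in) and S1 (from pool_out)
    if (useWat) {
      wr <- params@waterSfRate
      wIn <- st[8]
      wOut <- n[["WAT"]] - sum(st[1:5] == 4L) - wIn
      if (wIn > 0L) { st2 <- st; st2[8] <- st2[8] - 1L
        addRate(i, st2, wIn * nu[["bulk"]]) }
      if (wOut > 0L) { st2 <- st; st2[8] <- st2[8] + 1L
        addRate(i, st2, wOut * nu[["bulk"]]) }
      if (wIn > 0L && st[2] == 0L) {
        st2 <- st; st2[2] <- 4L; st2[8] <- st2[8] - 1L
        addRate(i, st2, wIn * wr)
      }
      if (st[2] == 4L) { st2 <- st; st2[2] <- 0L; st2[8] <- st2[8] + 1L
        addRate(i, st2, wr) }
      if (wOut > 0L && st[5] == 0L) { st2 <- st; st2[5] <- 4L
        addRate(i, st2, wOut * wr) }
      if (st[5] == 4L) { st2 <- st; st2[5] <- 0L
        addRate(i, st2, wr) }
    }
    # Ca moves
    if (n[["CA"]] > 0L) {
      caPool <- n[["CA"]] - st[9] - st[10]
      if (caPool > 0L && st[9] == 0L) {
        st2 <- st; st2[9] <- 1L
        addRate(i, st2, caPool * caR[["e92_on"]])
      }
      if (st[9] == 1L) { st2 <- st; st2[9] <- 0L
        addRate(i, st2, caR[["e92_off"]]) }
      if (caPool > 0L && st[10] == 0L) {
        st2 <- st; st2[10] <- 1L
        R <- .caInteraction(params, occFull(st))
        addRate(i, st2, caPool * caR[["f87_on"]] * vCa * exp(-R / 2))
      }
      if (st[10] == 1L) {
        st2 <- st; st2[10] <- 0L
        R <- .caInteraction(params, occFull(st))
        off <- caR[["f87_off"]] * exp(R / 2)
        if (params@caOffVoltageDependent) off <- off / vCa
        addRate(i, st2, off)
      }
    }
  }

  diag(Q) <- -rowSums(Q)
  A <- t(Q)
  A[nS, ] <- 1
  b <- c(rep(0, nS - 1L), 1)
  pi <- solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  pi <- pi / sum(pi)

  # --- marginals ------------------------------------------------------------
  siteNames <- c("S1", "S2", "S3", "S4", "Scav")
  stCols <- c(5L, 4L, 3L, 2L, 1L)  # state columns in S1..Scav order
  spLab <- c("K", "NH4", "WAT")
  spCode <- c(1L, 2L, 4L)
  siteProbs <- matrix(0, 5, 3, dimnames = list(siteNames, spLab))
  for (s in 1:5)
    for (j in 1:3)
      siteProbs[s, j] <- sum(pi[S[, stCols[s]] == spCode[j]])
  letters <- c("O", "K", "N", "X", "W")
  codeOf <- apply(S[, stCols[1:4], drop = FALSE], 1, function(v)
    paste(letters[v + 1L], collapse = ""))
  stateProbs <- tapply(pi, codeOf, sum)
  bound <- S[, 10] == 1L
  cond <- function(sel) {
    if (!any(sel) || sum(pi[sel]) == 0) return(numeric())
    p <- tapply(pi[sel], codeOf[sel], sum)
    stats::setNames(as.numeric(p) / sum(p), names(p))
  }
  new("StationaryOccupancy",
      siteProbs = siteProbs,
      stateProbs = stats::setNames(as.numeric(stateProbs),
                                   names(stateProbs)),
      condStateProbs = list(ca_bound = cond(bound), ca_free = cond(!bound)),
      caF87Prob = sum(pi[bound]), caE92Prob = sum(pi[S[, 9] == 1L]),
      nStates = nS)
}
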