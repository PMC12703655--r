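#' @include AllClasses.R
NULL

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP")

.SF_RESID <- c("THR", "VAL", "GLY", "TYR", "GLY")
.SF_ONE <- c("T", "V", "G", "Y", "G")
.SITES <- c("S1", "S2", "S3", "S4", "Scav")

#' Default pore configuration
#'
#' Residue numbering, species map and cutoffs for the MthK pore domain:
#' SF sequence TVGYG at residues 59-63, auxiliary residues F87 (Ca2+ site
#' below the cavity), E92/E96 (glutamate rings) and F97 (lower gate).
#' Any field can be overridden through the `config` argument of
#' [loadPoreSpec()].
#'
#' @return a named list.
#' @export
defaultPoreConfig <- function() {
  list(
    sf_resnos = 59:63,
    aux_resnos = c(F87 = 87, E92 = 92, E96 = 96, F97 = 97),
    species_map = c(K = "K", POT = "K", NH4 = "NH4", AMM = "NH4",
                    CA = "CA", CAL = "CA", CL = "CL", CLA = "CL",
                    HOH = "WAT", SOL = "WAT", TIP3 = "WAT", WAT = "WAT"),
    cutoffs = c(sf_radial = 3.5, scav_radial = 3.5, f87_radial = 5.0,
                e92_contact = 4.5)
  )
}

#' Load and validate a pore specification
#'
#' Parses a channel topology (PDB), locates the selectivity-filter oxygen
#' rings and the auxiliary residues in every chain, and classifies the
#' non-protein particles by species. Residue numbers, species names and
#' cutoffs come from `config` (a list or a YAML file path); omitted keys
#' fall back to [defaultPoreConfig()]. Unknown particle residue names map
#' to species `"other"`.
#'
#' A missing SF residue is a hard error naming the residue and chain; a
#' non-tetrameric channel (3 chains) gives a warning and proceeds.
#'
#' @param topology path to a PDB file, or a bio3d `pdb` object.
#' @param config list or YAML path overriding [defaultPoreConfig()] keys.
#' @return a [PoreSpec-class]
#' @export
loadPoreSpec <- function(topology, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- defaultPoreConfig()
  for (k in names(def)) {
    if (is.null(config[[k]])) {
      config[[k]] <- def[[k]]
    } else if (k %in% c("species_map", "cutoffs", "aux_resnos")) {
      v <- unlist(config[[k]])
      miss <- setdiff(names(def[[k]]), names(v))
      config[[k]] <- c(v, def[[k]][miss])
    }
  }
  pdb <- if (is.character(topology)) readTopology(topology) else topology
  atoms <- pdb$atom
  sfRes <- as.integer(unlist(config$sf_resnos))
  if (length(sfRes) != 5L) stop("sf_resnos must list exactly 5 residues")
  aux <- config$aux_resnos
  sfLabels <- paste0(.SF_ONE, sfRes)

  isSF <- atoms$resno %in% sfRes & atoms$resid %in% .SF_RESID
  chains <- sort(unique(atoms$chain[isSF]))
  if (length(chains) < 3L)
    stop("fewer than 3 chains carry the selectivity filter")
  if (length(chains) != 4L)
    warning("expected a tetrameric channel; found ", length(chains),
            " chains, proceeding")

  findAtoms <- function(resno, elety, resid = NULL) {
    idx <- integer(length(chains))
    for (i in seq_along(chains)) {
      sel <- which(atoms$chain == chains[i] & atoms$resno == resno &
                     atoms$elety %in% elety &
                     (is.null(resid) | atoms$resid %in% resid))
      idx[i] <- if (length(sel)) sel[1] else NA_integer_
    }
    idx
  }
  requireRing <- function(idx, label) {
    if (anyNA(idx))
      stop("SF residue ", label, " missing in chain ",
           paste(chains[is.na(idx)], collapse = ", "))
    idx
  }

  rings <- list(
    t59_o   = requireRing(findAtoms(sfRes[1], "O"), sfLabels[1]),
    t59_og1 = requireRing(findAtoms(sfRes[1], c("OG1", "OG")), sfLabels[1]),
    v60_o   = requireRing(findAtoms(sfRes[2], "O"), sfLabels[2]),
    g61_o   = requireRing(findAtoms(sfRes[3], "O"), sfLabels[3]),
    y62_o   = requireRing(findAtoms(sfRes[4], "O"), sfLabels[4]),
    g63_o   = requireRing(findAtoms(sfRes[5], "O"), sfLabels[5])
  )

  ringAtoms <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "CEN")
  f87 <- lapply(chains, function(ch) {
    which(atoms$chain == ch & atoms$resno == aux[["F87"]] &
            atoms$elety %in% ringAtoms)
  })
  names(f87) <- chains
  if (sum(lengths(f87) > 0) < 3L)
    stop("F87 ring atoms found in fewer than 3 chains")
  rings$f87_ring <- f87

  rings$e92_o <- which(atoms$resno == aux[["E92"]] &
                         atoms$elety %in% c("OE1", "OE2"))
  if (!length(rings$e92_o))
    warning("no E92 carboxylate oxygens found; E92 Ca flag disabled")
  rings$f97_ca <- findAtoms(aux[["F97"]], "CA")

  map <- config$species_map
  species <- rep(NA_character_, nrow(atoms))
  known <- atoms$resid %in% names(map)
  species[known] <- map[atoms$resid[known]]
  isProtein <- atoms$resid %in% .AA3
  species[!known & !isProtein] <- "other"
  # one representative point per particle: water -> oxygen, ammonium -> N
  drop <- (species %in% "WAT" & !atoms$elety %in% c("O", "OW", "OH2")) |
    (species %in% "NH4" & atoms$elety != "N")
  species[drop] <- NA_character_
  pidx <- which(!is.na(species))
  part <- data.frame(atom = pidx, species = species[pidx],
                     id = seq_along(pidx))

  atoms$species <- species
  new("PoreSpec", atoms = atoms, chains = chains, rings = rings,
      sfLabels = sfLabels, particles = part,
      cutoffs = config$cutoffs, speciesMap = map)
}

# Lean geometry core shared by frameGeometry() and the batched pipeline.
# coords: n_atoms x 3 matrix for one frame. Returns a plain list.
.geomCore <- function(coords, spec) {
  r <- spec@rings
  carbonyl <- c(r$t59_o, r$v60_o, r$g61_o, r$y62_o, r$g63_o)
  P <- coords[carbonyl, , drop = FALSE]
  if (anyNA(P)) {
    bad <- is.na(coords[carbonyl, 1])
    if (sum(!bad) < 3L * 5L) stop("fewer than 3 chains contribute to a ring")
    P <- P[!bad, , drop = FALSE]
  }
  ctr <- colMeans(P)
  ax <- eigen(crossprod(sweep(P, 2, ctr)), symmetric = TRUE)$vectors[, 1]
  origin <- colMeans(coords[r$t59_o, , drop = FALSE])
  # sign: Y62 ring extracellular of T59 ring
  if (sum((colMeans(coords[r$y62_o, , drop = FALSE]) - origin) * ax) < 0)
    ax <- -ax
  proj <- function(idx) {
    mean((coords[idx, , drop = FALSE] %*% ax)) - sum(origin * ax)
  }
  f87pts <- t(vapply(spec@rings$f87_ring[lengths(spec@rings$f87_ring) > 0],
                     function(i) colMeans(coords[i, , drop = FALSE]),
                     numeric(3)))
  planes <- c(G63 = proj(r$g63_o), Y62 = proj(r$y62_o), G61 = proj(r$g61_o),
              V60 = proj(r$v60_o), T59O = proj(r$t59_o),
              T59OG1 = proj(r$t59_og1),
              F87 = mean(f87pts %*% ax) - sum(origin * ax))
  if (is.unsorted(rev(planes)))
    warning("site planes out of order along the pore axis: ",
            paste(sprintf("%s=%.2f", names(planes), planes), collapse = " "))
  si <- matrix(c(planes["G61"], planes["Y62"],
                 planes["V60"], planes["G61"],
                 planes["T59O"], planes["V60"],
                 planes["T59OG1"], planes["T59O"],
                 planes["F87"], planes["T59OG1"]),
               ncol = 2, byrow = TRUE,
               dimnames = list(.SITES, c("lo", "hi")))
  list(origin = origin, axis = ax, planes = planes, siteIntervals = si)
}

#' Per-frame pore geometry
#'
#' Computes the instantaneous pore axis (principal axis of the SF backbone
#' carbonyl-oxygen set, signed so Y62 lies extracellular of T59), the T59
#' carbonyl-oxygen reference origin, the axial ring planes, and the site
#' intervals: S1 = \[G61-O, Y62-O\], S2 = \[V60-O, G61-O\],
#' S3 = \[T59-O, V60-O\], S4 = \[T59-OG1, T59-O\] and
#' Scav = \[F87 plane, T59-OG1\], all relative to the T59-O centroid.
#' Geometry is recomputed independently on every frame (no smoothing);
#' a violation of the extracellular-to-intracellular plane ordering is
#' reported as a warning, never silently reordered.
#'
#' @param coords n_atoms x 3 coordinate matrix for one frame, ordered as in
#'   the topology behind `spec`.
#' @param spec a [PoreSpec-class]
#' @return a [FrameGeometry-class]
#' @export
frameGeometry <- function(coords, spec) {
  g <- .geomCore(coords, spec)
  new("FrameGeometry", axisOrigin = as.numeric(g$origin),
      axisDirection = as.numeric(g$axis), planes = g$planes,
      siteIntervals = g$siteIntervals, cutoffs = spec@cutoffs)
}

# Axial (relative to T59-O) and radial coordinates of selected atoms.
.axialRadial <- function(coords, geom, idx) {
  v <- sweep(coords[idx, , drop = FALSE], 2, geom$origin)
  z <- drop(v %*% geom$axis)
  r2 <- rowSums(v^2) - z^2
  list(z = z, r = sqrt(pmax(r2, 0)))
}
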