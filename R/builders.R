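# molecule construction and solution assembly
#
# length mapping: one lattice unit = 0.3 nm (PEG segment length 0.71 nm
# mapped to ~2.37 lattice units, rounded convention 1 u = 3 Angstrom)

.NM_PER_LATTICE <- 0.3

#' Map physical lengths to lattice units and back
#'
#' One lattice unit corresponds to 0.3 nm (3 Angstrom), fixed by mapping the
#' PEG statistical segment length of 7.1 Angstrom onto the lattice model.
#'
#' @param valueNm length in nm (>= 0).
#' @return \code{mapLength}: length in lattice units (numeric; round at call
#'   sites where an integer site count is required).
#' @examples
#' mapLength(0.3)        # 1
#' latticeToNm(256)      # 76.8 nm box edge
#' @export
mapLength <- function(valueNm) {
  if (any(valueNm < 0)) stop("lengths must be non-negative")
  valueNm / .NM_PER_LATTICE
}

#' @rdname mapLength
#' @param valueLattice length in lattice units (>= 0).
#' @return \code{latticeToNm}: length in nm.
#' @export
latticeToNm <- function(valueLattice) {
  if (any(valueLattice < 0)) stop("lengths must be non-negative")
  valueLattice * .NM_PER_LATTICE
}

# run expr with a private RNG stream, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# self-avoidance test in an unbounded hash of occupied sites
.siteKeys <- function(p) {
  off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  s <- cbind(p[1] + off[, 1], p[2] + off[, 2], p[3] + off[, 3])
  paste(s[, 1], s[, 2], s[, 3])
}

#' Build a starPEG molecule template
#'
#' A tetra-functional star: one central monomer plus four arms of 29
#' statistical monomers each (117 monomers total; the centre is counted in
#' addition to the arms). The four arm termini are the reactive thiol ends.
#' The initial conformation is a self-avoiding walk grown arm by arm with
#' allowed bond vectors.
#'
#' @param seed integer seed for the conformation.
#' @param armLength monomers per arm (default 29).
#' @return a [MoleculeTemplate-class] whose \code{positions} are relative
#'   corner coordinates (centre at the origin).
#' @export
buildStarPEG <- function(seed = 1L, armLength = 29L) {
  .withSeed(seed, {
    bv <- allowedBondSet()
    for (attempt in 1:200) {
      occ <- new.env(hash = TRUE, parent = emptyenv())
      mark <- function(p) for (k in .siteKeys(p)) assign(k, TRUE, envir = occ)
      free <- function(p) !any(vapply(.siteKeys(p), exists, TRUE, envir = occ))
      pos <- matrix(0L, 1 + 4L * armLength, 3)
      bonds_i <- integer(); bonds_j <- integer()
      mark(c(0L, 0L, 0L))
      idx <- 1L
      ok <- TRUE
      for (arm in 1:4) {
        prev <- 1L
        for (m in seq_len(armLength)) {
          placed <- FALSE
          for (v in sample(nrow(bv))) {
            cand <- pos[prev, ] + bv[v, ]
            if (free(cand)) {
              idx <- idx + 1L
              pos[idx, ] <- cand
              mark(cand)
              bonds_i <- c(bonds_i, prev); bonds_j <- c(bonds_j, idx)
              prev <- idx
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        termini <- 1L + armLength * (1:4)
        return(new("MoleculeTemplate", species = "PEG", positions = pos,
                   bonds = data.frame(i = bonds_i, j = bonds_j),
                   reactiveIndices = termini, rigidity = "flexible",
                   molarMass = 10000))
      }
    }
    stop("starPEG conformation growth failed after bounded retries")
  })
}

#' Build a heparin molecule template
#'
#' Heparin is a bulky, rod-like multifunctional crosslinker of 90 monomer
#' cubes: 26 axial slices at spacing 2 (12 slices of 4 monomers in a 2x2
#' cross-section, 14 slices of 3), connected by axial and lateral
#' minimum-length bonds. The dense packing makes the object effectively
#' rigid under single-monomer moves, and the mapped long-axis extent is
#' 52 sites = 15.6 nm, matching the ~15.5 nm end-to-end distance reported
#' for heparin of this molar mass. 28 distinct monomers (the average number
#' of carboxylic acid groups) are sampled uniformly as reactive sites.
#'
#' @param seed integer seed for the reactive-site sampling.
#' @param nReactive number of reactive sites (default 28).
#' @return a [MoleculeTemplate-class] with relative corner coordinates.
#' @export
buildHeparin <- function(seed = 1L, nReactive = 28L) {
  lateral <- list(c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  nSlices <- 26L
  counts <- ifelse(seq_len(nSlices) <= 12L, 4L, 3L)
  pos <- NULL
  slice <- integer(); lat <- integer()
  for (s in seq_len(nSlices)) {
    for (l in seq_len(counts[s])) {
      pos <- rbind(pos, c(2L * (s - 1L), lateral[[l]][1], lateral[[l]][2]))
      slice <- c(slice, s); lat <- c(lat, l)
    }
  }
  storage.mode(pos) <- "integer"
  n <- nrow(pos)
  bonds_i <- integer(); bonds_j <- integer()
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      d <- abs(pos[a, ] - pos[b, ])
      if (sum(d) == 2 && max(d) == 2) {   # one axis apart by 2: (2,0,0) class
        bonds_i <- c(bonds_i, a); bonds_j <- c(bonds_j, b)
      }
    }
  }
  stopifnot(n == 90L)
  if (nReactive > n) stop("cannot place more reactive sites than monomers")
  reactive <- .withSeed(seed, sort(sample(n, nReactive)))
  new("MoleculeTemplate", species = "HEP", positions = pos,
      bonds = data.frame(i = bonds_i, j = bonds_j),
      reactiveIndices = as.integer(reactive), rigidity = "rod",
      molarMass = 14000)
}

#' Molecule count from molar concentration and box size
#'
#' @param cMilliMolar concentration in mM.
#' @param boxEdgeLattice box edge in lattice units.
#' @return integer molecule count \code{round(c * N_A * V)}.
#' @examples
#' molarToCount(1.5, 256)  # 409 heparins in the reference box
#' @export
molarToCount <- function(cMilliMolar, boxEdgeLattice) {
  if (cMilliMolar <= 0 || boxEdgeLattice <= 0) stop("inputs must be positive")
  volLitre <- (latticeToNm(boxEdgeLattice))^3 * 1e-24
  count <- round(cMilliMolar * 1e-3 * 6.02214076e23 * volLitre)
  if (count < 1)
    stop("box too small for the requested concentration (count < 1)")
  as.integer(count)
}

# site linear indices (1-based) of a monomer cube at corner p, wrapped
.cubeSites <- function(p, L) {
  off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  x <- (p[1] + off[, 1]) %% L
  y <- (p[2] + off[, 2]) %% L
  z <- (p[3] + off[, 3]) %% L
  1L + x + L * (y + L * z)
}

# place a rigid template at a random position/orientation; returns coords or NULL
.placeRigid <- function(tpl, occ, L, maxTries = 5000L) {
  n <- nrow(tpl@positions)
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1),
                c(1, 3, 2), c(2, 3, 1), c(3, 1, 2))
  for (t in seq_len(maxTries)) {
    pr <- perms[[sample(6L, 1L)]]
    coords <- tpl@positions[, pr, drop = FALSE]
    shift <- sample(0:(L - 1L), 3L, replace = TRUE)
    coords <- sweep(coords, 2, shift, "+") %% L
    sites <- integer(8L * n)
    for (m in seq_len(n)) sites[(8 * m - 7):(8 * m)] <- .cubeSites(coords[m, ], L)
    if (!anyDuplicated(sites) && all(occ[sites] == 0L))
      return(list(coords = coords, sites = sites))
  }
  NULL
}

# grow one starPEG in the box as a SAW avoiding occupied sites
.growStar <- function(armLength, occ, L, bv, maxMolTries = 60L) {
  for (t in seq_len(maxMolTries)) {
    centre <- sample(0:(L - 1L), 3L, replace = TRUE)
    cs <- .cubeSites(centre, L)
    if (any(occ[cs] != 0L)) next
    nTot <- 1L + 4L * armLength
    coords <- matrix(0L, nTot, 3)
    coords[1, ] <- centre
    placedSites <- list(cs)
    occ[cs] <- 1L
    bonds_i <- integer(); bonds_j <- integer()
    idx <- 1L
    ok <- TRUE
    for (arm in 1:4) {
      prev <- 1L
      for (m in seq_len(armLength)) {
        placed <- FALSE
        for (v in sample(nrow(bv))) {
          cand <- (coords[prev, ] + bv[v, ]) %% L
          s <- .cubeSites(cand, L)
          if (all(occ[s] == 0L)) {
            idx <- idx + 1L
            coords[idx, ] <- cand
            occ[s] <- 1L
            placedSites[[idx]] <- s
            bonds_i <- c(bonds_i, prev); bonds_j <- c(bonds_j, idx)
            prev <- idx
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok)
      return(list(coords = coords,
                  bonds = data.frame(i = bonds_i, j = bonds_j),
                  occ = occ))
    # undo partial growth
    for (s in placedSites) occ[s] <- 0L
  }
  NULL
}

#' Assemble an equilibrated precursor solution
#'
#' Places \code{nHEP = molarToCount(cHep, boxEdge)} heparin rods and
#' \code{nPEG = round(gamma * nHEP)} starPEG stars at random non-overlapping
#' positions in a periodic box and equilibrates the athermal (good-solvent)
#' system by Monte Carlo.
#'
#' @param gamma molar ratio nPEG/nHEP (>= 0).
#' @param cHep heparin concentration in mM (default 1.5, the experimental
#'   value).
#' @param boxEdge box edge in lattice units (default 128, the scaled test
#'   box; the reference system uses 256).
#' @param equilibrationMCS Monte Carlo steps of athermal equilibration.
#' @param seed integer seed.
#' @param armLength,hepReactive template parameters passed through.
#' @return an equilibrated [LatticeState-class]; attributes \code{nPEG},
#'   \code{nHEP} and \code{volumeFraction} record the composition.
#' @export
assembleSolution <- function(gamma, cHep = 1.5, boxEdge = 128L,
                             equilibrationMCS = 10000, seed = 1L,
                             armLength = 29L, hepReactive = 28L) {
  if (gamma < 0) stop("gamma must be >= 0")
  L <- as.integer(boxEdge)
  nHEP <- molarToCount(cHep, L)
  nPEG <- as.integer(round(gamma * nHEP))
  hepExtent <- 52L
  if (L < 4L * ceiling(hepExtent / 4L))  # box must comfortably hold the rod
    stop("box too small relative to the heparin rod extent")
  .assembleCounts(nPEG, nHEP, L, equilibrationMCS, seed, armLength,
                  hepReactive)
}

# count-based assembler shared with the fixture generators
.assembleCounts <- function(nPEG, nHEP, L, equilibrationMCS, seed,
                            armLength = 29L, hepReactive = 28L) {
  if (nHEP > 0 && L < 56L)
    stop("box edge must be at least 56 lattice units to hold the 52-site heparin rod without periodic self-overlap")
  frac <- 8 * (90 * nHEP + (1 + 4 * armLength) * nPEG) / as.numeric(L)^3
  if (frac >= 0.5)
    stop(sprintf("occupied volume fraction %.2f exceeds the BFM mobility bound 0.5", frac))
  bv <- allowedBondSet()
  .withSeed(seed + 1L, {
    occ <- integer(L^3)
    pos <- NULL; species <- character(); molId <- integer()
    bonds <- data.frame(i = integer(), j = integer(), kind = character())
    reactive <- logical()
    mol <- 0L
    for (h in seq_len(nHEP)) {
      tpl <- buildHeparin(seed = seed * 1000L + h, nReactive = hepReactive)
      pl <- .placeRigid(tpl, occ, L)
      if (is.null(pl)) stop("packing failure while placing heparin ", h)
      occ[pl$sites] <- 1L
      mol <- mol + 1L
      base <- if (is.null(pos)) 0L else nrow(pos)
      pos <- rbind(pos, pl$coords)
      species <- c(species, rep("HEP", nrow(pl$coords)))
      molId <- c(molId, rep(mol, nrow(pl$coords)))
      bonds <- rbind(bonds, data.frame(i = tpl@bonds$i + base,
                                       j = tpl@bonds$j + base,
                                       kind = "intra"))
      r <- logical(nrow(pl$coords)); r[tpl@reactiveIndices] <- TRUE
      reactive <- c(reactive, r)
    }
    for (p in seq_len(nPEG)) {
      gr <- .growStar(armLength, occ, L, bv)
      if (is.null(gr)) stop("packing failure while growing starPEG ", p)
      occ <- gr$occ
      mol <- mol + 1L
      base <- if (is.null(pos)) 0L else nrow(pos)
      pos <- rbind(pos, gr$coords)
      species <- c(species, rep("PEG", nrow(gr$coords)))
      molId <- c(molId, rep(mol, nrow(gr$coords)))
      bonds <- rbind(bonds, data.frame(i = gr$bonds$i + base,
                                       j = gr$bonds$j + base,
                                       kind = "intra"))
      r <- logical(nrow(gr$coords))
      r[1L + armLength * (1:4)] <- TRUE
      reactive <- c(reactive, r)
    }
    state <- latticeState(L, pos, species, molId, bonds, reactive)
    state <- runMCS(state, equilibrationMCS, energyModel(0), seed = seed + 7L)
    attr(state, "nPEG") <- nPEG
    attr(state, "nHEP") <- nHEP
    attr(state, "volumeFraction") <- frac
    state
  })
}
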