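## Deterministic toy geometries and a geometry-sensitive oracle label
## function.  These make every other module testable without external
## datasets: the oracle stands in for quantum-chemical shift labels with a
## smooth, rigid-motion-invariant function of the local environment.
##
## Fixture coordinates are idealized (exact bond lengths/angles solved in
## closed form), deliberately not force-field generated, so tests never
## depend on an embedding library's version.

.CC <- 1.526; .CH <- 1.093; .TETA <- 109.4712206

## Unit vector
.uv <- function(v) v / sqrt(sum(v^2))
.cross3 <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                            a[1]*b[2]-a[2]*b[1])

## The two remaining tetrahedral directions at an atom with bond unit
## vectors b1, b2 (angle ~109.5 between the results).
.tetraPair <- function(b1, b2) {
  s <- .uv(-(.uv(b1) + .uv(b2)))
  n <- .uv(.cross3(b1, b2))
  a <- 54.7356 * pi / 180
  list(s * cos(a) + n * sin(a), s * cos(a) - n * sin(a))
}

## Three staggered substituent directions at an atom whose single existing
## bond points along b; phi0 rotates the set about the bond axis (degrees).
.tetraTriple <- function(b, phi0 = 0) {
  b <- .uv(b)
  ref <- if (abs(b[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- .uv(.cross3(b, ref)); v <- .cross3(b, u)
  ct <- cos(.TETA * pi / 180); st <- sin(.TETA * pi / 180)
  lapply((phi0 + c(0, 120, 240)) * pi / 180,
         function(p) b * ct + (u * cos(p) + v * sin(p)) * st)
}

## Chair/boat carbon skeletons (exact closure: all C-C 1.526, angles 111).
.chairCarbons <- function() {
  a <- sqrt(2 * .CC^2 * (1 - cos(111 * pi / 180)) / 3)
  q <- sqrt(.CC^2 - a^2) / 2
  ang <- (0:5) * pi / 3
  cbind(a * cos(ang), a * sin(ang), q * c(1, -1, 1, -1, 1, -1))
}

.boatCarbons <- function() {
  L2 <- .CC^2; b <- .CC / 2
  dy <- -L2 * cos(111 * pi / 180) / (2 * b)
  a <- sqrt(L2 * (1 - cos(111 * pi / 180)) / 2)
  z <- sqrt(L2 - a^2 - dy^2)
  rbind(c(0,  b + dy, z),   # C1 (prow)
        c(a,  b, 0), c(a, -b, 0),
        c(0, -b - dy, z),   # C4 (stern)
        c(-a, -b, 0), c(-a, b, 0))
}

## Add two H to every ring carbon; returns list(coords, hParent, axialRow)
## where axialRow[k] is the row of the H on carbon k pointing away from the
## local ring plane ("axial" in the chair).
.ringWithH <- function(ringC) {
  n <- nrow(ringC)
  coords <- ringC
  hParent <- integer(); axial <- integer(n)
  for (k in seq_len(n)) {
    prev <- ringC[(k - 2) %% n + 1L, ]; nxt <- ringC[k %% n + 1L, ]
    pr <- .tetraPair(prev - ringC[k, ], nxt - ringC[k, ])
    ## the member with the larger |z-component| is the axial-like one
    ax <- which.max(c(abs(pr[[1]][3]), abs(pr[[2]][3])))
    for (m in seq_along(pr)) {
      coords <- rbind(coords, ringC[k, ] + pr[[m]] * .CH)
      hParent <- c(hParent, k)
      if (m == ax) axial[k] <- nrow(coords)
    }
  }
  list(coords = coords, hParent = hParent, axialRow = axial)
}

.ringBonds <- function(n = 6L) cbind(seq_len(n), c(2:n, 1L), 1L)

.methaneFixture <- function() {
  dirs <- rbind(c(1,1,1), c(1,-1,-1), c(-1,1,-1), c(-1,-1,1)) / sqrt(3)
  coords <- rbind(c(0, 0, 0), dirs * 1.093)
  mol <- Molecule("methane", c("C", rep("H", 4)),
                  bonds = cbind(1L, 2:5, 1L))
  list(molecule = mol,
       conformers = list(Conformer("methane", coords, 0, "user")))
}

## Place atom D bonded to C with bond length r, angle theta at C (degrees,
## to B) and torsion phi (degrees, about B->C relative to A).
.nerf <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- .uv(C - B)
  n <- .uv(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  C + r * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

.butaneFixture <- function() {
  ## backbone: C-C 1.526, C-C-C angle 112, torsion 180 (anti) / 65 (gauche)
  ang <- 112 * pi / 180
  bb <- function(torsion) {
    X <- matrix(0, 4, 3)
    X[1, ] <- c(0, 0, 0); X[2, ] <- c(.CC, 0, 0)
    X[3, ] <- X[2, ] + .CC * c(cos(pi - ang), sin(pi - ang), 0)
    X[4, ] <- .nerf(X[1, ], X[2, ], X[3, ], .CC, 112, torsion)
    X
  }
  addH <- function(X) {
    coords <- X; parent <- integer()
    ## methylenes C2, C3
    for (k in 2:3) {
      pr <- .tetraPair(X[k - 1, ] - X[k, ], X[k + 1, ] - X[k, ])
      for (d in pr) { coords <- rbind(coords, X[k, ] + d * .CH); parent <- c(parent, k) }
    }
    ## terminal methyls C1 (neighbor C2), C4 (neighbor C3)
    for (d in .tetraTriple(X[2, ] - X[1, ], 60)) {
      coords <- rbind(coords, X[1, ] + d * .CH); parent <- c(parent, 1L) }
    for (d in .tetraTriple(X[3, ] - X[4, ], 60)) {
      coords <- rbind(coords, X[4, ] + d * .CH); parent <- c(parent, 4L) }
    list(coords = coords, parent = parent)
  }
  anti <- addH(bb(180)); gauche <- addH(bb(65))
  bonds <- rbind(cbind(1:3, 2:4, 1L), cbind(anti$parent, 5:14, 1L))
  mol <- Molecule("butane", c(rep("C", 4), rep("H", 10)), bonds = bonds)
  list(molecule = mol,
       conformers = list(
         anti = Conformer("butane", anti$coords, 0, "user"),
         gauche = Conformer("butane", gauche$coords, NA_real_, "user")))
}

.cyclohexaneFixture <- function() {
  ch <- .ringWithH(.chairCarbons()); bo <- .ringWithH(.boatCarbons())
  bonds <- rbind(.ringBonds(), cbind(ch$hParent, 7:18, 1L))
  mol <- Molecule("cyclohexane", c(rep("C", 6), rep("H", 12)), bonds = bonds)
  list(molecule = mol,
       conformers = list(
         chair = Conformer("cyclohexane", ch$coords, 0, "user"),
         boat = Conformer("cyclohexane", bo$coords, NA_real_, "user")))
}

## 1,3-dimethylcyclohexane on the chair skeleton.  "cis" carries both
## methyls equatorial; "trans" has the C1 methyl equatorial and the C3
## methyl axial.  One canonical atom ordering serves both geometries, so
## the bond lists are identical while the 3D distance multisets differ --
## the desk-scale stand-in for a diastereomer pair.
## Atom order: 1-6 ring C; 7 methyl C on C1; 8 methyl C on C3; 9 H on C1;
## 10 H on C3; 11-18 H pairs on C2,C4,C5,C6; 19-21 H on C7; 22-24 H on C8.
.disubCyclohexaneFixture <- function() {
  build <- function(axialAt3) {
    ring <- .ringWithH(.chairCarbons())
    rc <- ring$coords[1:6, , drop = FALSE]
    hOf <- function(k) {  # the two H positions of ring carbon k (ax, eq)
      rows <- which(ring$hParent == k) + 6L
      ax <- ring$axialRow[k]
      list(ax = ring$coords[ax, ], eq = ring$coords[setdiff(rows, ax)[1], ])
    }
    sub <- function(k, axial) {  # methyl carbon + remaining H for carbon k
      h <- hOf(k)
      hPos <- if (axial) h$ax else h$eq
      dirM <- .uv(hPos - rc[k, ])
      cm <- rc[k, ] + dirM * .CC
      list(cm = cm, hKeep = if (axial) h$eq else h$ax,
           mh = do.call(rbind, lapply(.tetraTriple(-dirM, 60),
                                      function(d) cm + d * .CH)))
    }
    s1 <- sub(1L, FALSE); s3 <- sub(3L, axialAt3)
    rest <- do.call(rbind, lapply(c(2L, 4L, 5L, 6L), function(k) {
      h <- hOf(k); rbind(h$ax, h$eq)
    }))
    rbind(rc, s1$cm, s3$cm, s1$hKeep, s3$hKeep, rest, s1$mh, s3$mh)
  }
  elements <- c(rep("C", 6), "C", "C", rep("H", 16))
  bonds <- rbind(.ringBonds(),
                 c(1L, 7L, 1L), c(3L, 8L, 1L), c(1L, 9L, 1L), c(3L, 10L, 1L),
                 cbind(rep(c(2L, 4L, 5L, 6L), each = 2), 11:18, 1L),
                 cbind(7L, 19:21, 1L), cbind(8L, 22:24, 1L))
  mol <- Molecule("dm-cyclohexane", elements, bonds = bonds)
  list(molecule = mol,
       conformers = list(
         cis = Conformer("dm-cyclohexane", build(FALSE), 0, "user"),
         trans = Conformer("dm-cyclohexane", build(TRUE), NA_real_, "user")),
       methylCarbons = c(7L, 8L))
}

## Valine-like amino acid: a stereocentre bearing H, NH2, COOH and an
## isopropyl group whose two methyl carbons are diastereotopic.
.valineFixture <- function() {
  t4 <- rbind(c(1,1,1), c(1,-1,-1), c(-1,1,-1), c(-1,-1,1)) / sqrt(3)
  CA <- c(0, 0, 0)
  N  <- CA + t4[1, ] * 1.47
  HA <- CA + t4[2, ] * 1.09
  Cp <- CA + t4[3, ] * 1.52
  CB <- CA + t4[4, ] * 1.53
  ## amine hydrogens
  nh <- .tetraTriple(CA - N, 30)[1:2]
  HN1 <- N + nh[[1]] * 1.01; HN2 <- N + nh[[2]] * 1.01
  ## planar carboxyl: sp2 directions 120 deg from the Ca-C' bond
  bC <- .uv(CA - Cp)
  refn <- .uv(.cross3(bC, c(0, 0, 1)))
  rot <- function(v, axis, ang) {  # Rodrigues
    a <- ang * pi / 180
    v * cos(a) + .cross3(axis, v) * sin(a) + axis * sum(axis * v) * (1 - cos(a))
  }
  dO1 <- rot(bC, refn, 122); dO2 <- rot(bC, refn, -122)
  O1 <- Cp + dO1 * 1.21            # carbonyl O
  O2 <- Cp + dO2 * 1.36            # hydroxyl O
  HO <- O2 + .uv(rot(.uv(Cp - O2), .uv(.cross3(.uv(Cp - O2), refn)), 109)) * 0.97
  ## isopropyl: CB carries HB and two methyls at staggered positions
  dirs <- .tetraTriple(CA - CB, 15)
  CG1 <- CB + dirs[[1]] * 1.53
  CG2 <- CB + dirs[[2]] * 1.53
  HB <- CB + dirs[[3]] * 1.09
  mh <- function(cg) {
    d <- .tetraTriple(CB - cg, 60)
    rbind(cg + d[[1]] * .CH, cg + d[[2]] * .CH, cg + d[[3]] * .CH)
  }
  coords <- rbind(CA, HA, N, HN1, HN2, Cp, O1, O2, HO, CB, HB,
                  CG1, mh(CG1), CG2, mh(CG2))
  elements <- c("C", "H", "N", "H", "H", "C", "O", "O", "H", "C", "H",
                "C", "H", "H", "H", "C", "H", "H", "H")
  bonds <- rbind(
    c(1, 2, 1), c(1, 3, 1), c(1, 6, 1), c(1, 10, 1),
    c(3, 4, 1), c(3, 5, 1), c(6, 7, 2), c(6, 8, 1), c(8, 9, 1),
    c(10, 11, 1), c(10, 12, 1), c(10, 16, 1),
    c(12, 13, 1), c(12, 14, 1), c(12, 15, 1),
    c(16, 17, 1), c(16, 18, 1), c(16, 19, 1))
  mol <- Molecule("valine-like", elements, bonds = bonds,
                  stereoDefined = TRUE)
  list(molecule = mol,
       conformers = list(Conformer("valine-like", coords, 0, "user")),
       methylCarbons = c(12L, 16L))
}

#' Deterministic molecular fixtures
#'
#' Hard-wired idealized geometries used throughout the test-suite and the
#' oracle-recovery experiments.  The \code{cis_trans_disub_cyclohexane} and
#' \code{cyclohexane_chair_boat} fixtures each return two geometries sharing
#' one bond list but differing in their interatomic-distance multisets.
#'
#' @param name one of \code{"methane"}, \code{"butane_anti_gauche"},
#'   \code{"cyclohexane_chair_boat"}, \code{"cis_trans_disub_cyclohexane"},
#'   \code{"valine_like"}.
#' @return A list with elements \code{molecule} ([Molecule-class]),
#'   \code{conformers} (named list of [Conformer-class]) and, where
#'   relevant, \code{methylCarbons} (atom indices of the substituent methyl
#'   carbons).
#' @export
#' @examples
#' fx <- makeFixture("cyclohexane_chair_boat")
#' names(fx$conformers)
makeFixture <- function(name) {
  switch(name,
    methane = .methaneFixture(),
    butane_anti_gauche = .butaneFixture(),
    cyclohexane_chair_boat = .cyclohexaneFixture(),
    cis_trans_disub_cyclohexane = .disubCyclohexaneFixture(),
    valine_like = .valineFixture(),
    stop("unknown fixture: '", name, "'"))
}

#' Oracle label parameters
#'
#' The oracle shift of atom i is
#' \deqn{\delta_i = b_{Z(i)} + \sum_{j \ne i,\; d_{ij} < cutoff} c_{Z(j)}
#'   \exp(-d_{ij}/\lambda),}
#' a smooth, rigid-motion-invariant, geometry-sensitive function of the
#' atomic environment within the model cutoff.
#'
#' @param b named base shift per element (ppm); only the entries for
#'   predicted nuclei (C, H) matter.
#' @param c_coef named neighbour coefficient per element (ppm).
#' @param lambda decay length (Angstrom).
#' @param cutoff neighbour cutoff (Angstrom); keep equal to the model's.
#' @return Parameter list of class \code{"oracleParams"}.
#' @export
oracleParams <- function(b = c(C = 100, H = 5, O = 0, N = 0, F = 0,
                               Cl = 0, P = 0, S = 0),
                         c_coef = stats::setNames(rep(10, 8), names(b)),
                         lambda = 1.5, cutoff = 5.0) {
  stopifnot(lambda > 0, cutoff > 0)
  structure(list(b = b, c_coef = c_coef, lambda = lambda, cutoff = cutoff),
            class = "oracleParams")
}

#' Oracle shift labels for a conformer
#'
#' @param conf a [Conformer-class].
#' @param mol the parent [Molecule-class].
#' @param params an [oracleParams()] list.
#' @return Shift-record data.frame (columns \code{molecule_id},
#'   \code{atom} (1-based), \code{nucleus}, \code{shift},
#'   \code{provenance = "computed"}) covering every H and C atom.
#' @export
oracleShifts <- function(conf, mol, params = oracleParams()) {
  el <- atomElements(mol)
  xyz <- coords(conf)
  n <- nrow(xyz)
  dm <- if (n > 1) as.matrix(stats::dist(xyz)) else matrix(0, 1, 1)
  shifts <- vapply(seq_len(n), function(i) {
    nb <- which(dm[i, ] > 0 & dm[i, ] < params$cutoff)
    params$b[[el[i]]] +
      sum(params$c_coef[el[nb]] * exp(-dm[i, nb] / params$lambda))
  }, numeric(1))
  keep <- el %in% c("H", "C")
  data.frame(molecule_id = molId(mol),
             atom = which(keep),
             nucleus = ifelse(el[keep] == "H", "H1", "C13"),
             shift = shifts[keep],
             provenance = "computed",
             stringsAsFactors = FALSE)
}

.randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Jittered oracle-labelled conformer dataset
#'
#' Draws conformers round-robin from the fixture library, perturbs every
#' coordinate with Gaussian jitter, applies a random rigid motion, and
#' labels each geometry with [oracleShifts()].  This emulates a set of
#' related-but-distinct 3D structures with geometry-dependent labels, the
#' desk-scale analogue of a quantum-chemistry-labelled training corpus.
#'
#' @param n number of conformers to generate.
#' @param seed RNG seed (the dataset is fully determined by it).
#' @param jitterSd coordinate jitter standard deviation (Angstrom).
#' @param params an [oracleParams()] list.
#' @param fixtures fixture names to draw from.
#' @return List of entries \code{list(molecule, conformer, shifts)}.
#' @export
makeOracleDataset <- function(n = 200L, seed = 1L, jitterSd = 0.05,
                              params = oracleParams(),
                              fixtures = c("methane", "butane_anti_gauche",
                                           "cyclohexane_chair_boat",
                                           "cis_trans_disub_cyclohexane",
                                           "valine_like")) {
  fx <- lapply(fixtures, makeFixture)
  pool <- list()
  for (f in fx)
    for (cf in f$conformers)
      pool[[length(pool) + 1L]] <- list(molecule = f$molecule, conformer = cf)
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    p <- pool[[(k - 1L) %% length(pool) + 1L]]
    xyz <- coords(p$conformer)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitterSd), nrow(xyz), 3)
    xyz <- xyz %*% .randomRotation() + matrix(stats::runif(3, -5, 5),
                                              nrow(xyz), 3, byrow = TRUE)
    cf <- Conformer(molId(p$molecule), xyz, NA_real_, "user")
    out[[k]] <- list(molecule = p$molecule, conformer = cf,
                     shifts = oracleShifts(cf, p$molecule, params))
  }
  out
}

#' Build labelled graphs from an oracle dataset
#'
#' @param dataset output of [makeOracleDataset()] (or any list of
#'   molecule/conformer/shifts entries).
#' @param nucleus \code{"C13"} or \code{"H1"}.
#' @param rbf an [rbfParams()] list.
#' @return List of [labeledGraph()] entries for [trainModel()].
#' @export
labeledSetFromOracle <- function(dataset, nucleus = "C13",
                                 rbf = rbfParams()) {
  lapply(dataset, function(e) {
    g <- buildGraph(e$conformer, e$molecule, rbf, nucleus)
    labeledGraph(g, e$shifts[e$shifts$nucleus == nucleus, ])
  })
}

#' Contaminated paired computed/experimental shift records
#'
#' Differences (computed - experimental) are Normal(0, sigma) except for a
#' seeded random subset displaced by +/- \code{outlier_mag}; the planted
#' indices are recorded so outlier-removal procedures can be scored.
#'
#' @param n number of pairs.
#' @param sigma noise s.d. of the inlier differences (ppm).
#' @param outlier_frac fraction of planted outliers, in [0, 0.5).
#' @param outlier_mag displacement magnitude of outliers (ppm).
#' @param seed RNG seed.
#' @param nucleus nucleus tag for the records.
#' @return List with data.frames \code{computed} and \code{experimental}
#'   (matched row-for-row) and integer vector \code{outlierIdx}.
#' @export
makeContaminatedPairs <- function(n, sigma = 2, outlier_frac = 0.05,
                                  outlier_mag = 15, seed = 1L,
                                  nucleus = "C13") {
  if (outlier_frac < 0 || outlier_frac >= 0.5)
    stop("outlier_frac must lie in [0, 0.5)")
  set.seed(seed)
  base <- stats::runif(n, 0, 200)
  diffs <- stats::rnorm(n, 0, sigma)
  nOut <- round(n * outlier_frac)
  outlierIdx <- sort(sample.int(n, nOut))
  diffs[outlierIdx] <- diffs[outlierIdx] +
    sample(c(-1, 1), nOut, replace = TRUE) * outlier_mag
  ids <- sprintf("m%05d", seq_len(n))
  experimental <- data.frame(molecule_id = ids, atom = 1L, nucleus = nucleus,
                             shift = base, provenance = "experimental",
                             stringsAsFactors = FALSE)
  computed <- experimental
  computed$shift <- base + diffs
  computed$provenance <- "computed"
  list(computed = computed, experimental = experimental,
       outlierIdx = outlierIdx)
}

#' Write fixtures and oracle labels to disk
#'
#' Emits one SDF per fixture (all geometries as successive records) plus a
#' combined oracle-label CSV consumable by [parseShiftTable()].
#'
#' @param dir output directory (created if missing).
#' @param params an [oracleParams()] list.
#' @return The directory, invisibly.
#' @export
writeFixtures <- function(dir, params = oracleParams()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- list()
  for (name in c("methane", "butane_anti_gauche", "cyclohexane_chair_boat",
                 "cis_trans_disub_cyclohexane", "valine_like")) {
    fx <- makeFixture(name)
    writeStructuresSDF(fx$molecule, fx$conformers,
                       file.path(dir, paste0(name, ".sdf")))
    ## one label block per geometry, tagged so table keys stay unique
    cfNames <- names(fx$conformers) %||% seq_along(fx$conformers)
    for (k in seq_along(fx$conformers)) {
      lab <- oracleShifts(fx$conformers[[k]], fx$molecule, params)
      if (length(fx$conformers) > 1L)
        lab$molecule_id <- paste0(lab$molecule_id, "#", cfNames[[k]])
      labels[[length(labels) + 1L]] <- lab
    }
  }
  writeShiftTable(do.call(rbind, labels), file.path(dir, "oracle_shifts.csv"))
  invisible(dir)
}
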