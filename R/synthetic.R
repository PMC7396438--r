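## Synthetic two-body complexes with ground truth: a slab-like receptor
## with a surface pocket, a block ligand filling the pocket in the native
## placement, planted cross-link anchor pairs, a blocked (membrane
## analogue) receptor layer, and decoy ensembles. Everything is a pure
## function of its seed and parameters.

LATTICE <- 3.5     # pseudo-residue lattice spacing, Angstrom
JITTER_SD <- 0.2   # per-coordinate positional noise, Angstrom

## backbone + side-chain pseudo-atoms for one residue at a lattice site;
## the footprint is mirror-symmetric in x and y so surface complementarity
## has no built-in directional bias
pseudoResidueAtoms <- function(chain, resno, resid, site, extra = NULL) {
  atoms <- data.frame(
    chain = chain, resno = resno, insert = "", resid = resid,
    elety = c("N", "CA", "C", "CB", "CG"),
    x = site[1L] + c(-1.4, 0, 1.4, 0, 0),
    y = site[2L] + c(0, 0, 0, 1.4, -1.4),
    z = site[3L] + c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    atoms <- rbind(atoms, data.frame(
      chain = chain, resno = resno, insert = "", resid = resid,
      elety = extra$elety,
      x = site[1L] + extra$offset[1L],
      y = site[2L] + extra$offset[2L],
      z = site[3L] + extra$offset[3L],
      stringsAsFactors = FALSE))
  }
  atoms
}

.buildBlockComplex <- function(seed, n_receptor, n_ligand, interface_size) {
  d <- LATTICE
  nz <- 5L       # slab layers; the bottom one is the blocked region
  pdepth <- 2L   # pocket depth in layers
  p <- max(2L, as.integer(round(sqrt(interface_size))))
  pw <- p + 1L   # carved pocket width: one lattice unit of clearance so
                 # the ligand block fits without grid-level core clashes
  ## slab wide enough for the pocket plus one wall on every side
  m <- ceiling((n_receptor + pdepth * pw^2) / nz)
  nx <- max(ceiling(sqrt(m)), pw + 2L)
  ny <- max(ceiling(m / nx), pw + 2L)
  while (nx * ny * nz - pdepth * pw^2 < n_receptor) nx <- nx + 1L
  ox <- floor((nx - pw) / 2)
  oy <- floor((ny - pw) / 2)

  sites <- expand.grid(ix = 0:(nx - 1L), iy = 0:(ny - 1L), iz = 0:(nz - 1L))
  sites <- sites[order(sites$iz, sites$iy, sites$ix), ]
  inPocket <- sites$iz >= nz - pdepth &
    sites$ix >= ox & sites$ix < ox + pw &
    sites$iy >= oy & sites$iy < oy + pw
  sites <- sites[!inPocket, , drop = FALSE]

  ## trim the slab down to n_receptor residues with priority retention:
  ## the pocket wall ring, the floor under the pocket and the blocked
  ## column beneath it are structural and kept first; the remainder fills
  ## in by proximity to the pocket
  pc <- c((ox + (pw - 1) / 2) * d, (oy + (pw - 1) / 2) * d, (nz - 1) * d)
  inPocketXY <- sites$ix >= ox & sites$ix < ox + pw &
    sites$iy >= oy & sites$iy < oy + pw
  ringXY <- sites$ix >= ox - 1L & sites$ix <= ox + pw &
    sites$iy >= oy - 1L & sites$iy <= oy + pw & !inPocketXY
  essential <- (ringXY & sites$iz >= nz - pdepth) |            # pocket walls
    (inPocketXY & sites$iz == nz - pdepth - 1L) |              # pocket floor
    (inPocketXY & sites$iz == 0L)                              # blocked column
  if (sum(essential) > n_receptor)
    stop("synthetic generation error: n_receptor = ", n_receptor,
         " is below the ", sum(essential),
         " residues the pocket geometry requires")
  distPocket <- sqrt((sites$ix * d - pc[1L])^2 + (sites$iy * d - pc[2L])^2 +
                     (sites$iz * d - pc[3L])^2)
  keep <- order(!essential, distPocket)[seq_len(n_receptor)]
  sites <- sites[sort(keep), , drop = FALSE]

  ## chain B = bottom (blocked, membrane-embedded analogue) layer
  sites$chain <- ifelse(sites$iz == 0L, "B", "A")
  sites$resno <- stats::ave(seq_len(nrow(sites)), sites$chain,
                            FUN = seq_along)

  ## planted anchors on the pocket walls (top layer, chain A)
  wallCys <- c(ox - 1L, oy, nz - 1L)
  wallLys <- c(ox + pw, oy + pw - 1L, nz - 1L)
  siteRow <- function(w) which(sites$ix == w[1L] & sites$iy == w[2L] &
                               sites$iz == w[3L])
  iCys <- siteRow(wallCys)
  iLys <- siteRow(wallLys)
  if (length(iCys) != 1L || length(iLys) != 1L)
    stop("synthetic generation error: pocket wall anchor sites were trimmed")

  recAtoms <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    resid <- "ALA"; extra <- NULL
    if (i == iCys) {
      resid <- "CYS"; extra <- list(elety = "SG", offset = c(0, 0, 1.2))
    } else if (i == iLys) {
      resid <- "LYS"; extra <- list(elety = "NZ", offset = c(0, 0, 1.2))
    }
    pseudoResidueAtoms(s$chain, s$resno, resid,
                       c(s$ix, s$iy, s$iz) * d, extra)
  }))

  ## ligand: p x p footprint centred in the carved pocket (0.5 lattice
  ## units of clearance each side) for the in-pocket layers, then a
  ## stepped pyramid above -- no large flat outer face, so the pocket is
  ## the unique high-complementarity placement. Residues beyond the
  ## pyramid capacity continue as a single-site column at the apex.
  layerSize <- function(k) {
    if (k < pdepth) p else max(1L, p - (k - pdepth + 1L))
  }
  lig <- NULL
  k <- 0L
  while (is.null(lig) || nrow(lig) < n_ligand) {
    s <- layerSize(k)
    off <- (p - s) / 2
    lay <- expand.grid(layer_x = off + 0:(s - 1L), layer_y = off + 0:(s - 1L))
    lay <- lay[order(lay$layer_y, lay$layer_x), , drop = FALSE]
    lay$layer <- k
    lig <- rbind(lig, lay)
    k <- k + 1L
  }
  lig <- lig[seq_len(n_ligand), , drop = FALSE]
  lig$ix <- ox + 0.5 + lig$layer_x
  lig$iy <- oy + 0.5 + lig$layer_y
  ## the small downward shift seats the block so its bottom face already
  ## touches the pocket floor contact band in the native pose
  lig$iz <- (nz - pdepth) + lig$layer - 0.6 / d
  lig$resno <- seq_len(n_ligand)

  ligLysA <- which(lig$layer_x == 0L & lig$layer_y == 0L &
                   lig$layer == pdepth - 1L)   # partner of Cys wall
  ligLysB <- which(lig$layer_x == p - 1L & lig$layer_y == p - 1L &
                   lig$layer == pdepth - 1L)   # partner of Lys wall
  if (length(ligLysA) != 1L || length(ligLysB) != 1L)
    stop("synthetic generation error: ligand anchor sites not available")

  ligAtoms <- do.call(rbind, lapply(seq_len(nrow(lig)), function(i) {
    s <- lig[i, ]
    resid <- "ALA"; extra <- NULL
    if (i %in% c(ligLysA, ligLysB)) {
      resid <- "LYS"; extra <- list(elety = "NZ", offset = c(0, 0, 1.2))
    }
    pseudoResidueAtoms("S", s$resno, resid, c(s$ix, s$iy, s$iz) * d, extra)
  }))

  ## deterministic positional jitter
  withr::with_seed(as.integer(seed), {
    recAtoms$x <- recAtoms$x + stats::rnorm(nrow(recAtoms), 0, JITTER_SD)
    recAtoms$y <- recAtoms$y + stats::rnorm(nrow(recAtoms), 0, JITTER_SD)
    recAtoms$z <- recAtoms$z + stats::rnorm(nrow(recAtoms), 0, JITTER_SD)
    ligAtoms$x <- ligAtoms$x + stats::rnorm(nrow(ligAtoms), 0, JITTER_SD)
    ligAtoms$y <- ligAtoms$y + stats::rnorm(nrow(ligAtoms), 0, JITTER_SD)
    ligAtoms$z <- ligAtoms$z + stats::rnorm(nrow(ligAtoms), 0, JITTER_SD)
  })

  receptor <- Structure(recAtoms, id = "synthetic_receptor")
  ligand <- Structure(ligAtoms, id = "synthetic_ligand")

  cysKey <- resKey("A", sites$resno[iCys])
  lysKey <- resKey("A", sites$resno[iLys])
  links <- data.frame(
    kind = c("amine_sulfhydryl", "amine_amine", "amine_amine", "photo_pBpa"),
    receptor_chain = "A",
    receptor_res = c(sites$resno[iCys], sites$resno[iLys],
                     sites$resno[iLys], sites$resno[iLys]),
    ligand_chain = c("S", "S", "*", "S"),
    ligand_res = c(as.character(ligLysA), as.character(ligLysB), "*",
                   as.character(ligLysB)),
    max_dist = c(6.8, 12, 12, 10),
    label = c("SPDP_6.8", "DSP_12", "DSP_12_anyLys", "pBpa_site"),
    stringsAsFactors = FALSE)

  inPocketLayer <- lig$layer < pdepth
  bottom <- lig$layer == 0L
  distal <- lig$layer >= pdepth + 1L
  new("SyntheticSystem",
      receptor = receptor, ligand = ligand,
      nativePose = identityPose(),
      restraints = RestraintSet(links),
      blockedResidues = resKey("B", sites$resno[sites$chain == "B"]),
      ligandDomain = resKey("S", lig$resno[inPocketLayer]),
      orientationSets = list(proximal = resKey("S", lig$resno[bottom]),
                             distal = resKey("S", lig$resno[distal])),
      seed = as.integer(seed),
      metadata = list(lattice = d, pocket_side = p, pocket_origin = c(ox, oy),
                      layers = nz, anchors = list(
                        receptor_cys = cysKey, receptor_lys = lysKey,
                        ligand_lys = resKey("S", c(ligLysA, ligLysB)))))
}

.systemInvariantsOK <- function(sys) {
  rep <- evaluateRestraints(sys@restraints, sys@receptor, sys@ligand)
  if (!all(rep$distance <= rep$max_dist - 0.5)) return(FALSE)
  ligXYZ <- as.matrix(heavyAtoms(sys@ligand)[, c("x", "y", "z")])
  recA <- heavyAtoms(sys@receptor)
  blk <- recA[atomResKeys(recA) %in% sys@blockedResidues, , drop = FALSE]
  if (nrow(blk) > 0) {
    dmin <- sqrt(min(crossDist2(as.matrix(blk[, c("x", "y", "z")]), ligXYZ)))
    if (dmin < 8) return(FALSE)
  }
  ## distal (away-facing) ligand residues must stay out of the native
  ## interface so orientation criteria have ground truth
  if (length(sys@orientationSets$distal) > 0) {
    im <- interfaceResidues(sys@receptor, sys@ligand, cutoff = 5)
    if (any(sys@orientationSets$distal %in% im@ligandResidues)) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic receptor-ligand complex with ground truth
#'
#' Builds two interdigitated pseudo-protein bodies: a four-layer receptor
#' slab whose top face carries a pocket, and a block ligand whose bottom
#' layer fills the pocket in the native placement. The bottom receptor
#' layer (chain B) is the blocked, membrane-embedded analogue; pocket-wall
#' residues carry planted lysine/cysteine anchors paired with ligand
#' lysines across the interface, within the 6.8 A and 12 A spacer-arm
#' reach. The native pose is the identity transform and satisfies every
#' planted restraint by construction.
#'
#' @param seed integer; the generator is deterministic given the seed.
#' @param n_receptor,n_ligand residue counts (both >= 5).
#' @param interface_size requested interface residue count; realised as a
#'   \code{p x p} pocket footprint with \code{p = max(2, round(sqrt(.)))}.
#' @return A \linkS4class{SyntheticSystem}.
#' @export
makeBlockComplex <- function(seed, n_receptor = 120L, n_ligand = 23L,
                             interface_size = 9L) {
  stopifnot(n_receptor >= 5L, n_ligand >= 5L,
            interface_size < min(n_receptor, n_ligand))
  for (attempt in 0:9) {
    sys <- .buildBlockComplex(seed + attempt * 1000003L, n_receptor,
                              n_ligand, interface_size)
    sys@seed <- as.integer(seed)
    if (.systemInvariantsOK(sys)) return(sys)
  }
  stop("synthetic generation error: no feasible geometry after 10 attempts")
}

#' Generate decoy poses around the native placement
#'
#' Rigid perturbations of the native pose: rotation by a normally
#' distributed angle about a uniform random axis, translation with
#' isotropic Gaussian components. With both sigmas zero all decoys equal
#' the native pose. Deterministic given the seed.
#'
#' @param sys \linkS4class{SyntheticSystem}.
#' @param n number of decoys (>= 1).
#' @param rot_sigma rotation angle standard deviation, degrees.
#' @param trans_sigma per-axis translation standard deviation, Angstrom.
#' @param seed integer seed.
#' @return A \linkS4class{PoseSet} of n decoys.
#' @export
makeDecoys <- function(sys, n, rot_sigma = 10, trans_sigma = 5, seed = 1L) {
  stopifnot(n >= 1L, rot_sigma >= 0, trans_sigma >= 0)
  q <- matrix(0, n, 4L)
  tr <- matrix(0, n, 3L)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n)) {
      axis <- stats::rnorm(3L)
      while (vnorm(axis) < 1e-8) axis <- stats::rnorm(3L)
      ang <- stats::rnorm(1L, 0, max(rot_sigma, 0))
      q[i, ] <- axisAngleToQuat(axis, if (rot_sigma > 0) ang else 0)
      tr[i, ] <- stats::rnorm(3L, 0, trans_sigma)
    }
  })
  PoseSet(q, tr, score = rep(0, n), id = seq_len(n))
}

#' Ideal alpha-helical backbone
#'
#' Builds an N-CA-C backbone with phi = -57, psi = -47 and omega = 180
#' degrees for all interior residues, using standard bond lengths and
#' angles -- the canonical fixture for dihedral-angle code.
#'
#' @param n residue count (>= 4).
#' @return A \linkS4class{Structure} (chain A, residues ALA 1..n).
#' @export
makeHelixBackbone <- function(n) {
  stopifnot(n >= 4L)
  phi <- -57; psi <- -47; omega <- 180
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7
  xyz <- matrix(NA_real_, nrow = 3L * n, ncol = 3L)
  xyz[1L, ] <- c(0, 0, 0)                                   # N1
  xyz[2L, ] <- c(bNCA, 0, 0)                                # CA1
  xyz[3L, ] <- xyz[2L, ] + bCAC *
    c(-cos(deg2rad(aNCAC)), sin(deg2rad(aNCAC)), 0)         # C1
  for (i in seq_len(n - 1L)) {
    b <- 3L * (i - 1L)
    Ni <- xyz[b + 1L, ]; CAi <- xyz[b + 2L, ]; Ci <- xyz[b + 3L, ]
    Nn <- placeAtom(Ni, CAi, Ci, bCN, aCACN, psi)
    CAn <- placeAtom(CAi, Ci, Nn, bNCA, aCNCA, omega)
    Cn <- placeAtom(Ci, Nn, CAn, bCAC, aNCAC, phi)
    xyz[b + 4L, ] <- Nn; xyz[b + 5L, ] <- CAn; xyz[b + 6L, ] <- Cn
  }
  atoms <- data.frame(
    chain = "A", resno = rep(seq_len(n), each = 3L), insert = "",
    resid = "ALA", elety = rep(c("N", "CA", "C"), n),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE)
  Structure(atoms, id = sprintf("ideal_helix_%d", n))
}

#' Build FilterCriteria from a synthetic system's ground truth
#'
#' The planted receptor anchors become required interface residues, the
#' ligand docking domain and orientation sets are taken from the
#' generator, and the blocked receptor layer is carried over -- the
#' synthetic analogue of criteria derived from photo-cross-linking data.
#'
#' @param sys \linkS4class{SyntheticSystem}.
#' @param minDomainFraction see \code{\link{FilterCriteria}}.
#' @export
syntheticCriteria <- function(sys, minDomainFraction = 0.5) {
  anch <- sys@metadata$anchors
  FilterCriteria(
    requiredReceptorInterface = c(anch$receptor_cys, anch$receptor_lys),
    requiredLigandDomain = sys@ligandDomain,
    minDomainFraction = minDomainFraction,
    orientationRequired = sys@orientationSets$proximal,
    orientationRequiredMin = 1L,
    orientationForbidden = sys@orientationSets$distal,
    orientationForbiddenMax = 0L,
    blocked = sys@blockedResidues)
}

#' Write a synthetic system to disk
#'
#' Writes receptor.pdb, ligand.pdb, restraints.tsv, criteria.yaml and a
#' manifest.json recording the seed, so a simulation is reproducible from
#' its output directory alone.
#'
#' @param sys \linkS4class{SyntheticSystem}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSyntheticSystem <- function(sys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePDB(sys@receptor, file.path(dir, "receptor.pdb"))
  writePDB(sys@ligand, file.path(dir, "ligand.pdb"))
  writeRestraints(sys@restraints, file.path(dir, "restraints.tsv"))
  writeCriteria(syntheticCriteria(sys), file.path(dir, "criteria.yaml"))
  jsonlite::write_json(
    list(generator = "makeBlockComplex", seed = sys@seed,
         n_receptor = nResidues(sys@receptor),
         n_ligand = nResidues(sys@ligand),
         pocket_side = sys@metadata$pocket_side,
         lattice = sys@metadata$lattice),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
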