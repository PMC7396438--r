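## Rigid-body docking: occupancy-grid discretisation, FFT cross-correlation
## of shape-complementarity weights, and exhaustive translational search per
## sampled rotation.

#' RotationSet: sampled rigid rotations for docking
#'
#' @slot q n x 4 matrix of unit quaternions.
#' @slot scheme sampling scheme label.
#' @slot seed integer seed.
#' @export
setClass("RotationSet",
         representation(q = "matrix", scheme = "character",
                        seed = "integer"),
         validity = function(object) {
           if (ncol(object@q) != 4L) return("q must have 4 columns")
           if (nrow(object@q) > 0 &&
               any(abs(sqrt(rowSums(object@q^2)) - 1) > 1e-9))
             return("rotations must be unit quaternions")
           TRUE
         })

#' @export
setMethod("length", "RotationSet", function(x) nrow(x@q))

setMethod("show", "RotationSet", function(object) {
  cat("RotationSet:", nrow(object@q), "rotations, scheme",
      object@scheme, "seed", object@seed, "\n")
})

#' Sample a rotation set
#'
#' The default scheme keeps the identity rotation as the first element
#' (so a sampled set always contains the input orientation) and fills the
#' rest with seeded uniform random unit quaternions; deterministic for
#' (scheme, seed, n).
#'
#' @param n number of rotations (>= 1).
#' @param seed integer seed.
#' @param scheme \code{"random+identity"} (default) or \code{"random"}.
#' @return A \linkS4class{RotationSet}.
#' @export
rotationSet <- function(n, seed = 1L, scheme = "random+identity") {
  stopifnot(n >= 1L)
  q <- switch(scheme,
    "random+identity" = {
      if (n == 1L) matrix(c(1, 0, 0, 0), 1L)
      else rbind(c(1, 0, 0, 0), randomQuaternions(n - 1L, seed))
    },
    "random" = randomQuaternions(n, seed),
    stop("unknown rotation sampling scheme: ", scheme))
  colnames(q) <- c("qw", "qx", "qy", "qz")
  new("RotationSet", q = q, scheme = scheme, seed = as.integer(seed))
}

## occupancy grid from heavy-atom coordinates; a cell is occupied when its
## centre lies within `radius` of an atom centre (the cell containing the
## centre is always occupied)
gridFromCoords <- function(xyz, spacing, radius, margin, cap) {
  stopifnot(spacing > 0)
  lo <- apply(xyz, 2L, min) - margin
  hi <- apply(xyz, 2L, max) + margin
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)), 1L)
  if (prod(as.numeric(dims)) > as.numeric(cap)^3)
    stop("grid of ", paste(dims, collapse = "x"),
         " cells exceeds the configured cap of ", cap, "^3")
  cells <- array(0L, dim = dims)
  k <- as.integer(ceiling(radius / spacing)) + 1L
  for (i in seq_len(nrow(xyz))) {
    ctr <- (xyz[i, ] - lo) / spacing + 0.5   # fractional cell index of atom
    i0 <- pmax(as.integer(floor(ctr - k)), 1L)
    i1 <- pmin(as.integer(ceiling(ctr + k)), dims)
    ix <- i0[1L]:i1[1L]; iy <- i0[2L]:i1[2L]; iz <- i0[3L]:i1[3L]
    dx2 <- ((ix - ctr[1L]) * spacing)^2
    dy2 <- ((iy - ctr[2L]) * spacing)^2
    dz2 <- ((iz - ctr[3L]) * spacing)^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    cells[ix, iy, iz][within] <- 1L
    ## containing cell is occupied even when spacing exceeds the radius
    cc <- pmin(pmax(as.integer(floor((xyz[i, ] - lo) / spacing)) + 1L, 1L), dims)
    cells[cc[1L], cc[2L], cc[3L]] <- 1L
  }
  list(origin = lo, spacing = spacing, dims = dims, cells = cells)
}

## label occupied cells: surface (>=1 empty 6-neighbour, boundary counts
## empty) vs core
labelSurfaceCore <- function(cells) {
  d <- dim(cells)
  occ <- cells > 0L
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- occ
  nb <- function(dx, dy, dz)
    pad[(2:(d[1L] + 1L)) + dx, (2:(d[2L] + 1L)) + dy, (2:(d[3L] + 1L)) + dz]
  allNeighbors <- nb(1,0,0) & nb(-1,0,0) & nb(0,1,0) & nb(0,-1,0) &
    nb(0,0,1) & nb(0,0,-1)
  out <- array(0L, d)
  out[occ & allNeighbors] <- 2L
  out[occ & !allNeighbors] <- 1L
  out
}

#' Discretise a structure onto an occupancy grid
#'
#' Heavy atoms are rasterised onto a cubic grid; occupied cells with at
#' least one empty 6-neighbour are labelled surface, the rest core. Atoms
#' of blocked residues are removed before rasterisation, so cells owed
#' solely to blocked residues contribute neither contact nor clash --
#' this is how a membrane-embedded receptor region is excluded from the
#' docking search surface.
#'
#' @param s \linkS4class{Structure} (non-empty).
#' @param spacing cell edge, Angstrom (default 1.2).
#' @param blocked character residue keys ("chain:resno") to exclude.
#' @param radius atom rasterisation radius, Angstrom (default 1.8).
#' @param margin empty border around the structure (default radius +
#'   spacing).
#' @param cap maximum grid dimension (error above \code{cap^3} cells).
#' @return A \linkS4class{DockGrid}.
#' @export
discretizeStructure <- function(s, spacing = 1.2, blocked = character(),
                                radius = 1.8, margin = NULL, cap = 128L) {
  a <- heavyAtoms(s)
  if (nrow(a) == 0) stop("structure has no heavy atoms")
  if (is.null(margin)) margin <- radius + spacing
  all_xyz <- as.matrix(a[, c("x", "y", "z")])
  keep <- !(atomResKeys(a) %in% blocked)
  g <- gridFromCoords(all_xyz, spacing, radius, margin, cap)
  if (!all(keep)) {
    ## rebuild occupancy from unblocked atoms on the same grid frame, so
    ## the grid extent stays that of the full structure
    g$cells[] <- 0L
    if (any(keep))
      g$cells <- rasterizeInto(g, all_xyz[keep, , drop = FALSE], radius)
  }
  new("DockGrid", origin = g$origin, spacing = g$spacing,
      dims = as.integer(g$dims), cells = labelSurfaceCore(g$cells))
}

## rasterise coordinates into an existing grid frame
rasterizeInto <- function(g, xyz, radius) {
  cells <- array(0L, dim = g$dims)
  dims <- g$dims; lo <- g$origin; spacing <- g$spacing
  k <- as.integer(ceiling(radius / spacing)) + 1L
  for (i in seq_len(nrow(xyz))) {
    ctr <- (xyz[i, ] - lo) / spacing + 0.5
    i0 <- pmax(as.integer(floor(ctr - k)), 1L)
    i1 <- pmin(as.integer(ceiling(ctr + k)), dims)
    ix <- i0[1L]:i1[1L]; iy <- i0[2L]:i1[2L]; iz <- i0[3L]:i1[3L]
    dx2 <- ((ix - ctr[1L]) * spacing)^2
    dy2 <- ((iy - ctr[2L]) * spacing)^2
    dz2 <- ((iz - ctr[3L]) * spacing)^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    cells[ix, iy, iz][within] <- 1L
    cc <- pmin(pmax(as.integer(floor((xyz[i, ] - lo) / spacing)) + 1L, 1L), dims)
    cells[cc[1L], cc[2L], cc[3L]] <- 1L
  }
  cells
}

## shape-complementarity weights: surface contact +1, core clash -C
gridWeights <- function(grid, clash) {
  w <- array(0, dim = grid@dims)
  w[grid@cells == 1L] <- 1
  w[grid@cells == 2L] <- -clash
  w
}

#' Correlate two occupancy grids over all integer translations
#'
#' For every integer cell shift \code{t} of the ligand grid relative to
#' the receptor grid, the score is the sum over overlapping cells of
#' +1 for (receptor surface, ligand occupied), -C for (receptor core,
#' ligand occupied), 0 otherwise. Computed by 3D FFT cross-correlation;
#' equal to the direct double-loop sum to within 1e-6.
#'
#' @param receptor,ligand \linkS4class{DockGrid}s with equal spacing.
#' @param clash core clash penalty C (default 9).
#' @return 3D numeric score array of size \code{dim(receptor) +
#'   dim(ligand) - 1}; element \code{[i,j,k]} is the score at shift
#'   \code{t = c(i,j,k) - dim(ligand)}; the shift vectors per axis are in
#'   attribute \code{"shifts"}.
#' @export
correlateGrids <- function(receptor, ligand, clash = 9) {
  if (abs(receptor@spacing - ligand@spacing) > 1e-9)
    stop("incompatible grids: spacing differs")
  dr <- receptor@dims; dl <- ligand@dims
  P <- dr + dl - 1L
  shifts <- lapply(1:3, function(k) seq.int(-(dl[k] - 1L), dr[k] - 1L))
  L <- array(0, P); Rw <- array(0, P)
  Rw[seq_len(dr[1L]), seq_len(dr[2L]), seq_len(dr[3L])] <-
    gridWeights(receptor, clash)
  lw <- array(0, dl); lw[ligand@cells > 0L] <- 1
  if (sum(lw) == 0) {
    out <- array(0, P)
    attr(out, "shifts") <- shifts
    return(out)
  }
  L[seq_len(dl[1L]), seq_len(dl[2L]), seq_len(dl[3L])] <- lw
  S <- stats::fft(stats::fft(Rw) * Conj(stats::fft(L)), inverse = TRUE)
  ## scores are sums of cell weights; rounding off FFT noise keeps exact
  ## ties exact so the documented tie-breaking applies
  s <- round(Re(S) / prod(P), 9L)
  ## reorder so index i along axis k corresponds to shift i - dl[k]
  perm <- lapply(1:3, function(k) ((seq_len(P[k]) - dl[k]) %% P[k]) + 1L)
  out <- s[perm[[1L]], perm[[2L]], perm[[3L]], drop = FALSE]
  dim(out) <- P
  attr(out, "shifts") <- shifts
  out
}

#' Rigid-body docking search
#'
#' For each sampled rotation the ligand is rotated about its heavy-atom
#' centroid, discretised, and correlated against the receptor grid over
#' all translations. The global top-n (rotation, translation) pairs by
#' shape-complementarity score are returned as real-space poses, with
#' deterministic tie-breaking (score, then rotation index, then
#' lexicographic translation).
#'
#' @param receptor,ligand \linkS4class{Structure}s.
#' @param rotations \linkS4class{RotationSet} (non-empty).
#' @param spacing grid spacing, Angstrom.
#' @param blocked receptor residue keys excluded from the search surface.
#' @param top_n number of poses to keep (>= 1).
#' @param clash core clash penalty C (default 9).
#' @param radius atom rasterisation radius.
#' @return A \linkS4class{PoseSet}; empty (with a warning) when the ligand
#'   has no heavy atoms.
#' @export
dockSearch <- function(receptor, ligand, rotations, spacing = 1.2,
                       blocked = character(), top_n = 200L, clash = 9,
                       radius = 1.8) {
  stopifnot(top_n >= 1L)
  if (length(rotations) == 0L)
    stop("empty rotation set")
  ligHeavy <- heavyAtoms(ligand)
  if (nrow(ligHeavy) == 0L) {
    warning("ligand has no heavy atoms; returning an empty pose set")
    return(PoseSet(matrix(numeric(0), 0L, 4L), matrix(numeric(0), 0L, 3L),
                   numeric(0), integer(0)))
  }
  recGrid <- discretizeStructure(receptor, spacing, blocked, radius)
  ctr <- ligandCenter(ligand)
  xyz <- as.matrix(ligHeavy[, c("x", "y", "z")])
  cand <- vector("list", length(rotations))
  for (r in seq_len(length(rotations))) {
    R <- quatToMatrix(rotations@q[r, ])
    ry <- sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, ctr, "+")
    lg <- gridFromCoords(ry, spacing, radius, radius + spacing, 128L)
    ligGrid <- new("DockGrid", origin = lg$origin, spacing = lg$spacing,
                   dims = as.integer(lg$dims),
                   cells = labelSurfaceCore(lg$cells))
    sc <- correlateGrids(recGrid, ligGrid, clash)
    shifts <- attr(sc, "shifts")
    n_keep <- min(top_n, length(sc))
    thr <- sort(sc, decreasing = TRUE)[n_keep]
    idx <- which(sc >= thr, arr.ind = TRUE)
    t1 <- shifts[[1L]][idx[, 1L]]
    t2 <- shifts[[2L]][idx[, 2L]]
    t3 <- shifts[[3L]][idx[, 3L]]
    delta0 <- recGrid@origin - ligGrid@origin
    cand[[r]] <- data.frame(
      rot = r, score = sc[idx],
      tx = delta0[1L] + t1 * spacing,
      ty = delta0[2L] + t2 * spacing,
      tz = delta0[3L] + t3 * spacing)
  }
  all <- do.call(rbind, cand)
  ord <- order(-all$score, all$rot, all$tx, all$ty, all$tz)
  all <- all[ord, , drop = FALSE][seq_len(min(top_n, nrow(all))), ,
                                  drop = FALSE]
  PoseSet(rotations@q[all$rot, , drop = FALSE],
          as.matrix(all[, c("tx", "ty", "tz")]),
          score = all$score, id = seq_len(nrow(all)))
}

#' Write / read poses as TSV
#'
#' Columns: id, qw, qx, qy, qz, tx, ty, tz, score.
#'
#' @param poses \linkS4class{PoseSet}.
#' @param path file path.
#' @export
writePoses <- function(poses, path) {
  utils::write.table(as.data.frame(poses), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePoses
#' @export
readPoses <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  PoseSet(as.matrix(d[, c("qw", "qx", "qy", "qz")]),
          as.matrix(d[, c("tx", "ty", "tz")]), d$score, d$id)
}
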