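# Voxel grid: solvent / protein / buried-cavity labelling.
#
# A voxel is protein when its center lies within (vdW radius + probe radius)
# of any atom; solvent voxels are the non-protein voxels connected to the
# grid boundary; enclosed empty voxels are buried cavities and are never
# traversed by the path search.

#' Build a solvent-accessibility voxel grid around a complex
#'
#' @param complex an `xl_complex`.
#' @param spacing voxel edge length in Angstrom, in `[0.5, 2]`.
#' @param margin solvent margin around the structure, Angstrom; must be at
#'   least the crosslinker arm length so surface paths are never clipped.
#' @param probe solvent probe radius (water, 1.4 A).
#' @param vdw named vdW radius table, see [vdw_radii()].
#' @param max_voxels memory budget: error if the grid would exceed this many
#'   voxels (suggesting a coarser spacing).
#' @return An object of class `xl_grid` with fields `origin`, `spacing`,
#'   `dim`, `labels` (integer vector, 0 solvent / 1 protein / 2 cavity) and
#'   `probe`.
#' @export
build_grid <- function(complex, spacing = 1, margin = 12, probe = 1.4,
                       vdw = vdw_radii(), max_voxels = 4e7) {
  stopifnot(inherits(complex, "xl_complex"))
  if (spacing < 0.5 || spacing > 2)
    stop("spacing must be in [0.5, 2] Angstrom")
  if (margin < default_linker()$linker_arm)
    stop("margin must be at least the linker arm length (",
         default_linker()$linker_arm, " A)")
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")])
  radii <- .element_radius(complex$atoms$elesy, vdw) + probe
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dim <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  if (prod(as.numeric(dim)) > max_voxels)
    stop("grid of ", paste(dim, collapse = "x"), " voxels exceeds the ",
         "memory budget (", format(max_voxels, scientific = FALSE),
         " voxels); use a coarser spacing")
  labels <- cpp_label_grid(xyz, radii, lo, dim, spacing)
  structure(list(origin = lo, spacing = spacing, dim = dim,
                 labels = labels, probe = probe, vdw = vdw),
            class = "xl_grid")
}

#' @export
print.xl_grid <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, 3)
  cat("Voxel grid ", paste(x$dim, collapse = " x "), ", spacing ",
      x$spacing, " A\n  solvent ", tab[1], ", protein ", tab[2],
      ", buried cavity ", tab[3], " voxels\n", sep = "")
  invisible(x)
}

# linear (1-based) voxel index from 0-based ijk triple(s)
.vox_index <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  1L + ijk[, 1] + grid$dim[1] * (ijk[, 2] + grid$dim[2] * ijk[, 3])
}

# voxel centers for 1-based linear indices
.vox_center <- function(grid, idx) {
  idx0 <- idx - 1L
  k <- idx0 %/% (grid$dim[1] * grid$dim[2])
  rem <- idx0 %% (grid$dim[1] * grid$dim[2])
  j <- rem %/% grid$dim[1]
  i <- rem %% grid$dim[1]
  cbind(grid$origin[1] + i * grid$spacing,
        grid$origin[2] + j * grid$spacing,
        grid$origin[3] + k * grid$spacing)
}

# Entry voxels for an anchor atom: solvent voxels whose center lies within
# the accessibility shell radius = vdW(anchor) + probe + spacing*sqrt(3)
# of the anchor position. Returns indices + anchor-to-center offsets.
.entry_voxels <- function(grid, anchor_xyz, anchor_elesy) {
  shell <- .element_radius(anchor_elesy, grid$vdw) + grid$probe +
    grid$spacing * sqrt(3)
  lo <- pmax(floor((anchor_xyz - shell - grid$origin) / grid$spacing), 0)
  hi <- pmin(ceiling((anchor_xyz + shell - grid$origin) / grid$spacing),
             grid$dim - 1)
  if (any(hi < lo)) return(list(idx = integer(0), offset = numeric(0)))
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  idx <- .vox_index(grid, ijk)
  ctr <- .vox_center(grid, idx)
  d <- sqrt(rowSums(sweep(ctr, 2, anchor_xyz)^2))
  keep <- d <= shell & grid$labels[idx] == 0L
  list(idx = idx[keep], offset = d[keep])
}

#' Is a residue's anchor atom solvent accessible?
#'
#' A residue is accessible when at least one solvent voxel lies within the
#' accessibility shell of its anchor atom (shell radius: one voxel diagonal
#' beyond the protein surface at the anchor).
#'
#' @param grid an `xl_grid` built from the same complex.
#' @param complex the `xl_complex`.
#' @param chain,resno residue identifiers (vectorized).
#' @return logical vector.
#' @export
is_accessible <- function(grid, complex, chain, resno) {
  stopifnot(inherits(grid, "xl_grid"))
  rt <- residue_table(complex)
  idx <- .match_residues(rt, chain, resno)
  if (anyNA(idx))
    stop("residue(s) not found: ",
         paste(chain[is.na(idx)], resno[is.na(idx)], collapse = ", "))
  vapply(idx, function(i) {
    ev <- .entry_voxels(grid, c(rt$ax[i], rt$ay[i], rt$az[i]),
                        rt$aelesy[i])
    length(ev$idx) > 0
  }, logical(1))
}

#' Export the solvent voxel graph
#'
#' Nodes are solvent voxels; edges connect 26-neighbors with Euclidean
#' center-to-center weights. Intended for cross-checking the path engine
#' against an independent shortest-path implementation.
#'
#' @param grid an `xl_grid`.
#' @return list with `nodes` (data.frame `idx`, `x`, `y`, `z`) and `edges`
#'   (data.frame `from`, `to`, `weight`; each undirected edge once, indices
#'   into `nodes` rows).
#' @export
voxel_graph <- function(grid) {
  stopifnot(inherits(grid, "xl_grid"))
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  solvent <- which(grid$labels == 0L)
  node_of <- integer(nx * ny * nz)
  node_of[solvent] <- seq_along(solvent)
  ctr <- .vox_center(grid, solvent)
  nodes <- data.frame(idx = solvent, x = ctr[, 1], y = ctr[, 2],
                      z = ctr[, 3])
  # 13 positive-direction offsets cover each undirected edge once
  offs <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  idx0 <- solvent - 1L
  k <- idx0 %/% (nx * ny); rem <- idx0 %% (nx * ny)
  j <- rem %/% nx; i <- rem %% nx
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
    ok <- ii >= 0 & ii < nx & jj >= 0 & jj < ny & kk >= 0 & kk < nz
    nb <- 1L + ii[ok] + nx * (jj[ok] + ny * kk[ok])
    sol <- grid$labels[nb] == 0L
    from <- c(from, node_of[solvent[ok][sol]])
    to <- c(to, node_of[nb[sol]])
    wt <- c(wt, rep(grid$spacing * sqrt(sum(offs[r, ]^2)), sum(sol)))
  }
  list(nodes = nodes, edges = data.frame(from = from, to = to,
                                         weight = wt))
}
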