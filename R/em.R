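# Simulated 3D-EM density maps and the density-fitness score
# F = (n x MI) - PS, where n is the number of subunits, MI the mutual
# information between the simulated model map and the target map, and PS a
# clash penalty; combined with the crosslink score as F + 0.5 x cMNXL.

#' Construct a density map object
#'
#' @param data 3D numeric array of intensities (x fastest).
#' @param origin position of the first voxel center, Angstrom.
#' @param voxel_size voxel edge length, Angstrom.
#' @param resolution nominal resolution label, Angstrom.
#' @return object of class `density_map`.
#' @export
density_map <- function(data, origin, voxel_size, resolution = NA_real_) {
  stopifnot(length(dim(data)) == 3, voxel_size > 0,
            all(is.finite(data)))
  structure(list(data = data, origin = as.numeric(origin),
                 voxel_size = voxel_size, resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("Density map ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ", x$voxel_size, " A",
      if (!is.na(x$resolution))
        paste0(", nominal resolution ", x$resolution, " A"),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a density map from a structure
#'
#' Each atom contributes a 3D Gaussian with FWHM equal to the nominal
#' resolution (sigma = resolution / (2 sqrt(2 ln 2))), weighted by its
#' atomic number; the map extent covers the structure plus a 2-sigma
#' margin.
#'
#' @param complex an `xl_complex`.
#' @param resolution nominal resolution, Angstrom.
#' @param voxel_size sampling, Angstrom; must satisfy
#'   `resolution >= 2 * voxel_size`.
#' @return a `density_map`.
#' @export
simulate_map <- function(complex, resolution, voxel_size = resolution / 4) {
  stopifnot(inherits(complex, "xl_complex"))
  if (resolution < 2 * voxel_size)
    stop("resolution must be at least twice the voxel size ",
         "(sampling error)")
  sigma <- resolution / (2 * sqrt(2 * log(2)))
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")])
  wz <- .element_number(complex$atoms$elesy)
  lo <- apply(xyz, 2, min) - 2 * sigma
  hi <- apply(xyz, 2, max) + 2 * sigma
  dm <- as.integer(ceiling((hi - lo) / voxel_size)) + 1L
  arr <- array(0, dm)
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dm[d]) - 1) * voxel_size)
  reach <- 3 * sigma
  norm <- (2 * pi * sigma^2)^(-1.5)
  for (a in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(d) {
      which(ax[[d]] >= xyz[a, d] - reach & ax[[d]] <= xyz[a, d] + reach)
    })
    if (any(!lengths(rng))) next
    gx <- exp(-(ax[[1]][rng[[1]]] - xyz[a, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - xyz[a, 2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - xyz[a, 3])^2 / (2 * sigma^2))
    arr[rng[[1]], rng[[2]], rng[[3]]] <-
      arr[rng[[1]], rng[[2]], rng[[3]]] +
      wz[a] * norm * (gx %o% gy %o% gz)
  }
  density_map(arr, lo, voxel_size, resolution)
}

#' Resample a map onto the grid of another map
#'
#' Trilinear interpolation of `map` at the voxel centers of `target`;
#' positions outside `map` read as 0.
#'
#' @param map,target `density_map` objects.
#' @return a `density_map` on the grid of `target`.
#' @export
resample_map <- function(map, target) {
  dm <- dim(target$data)
  pts <- as.matrix(expand.grid(
    x = target$origin[1] + (seq_len(dm[1]) - 1) * target$voxel_size,
    y = target$origin[2] + (seq_len(dm[2]) - 1) * target$voxel_size,
    z = target$origin[3] + (seq_len(dm[3]) - 1) * target$voxel_size))
  g <- sweep(pts, 2, map$origin) / map$voxel_size
  sm <- dim(map$data)
  i0 <- floor(g)
  f <- g - i0
  val <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    wtr <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    ok <- ii >= 0 & ii < sm[1] & jj >= 0 & jj < sm[2] &
      kk >= 0 & kk < sm[3] & wtr > 0
    if (!any(ok)) next
    lin <- 1L + ii[ok] + sm[1] * (jj[ok] + sm[2] * kk[ok])
    val[ok] <- val[ok] + wtr[ok] * map$data[lin]
  }
  density_map(array(val, dm), target$origin, target$voxel_size,
              map$resolution)
}

#' Mutual information between two density maps
#'
#' MI of the joint intensity histogram (equal-width bins over each map's
#' own intensity range, natural logarithm). Maps on different grids are
#' first brought onto the coarser of the two grids by trilinear
#' resampling.
#'
#' @param map_a,map_b `density_map` objects.
#' @param bins number of histogram bins per axis.
#' @return mutual information in nats (non-negative).
#' @export
mutual_information <- function(map_a, map_b, bins = 20) {
  if (diff(range(map_a$data)) == 0 || diff(range(map_b$data)) == 0) {
    warning("constant map: mutual information is 0")
    return(0)
  }
  same_grid <- identical(dim(map_a$data), dim(map_b$data)) &&
    isTRUE(all.equal(map_a$origin, map_b$origin)) &&
    isTRUE(all.equal(map_a$voxel_size, map_b$voxel_size))
  if (!same_grid) {
    # canonical target grid (so the result is symmetric in the inputs):
    # the coarser map, then the larger map, then the lower origin
    key <- function(m) c(m$voxel_size, prod(dim(m$data)), -m$origin)
    ka <- key(map_a); kb <- key(map_b)
    cmp <- (ka - kb)[match(TRUE, ka != kb)]
    if (!is.na(cmp) && cmp < 0) {
      map_a <- resample_map(map_a, map_b)
    } else {
      map_b <- resample_map(map_b, map_a)
    }
  }
  va <- as.numeric(map_a$data); vb <- as.numeric(map_b$data)
  if (diff(range(va)) == 0 || diff(range(vb)) == 0) {
    warning("constant map: mutual information is 0")
    return(0)
  }
  cut_idx <- function(v) {
    r <- range(v)
    pmin(pmax(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  bi <- cut_idx(va); bj <- cut_idx(vb)
  joint <- tabulate(bi + bins * (bj - 1L), bins * bins) / length(va)
  pj <- matrix(joint, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

#' Inter-subunit clash penalty
#'
#' Fraction of atoms involved in at least one inter-subunit atom pair
#' closer than `overlap_frac` times the sum of the two vdW radii, scaled by
#' `scale`.
#'
#' @param complex an `xl_complex` (>= 2 subunits).
#' @param scale multiplicative factor on the clashing-atom fraction.
#' @param overlap_frac clash threshold as a fraction of the vdW contact
#'   distance.
#' @return penalty >= 0.
#' @export
clash_penalty <- function(complex, scale = 1, overlap_frac = 0.5) {
  stopifnot(inherits(complex, "xl_complex"))
  a <- complex$atoms
  chains <- unique(a$chain)
  hit <- logical(nrow(a))
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (j <= i) next
    si <- which(a$chain == chains[i]); sj <- which(a$chain == chains[j])
    cp <- cpp_close_pairs(as.matrix(a[si, c("x", "y", "z")]),
                          as.matrix(a[sj, c("x", "y", "z")]),
                          .element_radius(a$elesy[si]),
                          .element_radius(a$elesy[sj]),
                          overlap_frac, 0)
    hit[si] <- hit[si] | cp$hit_a
    hit[sj] <- hit[sj] | cp$hit_b
  }
  scale * mean(hit)
}

#' Density fitness of a model against a target map
#'
#' Simulates a map of the model at the target's nominal resolution and
#' voxel size, computes the mutual information against the target and the
#' clash penalty of the model: `F = n_subunits * MI - PS`.
#'
#' @param model an `xl_complex`.
#' @param target a `density_map` with a `resolution` label.
#' @param bins MI histogram bins.
#' @param clash_scale scale of the clash penalty.
#' @return object of class `em_fitness` with fields `mi`, `ps`,
#'   `n_subunits`, `f`.
#' @export
f_score <- function(model, target, bins = 20, clash_scale = 1) {
  stopifnot(inherits(model, "xl_complex"),
            inherits(target, "density_map"))
  if (is.na(target$resolution))
    stop("target map has no resolution label")
  n <- nrow(model$subunits)
  mm <- simulate_map(model, target$resolution, target$voxel_size)
  mi <- mutual_information(mm, target, bins = bins)
  ps <- clash_penalty(model, scale = clash_scale)
  structure(list(mi = mi, ps = ps, n_subunits = n, f = n * mi - ps),
            class = "em_fitness")
}

#' @export
print.em_fitness <- function(x, ...) {
  cat(sprintf(
    "EM fitness: F = %d x %.4f (MI) - %.4f (clash) = %.4f\n",
    x$n_subunits, x$mi, x$ps, x$f))
  invisible(x)
}

#' Combined crosslink + density score
#'
#' `F + 0.5 * cMNXL`.
#'
#' @param f an `em_fitness` object or the numeric F value.
#' @param cmnxl a `cmnxl_score` object or the numeric total.
#' @param weight weight on the crosslink score.
#' @return numeric combined score.
#' @export
combined_score <- function(f, cmnxl, weight = 0.5) {
  fv <- if (inherits(f, "em_fitness")) f$f else f
  cv <- if (inherits(cmnxl, "cmnxl_score")) cmnxl$total else cmnxl
  stopifnot(is.finite(fv), is.finite(cv))
  fv + weight * cv
}
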