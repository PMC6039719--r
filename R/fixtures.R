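# Synthetic fixtures: idealized helical toy complexes with surface lysines,
# rigid-body decoy ensembles with a main-chain clash filter, and bundled
# benchmark generation. Everything is deterministic under a seed so tests
# and examples need no downloads.

# one idealized poly-alanine helix along +z, axis through (cx, cy);
# residues numbered resno_start .. resno_start + n_res - 1; lysines (side
# chain pointing radially outward) at `lys_pos` (absolute residue
# numbers). Returns an atom data.frame.
.helix_segment <- function(chain, n_res, cx = 0, cy = 0, phase = 0,
                           lys_pos = integer(0), resno_start = 1) {
  rise <- 1.5
  twist <- 100 * pi / 180
  rows <- list()
  add <- function(resno, resid, elety, elesy, r, ang, z) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = resid,
      elety = elety, elesy = elesy,
      x = cx + r * cos(ang), y = cy + r * sin(ang), z = z,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_res)) {
    i <- resno_start + j - 1
    ang <- phase + (j - 1) * twist
    z <- (j - 1) * rise
    resid <- if (i %in% lys_pos) "LYS" else "ALA"
    add(i, resid, "N", "N", 1.56, ang - 28 * pi / 180, z - 0.55)
    add(i, resid, "CA", "C", 2.30, ang, z)
    add(i, resid, "C", "C", 1.66, ang + 28 * pi / 180, z + 0.52)
    add(i, resid, "O", "O", 2.00, ang + 44 * pi / 180, z + 1.00)
    add(i, resid, "CB", "C", 3.30, ang, z - 0.30)
    if (resid == "LYS") {
      # side chain reaching outward with a slight curl, amine ~6.5 A
      # from the helix axis (a relaxed, not fully extended, lysine)
      side <- c(CG = 4.30, CD = 5.10, CE = 5.90, NZ = 6.55)
      zjit <- c(0.25, -0.2, 0.3, 0)
      for (s in seq_along(side))
        add(i, resid, names(side)[s],
            if (names(side)[s] == "NZ") "N" else "C",
            side[s], ang, z - 0.3 + zjit[s])
    }
  }
  do.call(rbind, rows)
}

#' Generate an idealized toy protein complex
#'
#' Subunits are small poly-alanine helix bundles. A dimer is built as a
#' concave receptor (three helices forming a U-shaped groove) holding a
#' two-helix ligand at its mouth, mimicking the interlocking interfaces of
#' real complexes; larger assemblies place two-helix subunits on a ring.
#' The requested number of lysines is substituted at surface sites chosen
#' so that (a) the side-chain amine has clearance from every other helix
#' (solvent accessibility, verified on the voxel grid) and (b)
#' inter-subunit amine separations concentrate in the distance band where
#' crosslink surface distances track the expected-distance distribution
#' observed for native complexes.
#'
#' @param n_subunits number of chains (>= 2).
#' @param residues_per_subunit residues per subunit (split over its
#'   helices).
#' @param n_surface_lysines total lysines across the complex.
#' @param seed RNG seed; the output is deterministic given the arguments.
#' @param identical_subunits when `TRUE`, every subunit gets the same
#'   lysine positions (a homo-oligomer by sequence).
#' @return an `xl_complex`.
#' @export
make_toy_complex <- function(n_subunits = 2, residues_per_subunit = 30,
                             n_surface_lysines = 6, seed = 1,
                             identical_subunits = FALSE) {
  if (n_subunits < 2) stop("a complex needs at least 2 subunits")
  twist <- 100 * pi / 180
  rise <- 1.5
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- residues_per_subunit
  split_n <- function(parts) diff(round(seq(0, n, length.out = parts + 1)))
  # helix layout: per-subunit axis positions in the xy plane (homo
  # assemblies use the symmetric ring so all copies are equivalent)
  if (n_subunits == 2 && !identical_subunits) {
    seg_a <- split_n(3)
    seg_b <- split_n(2)
    helices <- data.frame(
      sub = c(1, 1, 1, 2, 2),
      ax = c(0, -6, 0, 7, 15),
      ay = c(-7, 0, 7, 0, 0),
      n_res = c(seg_a, seg_b),
      resno_start = c(cumsum(c(0, seg_a[-3])) + 1,
                      cumsum(c(0, seg_b[-2])) + 1))
  } else {
    rad <- 20 / (2 * sin(pi / n_subunits))
    th <- 2 * pi * (seq_len(n_subunits) - 1) / n_subunits
    seg <- split_n(2)
    helices <- do.call(rbind, lapply(seq_len(n_subunits), function(s) {
      # homo-oligomers use one fixed orientation so every copy is an
      # exact translate of the others
      u <- if (identical_subunits) c(0, 1) else
        c(cos(th[s] + pi / 2), sin(th[s] + pi / 2))
      c0 <- c(rad * cos(th[s]), rad * sin(th[s]))
      data.frame(sub = s, ax = c0[1] + c(-5, 5) * u[1],
                 ay = c0[2] + c(-5, 5) * u[2], n_res = seg,
                 resno_start = cumsum(c(0, seg[-2])) + 1)
    }))
  }
  helices$phase <- runif(nrow(helices), 0, 2 * pi)
  if (identical_subunits)
    helices$phase <- rep(helices$phase[helices$sub == 1],
                         n_subunits)
  quota <- diff(round(seq(0, n_surface_lysines,
                          length.out = n_subunits + 1)))
  if (identical_subunits)
    quota <- rep(ceiling(n_surface_lysines / n_subunits), n_subunits)
  # candidate sites: interior residues of each helix whose analytic amine
  # position clears every other helix axis (accessible in the native, but
  # groove-adjacent sites become buried in wrong poses); greedy selection
  # then targets inter-subunit amine separations in the band where
  # crosslink surface distances track the expected-distance distribution
  # of real native complexes
  cand <- do.call(rbind, lapply(seq_len(nrow(helices)), function(hh) {
    h <- helices[hh, ]
    if (h$n_res < 4) return(NULL)
    local_pos <- 2:(h$n_res - 1)
    resno <- h$resno_start + local_pos - 1
    ang <- h$phase + (local_pos - 1) * twist
    nx <- h$ax + 6.55 * cos(ang)
    ny <- h$ay + 6.55 * sin(ang)
    clear <- vapply(seq_along(nx), function(i) {
      d <- sqrt((helices$ax - nx[i])^2 + (helices$ay - ny[i])^2)
      all(d[-hh] >= 6.5)
    }, logical(1))
    if (!any(clear)) return(NULL)
    data.frame(sub = h$sub, pos = resno[clear], nx = nx[clear],
               ny = ny[clear], nz = (local_pos[clear] - 1) * rise - 0.3)
  }))
  if (is.null(cand)) cand <- data.frame(sub = integer(0), pos = integer(0),
                                        nx = numeric(0), ny = numeric(0),
                                        nz = numeric(0))
  for (s in seq_len(n_subunits))
    if (quota[s] > sum(cand$sub == s))
      stop("requested lysines exceed available surface positions ",
           "(subunit ", s, ": ", sum(cand$sub == s), " eligible)")
  ed_band <- c(14, 23)
  in_band <- function(i, picked) {
    if (!length(picked)) return(0)
    other <- picked[cand$sub[picked] != cand$sub[i]]
    if (!length(other)) return(0)
    d <- sqrt((cand$nx[other] - cand$nx[i])^2 +
                (cand$ny[other] - cand$ny[i])^2 +
                (cand$nz[other] - cand$nz[i])^2)
    sum(d >= ed_band[1] & d <= ed_band[2]) -
      0.25 * sum(d > 26)  # discourage near-bound restraints
  }
  if (identical_subunits) {
    # same lysine positions on every copy so the sequences are identical
    common <- sort(Reduce(intersect, split(cand$pos, cand$sub)))
    if (length(common) < quota[1])
      stop("requested lysines exceed available surface positions ",
           "shared by all copies (", length(common), " eligible)")
    take <- unique(round(seq(1, length(common),
                             length.out = quota[1])))
    while (length(take) < quota[1])
      take <- unique(c(take, sample(setdiff(seq_along(common), take), 1)))
    lys <- rep(list(common[sort(take)]), n_subunits)
  } else {
    picked <- sample(which(cand$sub == 1), 1)
    left <- quota
    left[1] <- left[1] - 1
    while (sum(left) > 0) {
      open <- which(!(seq_len(nrow(cand)) %in% picked) &
                      left[cand$sub] > 0)
      gain <- vapply(open, in_band, numeric(1), picked = picked)
      best <- open[gain >= max(gain) - 1e-9]
      choice <- if (length(best) > 1) sample(best, 1) else best
      picked <- c(picked, choice)
      left[cand$sub[choice]] <- left[cand$sub[choice]] - 1
    }
    lys <- lapply(seq_len(n_subunits), function(s)
      sort(cand$pos[picked[cand$sub[picked] == s]]))
  }
  atoms <- do.call(rbind, lapply(seq_len(n_subunits), function(s) {
    hs <- helices[helices$sub == s, ]
    do.call(rbind, lapply(seq_len(nrow(hs)), function(k)
      .helix_segment(LETTERS[s], hs$n_res[k], hs$ax[k], hs$ay[k],
                     hs$phase[k], lys[[s]],
                     resno_start = hs$resno_start[k])))
  }))
  cx <- xl_complex(atoms, name = sprintf("toy_%ds_%dr_seed%d",
                                         n_subunits,
                                         residues_per_subunit, seed))
  grid <- build_grid(cx)
  rt <- crosslinkable_residues(cx)
  acc <- is_accessible(grid, cx, rt$chain, rt$resno)
  if (!all(acc))
    stop("internal fixture error: ", sum(!acc),
         " generated lysine(s) are not solvent accessible")
  cx
}

#' Toy complex with one buried (caged) lysine amine
#'
#' A two-chain helical complex in which one lysine side-chain amine of
#' chain A is enclosed by a synthetic cage of carbon atoms, making it
#' solvent inaccessible, while the remaining lysines stay on the surface.
#' Used to exercise the non-accessibility term.
#'
#' @param seed RNG seed passed to the underlying toy builder.
#' @return list with `complex` (an `xl_complex`), `buried` (chain/resno of
#'   the caged lysine) and `exposed` (data.frame of the accessible
#'   lysines).
#' @export
make_cage_complex <- function(seed = 1) {
  cx <- make_toy_complex(2, 20, 4, seed = seed)
  rt <- crosslinkable_residues(cx)
  target <- rt[rt$chain == "A", ][1, ]
  nz <- c(target$ax, target$ay, target$az)
  # Fibonacci sphere of cage atoms around the amine
  npts <- 48
  i <- seq_len(npts) - 0.5
  phi <- acos(1 - 2 * i / npts)
  theta <- pi * (1 + sqrt(5)) * i
  cage <- cbind(nz[1] + 3.4 * sin(phi) * cos(theta),
                nz[2] + 3.4 * sin(phi) * sin(theta),
                nz[3] + 3.4 * cos(phi))
  base <- max(cx$atoms$resno[cx$atoms$chain == "A"])
  cage_atoms <- data.frame(chain = "A", resno = base + seq_len(npts),
                           insert = "", resid = "GLY", elety = "CA",
                           elesy = "C", x = cage[, 1], y = cage[, 2],
                           z = cage[, 3], stringsAsFactors = FALSE)
  out <- xl_complex(rbind(cx$atoms, cage_atoms),
                    name = paste0(cx$name, "_caged"))
  grid <- build_grid(out)
  if (is_accessible(grid, out, target$chain, target$resno))
    stop("internal fixture error: caged lysine is still accessible")
  rt2 <- crosslinkable_residues(out)
  keep <- !(rt2$chain == target$chain & rt2$resno == target$resno)
  acc <- is_accessible(grid, out, rt2$chain[keep], rt2$resno[keep])
  list(complex = out,
       buried = list(chain = target$chain, resno = target$resno),
       exposed = rt2[keep, ][acc, c("chain", "resno")])
}

#' Decoy-generation recipe
#'
#' Each decoy is produced from the native by iteratively translating and
#' rotating every subunit by a random offset (per-axis translation uniform
#' in `trans_range`, rotation angle uniform in `rot_range` about a random
#' axis through the subunit centroid), then filtered to allow at most
#' `max_mainchain_clashes` inter-subunit main-chain atom pairs closer than
#' `clash_cutoff`. With `target_rmsd = "uniform"` the accepted pool is
#' subsampled to flatten the mean-RMSD histogram.
#'
#' @param n_decoys number of decoys.
#' @param trans_range translation interval per axis, Angstrom.
#' @param rot_range rotation-angle interval, degrees.
#' @param max_mainchain_clashes clash-filter bound.
#' @param clash_cutoff main-chain clash distance, Angstrom.
#' @param target_rmsd `"uniform"` or `"none"`.
#' @param n_iter_mean mean of the geometric number of perturbation
#'   iterations per subunit.
#' @param pool_factor accepted-pool size relative to `n_decoys` used for
#'   uniform-RMSD selection.
#' @param rng_seed seed used by [generate_decoys()].
#' @return list of class `decoy_recipe`.
#' @export
decoy_recipe <- function(n_decoys = 100, trans_range = c(-5, 5),
                         rot_range = c(0, 180),
                         max_mainchain_clashes = 20, clash_cutoff = 2,
                         target_rmsd = c("uniform", "none"),
                         n_iter_mean = 3, pool_factor = 3,
                         rng_seed = 1) {
  target_rmsd <- match.arg(target_rmsd)
  stopifnot(n_decoys >= 1, diff(trans_range) >= 0,
            diff(rot_range) >= 0, rot_range[1] >= 0)
  structure(list(n_decoys = n_decoys, trans_range = trans_range,
                 rot_range = rot_range,
                 max_mainchain_clashes = max_mainchain_clashes,
                 clash_cutoff = clash_cutoff, target_rmsd = target_rmsd,
                 n_iter_mean = n_iter_mean, pool_factor = pool_factor,
                 rng_seed = rng_seed),
            class = "decoy_recipe")
}

# random rotation matrix: uniform axis, given angle (radians)
.axis_rotation <- function(angle) {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

.count_mainchain_clashes <- function(x, cutoff) {
  mc <- c("N", "CA", "C", "O")
  chains <- unique(x$atoms$chain)
  total <- 0
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (j <= i) next
    a <- .chain_coords(x, chains[i], mc)
    b <- .chain_coords(x, chains[j], mc)
    total <- total + cpp_close_pairs(a, b, numeric(nrow(a)),
                                     numeric(nrow(b)), 0, cutoff)$count
  }
  total
}

.perturb_complex <- function(native, recipe, scale = 1) {
  x <- native
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  ch <- x$atoms$chain
  for (c_ in x$subunits$chain_id) {
    sel <- ch == c_
    sub <- m[sel, , drop = FALSE]
    n_iter <- 1 + rgeom(1, 1 / recipe$n_iter_mean)
    for (it in seq_len(n_iter)) {
      rot <- .axis_rotation(scale * runif(1, recipe$rot_range[1],
                                          recipe$rot_range[2]) * pi / 180)
      trans <- scale * runif(3, recipe$trans_range[1],
                             recipe$trans_range[2])
      ctr <- colMeans(sub)
      sub <- sweep(sweep(sub, 2, ctr) %*% t(rot), 2, ctr + trans, "+")
    }
    m[sel, ] <- sub
  }
  x$atoms$x <- m[, 1]
  x$atoms$y <- m[, 2]
  x$atoms$z <- m[, 3]
  x
}

#' Generate a rigid-body decoy ensemble
#'
#' @param native the native `xl_complex`.
#' @param recipe a [decoy_recipe()].
#' @param max_attempt_factor work budget: generation aborts when fewer
#'   than 1 percent of candidates pass the clash filter.
#' @return list of `xl_complex` decoys, each carrying its mean RMSD to the
#'   native as attribute `"mean_rmsd"`.
#' @export
generate_decoys <- function(native, recipe = decoy_recipe(),
                            max_attempt_factor = 100) {
  stopifnot(inherits(native, "xl_complex"),
            inherits(recipe, "decoy_recipe"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(recipe$rng_seed)
  pool_n <- if (recipe$target_rmsd == "uniform")
    recipe$pool_factor * recipe$n_decoys else recipe$n_decoys
  pool <- vector("list", pool_n)
  got <- 0; tries <- 0
  budget <- max_attempt_factor * pool_n
  while (got < pool_n) {
    tries <- tries + 1
    if (tries > budget)
      stop("decoy rejection rate too high (", got, "/", tries,
           " accepted); loosen the recipe")
    cand <- .perturb_complex(native, recipe)
    if (.count_mainchain_clashes(cand, recipe$clash_cutoff) >
        recipe$max_mainchain_clashes) next
    got <- got + 1
    pool[[got]] <- cand
  }
  rmsd <- vapply(pool, mean_rmsd, numeric(1), native = native)
  if (recipe$target_rmsd == "uniform" &&
      diff(range(rmsd)) > .Machine$double.eps) {
    # flatten the mean-RMSD histogram over [0, max achieved]: top up
    # deficient bins (near-native models are rare under random rigid-body
    # moves) and then select round-robin across bins
    br <- seq(0, max(rmsd), length.out = 11)
    quota <- ceiling(recipe$n_decoys / 10)
    bin <- findInterval(rmsd, br, rightmost.closed = TRUE)
    # full-range moves almost never land near the native, so deficient
    # bins in the lower half of the histogram are topped up with
    # magnitude-scaled candidates (the ensemble analogue of the
    # refinement used to obtain near-native benchmark models); the upper
    # bins are left to the full-range pool
    extra_budget <- 50 * recipe$n_decoys
    counts <- tabulate(bin, 10)
    while (any(counts[1:5] < quota) && extra_budget > 0) {
      extra_budget <- extra_budget - 1
      want <- which(counts[1:5] < quota)
      b_target <- want[sample.int(length(want), 1)]
      sc <- sqrt(runif(1, (b_target - 1) / 10, b_target / 10))
      cand <- .perturb_complex(native, recipe, scale = sc)
      if (.count_mainchain_clashes(cand, recipe$clash_cutoff) >
          recipe$max_mainchain_clashes) next
      r <- mean_rmsd(cand, native)
      b <- findInterval(r, br, rightmost.closed = TRUE)
      if (b < 1 || b > 10 || counts[b] >= quota) next
      pool[[length(pool) + 1]] <- cand
      rmsd <- c(rmsd, r)
      bin <- c(bin, b)
      counts[b] <- counts[b] + 1
    }
    by_bin <- split(seq_along(pool), bin)
    by_bin <- lapply(by_bin, sample)
    sel <- integer(0); round <- 1
    while (length(sel) < recipe$n_decoys) {
      for (b in seq_along(by_bin)) {
        if (length(sel) >= recipe$n_decoys) break
        if (length(by_bin[[b]]) >= round)
          sel <- c(sel, by_bin[[b]][round])
      }
      round <- round + 1
    }
    pool <- pool[sel]
    rmsd <- rmsd[sel]
  } else {
    pool <- pool[seq_len(recipe$n_decoys)]
    rmsd <- rmsd[seq_len(recipe$n_decoys)]
  }
  for (i in seq_along(pool)) {
    pool[[i]]$name <- sprintf("%s_decoy%03d", native$name, i)
    attr(pool[[i]], "mean_rmsd") <- rmsd[i]
  }
  pool
}

#' Bundle a reproducible synthetic benchmark
#'
#' Generates a decoy ensemble from a native complex, enumerates the
#' theoretical crosslinks of the native, samples an observed set at the
#' given recovery rate (with at least `min_inter` inter-subunit links) and
#' labels every decoy with its quality metrics.
#'
#' @param native the native `xl_complex`.
#' @param recipe a [decoy_recipe()].
#' @param recovery_rate fraction of theoretical crosslinks observed.
#' @param seed RNG seed for the recovery sample.
#' @param min_inter minimum inter-subunit crosslinks in the sample.
#' @param max_bound crosslinker maximum SASD bound, Angstrom.
#' @return object of class `xl_benchmark` with fields `native`, `decoys`,
#'   `theoretical`, `sampled`, `quality` (data.frame per decoy), `seed`.
#' @export
make_benchmark <- function(native, recipe = decoy_recipe(),
                           recovery_rate = 0.15, seed = 1,
                           min_inter = 2, max_bound = 32) {
  theo <- theoretical_crosslinks(native, max_bound = max_bound)
  sampled <- sample_recovery(theo, recovery_rate, min_inter = min_inter,
                             seed = seed)
  decoys <- generate_decoys(native, recipe)
  quality <- do.call(rbind, lapply(decoys, model_quality,
                                   native = native))
  quality <- cbind(model_id = vapply(decoys, `[[`, "", "name"), quality)
  rownames(quality) <- NULL
  structure(list(native = native, decoys = decoys, theoretical = theo,
                 sampled = sampled, quality = quality, seed = seed,
                 recipe = recipe, recovery_rate = recovery_rate),
            class = "xl_benchmark")
}

#' @export
print.xl_benchmark <- function(x, ...) {
  cat("Synthetic benchmark on '", x$native$name, "': ",
      length(x$decoys), " decoys, ", nrow(x$theoretical),
      " theoretical crosslinks, ", nrow(x$sampled), " sampled (",
      round(100 * x$recovery_rate), "% recovery), ",
      sum(x$quality$positive), " positive models\n", sep = "")
  invisible(x)
}

#' Write a benchmark fixture to disk
#'
#' Standard PDB files for native and decoys, a crosslink TSV, and a JSON
#' manifest (seed, recipe, file list).
#'
#' @param bench an `xl_benchmark`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(native = "native.pdb")
  write_complex(bench$native, file.path(dir, "native.pdb"))
  for (i in seq_along(bench$decoys)) {
    f <- sprintf("decoy%03d.pdb", i)
    write_complex(bench$decoys[[i]], file.path(dir, f))
    files <- c(files, f)
  }
  write_crosslinks(bench$sampled, file.path(dir, "crosslinks.tsv"))
  files <- c(files, crosslinks = "crosslinks.tsv")
  manifest <- list(seed = bench$seed,
                   recovery_rate = bench$recovery_rate,
                   recipe = unclass(bench$recipe),
                   files = unname(files))
  path <- file.path(dir, "manifest.json")
  writeLines(.to_json(manifest), path)
  invisible(path)
}

# tiny JSON writer for the manifest (numbers, strings, lists)
.to_json <- function(x) {
  if (is.list(x)) {
    if (is.null(names(x)))
      paste0("[", paste(vapply(x, .to_json, ""), collapse = ","), "]")
    else
      paste0("{", paste(sprintf('"%s":%s', names(x),
                                vapply(x, .to_json, "")),
                        collapse = ","), "}")
  } else if (is.character(x)) {
    if (length(x) > 1) .to_json(as.list(x))
    else sprintf('"%s"', x)
  } else {
    if (length(x) > 1) .to_json(as.list(x))
    else format(x, scientific = FALSE)
  }
}
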