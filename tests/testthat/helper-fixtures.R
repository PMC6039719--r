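# Shared fixture builders. Everything is generated in code; structures are
# small so the whole suite stays fast.

# a bare two-chain complex from explicit CA (+ optional extra atom) rows
flat_complex <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, rows)
  xl_complex(atoms, name = "flat")
}

atom_row <- function(chain, resno, elety, x, y, z, resid = "ALA",
                     elesy = NULL) {
  if (is.null(elesy)) elesy <- xlscore:::.infer_element(elety)
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# a rigid slab of CA atoms in the z = 0 plane (two chains split in x),
# plus two lysines whose amines protrude into the solvent above the slab
# at the given (x, y) positions
slab_complex <- function(nx = 12, ny = 8, spacing = 2,
                         lys_at = list(c(4, 6), c(14, 6))) {
  rows <- list()
  rn <- 0
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    rn <- rn + 1
    ch <- if (ix <= nx / 2) "A" else "B"
    rows[[length(rows) + 1]] <-
      atom_row(ch, rn, "CA", (ix - 1) * spacing, (iy - 1) * spacing, 0)
  }
  half <- (nx / 2) * spacing
  for (p in lys_at) {
    rn <- rn + 1
    ch <- if (p[1] < half) "A" else "B"
    rows[[length(rows) + 1]] <-
      atom_row(ch, rn, "CB", p[1], p[2], 1.8, resid = "LYS")
    rows[[length(rows) + 1]] <-
      atom_row(ch, rn, "NZ", p[1], p[2], 3.6, resid = "LYS")
  }
  do.call(flat_complex, rows)
}

# independent shortest-path oracle on the exported voxel graph (igraph).
# The graph is built once per grid; each pair query adds two virtual
# terminal nodes wired to the anchor entry voxels with the anchor-to-entry
# offsets as edge weights, so one shortest-path call yields the SASD.
make_sasd_oracle <- function(grid) {
  skip_if_not_installed("igraph")
  vg <- voxel_graph(grid)
  g0 <- igraph::make_empty_graph(n = nrow(vg$nodes) + 2,
                                 directed = FALSE)
  g0 <- igraph::add_edges(
    g0, rbind(vg$edges$from, vg$edges$to),
    weight = vg$edges$weight)
  list(g0 = g0, node_of = vg$nodes$idx, n = nrow(vg$nodes))
}

oracle_sasd <- function(oracle, grid, complex, chain_a, res_a,
                        chain_b, res_b, cap = 60) {
  rt <- residue_table(complex)
  entry_of <- function(chain, resno) {
    i <- xlscore:::.match_residues(rt, chain, resno)
    xlscore:::.entry_voxels(grid, c(rt$ax[i], rt$ay[i], rt$az[i]),
                            rt$aelesy[i])
  }
  ea <- entry_of(chain_a, res_a)
  eb <- entry_of(chain_b, res_b)
  if (!length(ea$idx) || !length(eb$idx)) return(NA_real_)
  na_ <- match(ea$idx, oracle$node_of)
  nb_ <- match(eb$idx, oracle$node_of)
  src <- oracle$n + 1L
  dst <- oracle$n + 2L
  g <- igraph::add_edges(
    oracle$g0,
    rbind(c(rep(src, length(na_)), rep(dst, length(nb_))),
          c(na_, nb_)),
    weight = c(ea$offset, eb$offset))
  best <- as.numeric(igraph::distances(g, v = src, to = dst))
  if (is.finite(best) && best <= cap) best else NA_real_
}

# brute-force flood-fill labelling oracle in plain R (6-connectivity),
# mirroring the contract: protein within radius, boundary-connected
# solvent, the rest buried cavity
oracle_labels <- function(coords, radii, origin, dim, spacing) {
  nvox <- prod(dim)
  lab <- rep(2L, nvox)
  ctr <- as.matrix(expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                               k = 0:(dim[3] - 1)))
  xyz <- sweep(ctr * spacing, 2, origin, "+")
  if (nrow(coords))
    for (a in seq_len(nrow(coords))) {
      d2 <- rowSums(sweep(xyz, 2, coords[a, ])^2)
      lab[d2 <= radii[a]^2] <- 1L
    }
  on_boundary <- ctr[, 1] %in% c(0, dim[1] - 1) |
    ctr[, 2] %in% c(0, dim[2] - 1) | ctr[, 3] %in% c(0, dim[3] - 1)
  queue <- which(lab == 2L & on_boundary)
  lab[queue] <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    i <- ctr[v, ]
    for (d in 1:3) for (s in c(-1, 1)) {
      nb <- i; nb[d] <- nb[d] + s
      if (nb[d] < 0 || nb[d] >= dim[d]) next
      w <- 1 + nb[1] + dim[1] * (nb[2] + dim[2] * nb[3])
      if (lab[w] == 2L) { lab[w] <- 0L; queue <- c(queue, w) }
    }
  }
  lab
}

# AUC by the Mann-Whitney rank formulation (ties counted half)
rank_auc <- function(score, positive) {
  r <- rank(score)
  P <- sum(positive); N <- sum(!positive)
  (sum(r[positive]) - P * (P + 1) / 2) / (P * N)
}

# cached small benchmark shared across test files
.xl_test_cache <- new.env(parent = emptyenv())
cached_benchmark <- function(seed = 101, n_decoys = 40) {
  key <- paste0("bench_", seed, "_", n_decoys)
  if (is.null(.xl_test_cache[[key]])) {
    native <- make_toy_complex(2, 20, 12, seed = seed)
    .xl_test_cache[[key]] <- make_benchmark(
      native, decoy_recipe(n_decoys = n_decoys, rng_seed = seed),
      seed = seed)
  }
  .xl_test_cache[[key]]
}
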