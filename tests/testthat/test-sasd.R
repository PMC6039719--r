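# SASD engine: Euclidean distances, path search on the solvent grid,
# agreement with an independent shortest-path oracle, and theoretical
# crosslink enumeration.

test_that("compute_ed returns plain Euclidean anchor distances", {
  cx <- flat_complex(
    atom_row("A", 1, "CA", 0, 0, 0),
    atom_row("A", 2, "CA", 0, 8, 0),
    atom_row("B", 1, "CA", 3, 4, 0))
  pairs <- data.frame(chain_a = c("A", "A"), res_a = c(1, 1),
                      chain_b = c("B", "A"), res_b = c(1, 2))
  expect_equal(compute_ed(cx, pairs), c(5, 8))
  # identical anchors across a duplicated pair give 0
  p0 <- data.frame(chain_a = "A", res_a = 1, chain_b = "A", res_b = 1)
  expect_equal(compute_ed(cx, p0), 0)
})

test_that("on a flat exposed face SASD stays close to ED", {
  cx <- slab_complex()
  grid <- build_grid(cx)
  rt <- crosslinkable_residues(cx)
  pairs <- data.frame(chain_a = rt$chain[1], res_a = rt$resno[1],
                      chain_b = rt$chain[2], res_b = rt$resno[2])
  d <- compute_sasd(cx, pairs, grid = grid)
  expect_equal(d$status, "ok")
  expect_gte(d$sasd, d$ed)
  expect_lte(d$sasd, d$ed + 2 * grid$spacing)
})

test_that("a buried endpoint yields non_accessible and no SASD", {
  cage <- make_cage_complex(seed = 2)
  ex <- cage$exposed[1, ]
  pairs <- data.frame(chain_a = cage$buried$chain,
                      res_a = cage$buried$resno,
                      chain_b = ex$chain, res_b = ex$resno)
  d <- compute_sasd(cage$complex, pairs)
  expect_equal(d$status, "non_accessible")
  expect_true(is.na(d$sasd))
  expect_true(is.finite(d$ed))
})

test_that("SASD is symmetric and respects the ED lower bound", {
  cx <- make_toy_complex(2, 16, 6, seed = 5)
  grid <- build_grid(cx)
  rt <- crosslinkable_residues(cx)
  comb <- utils::combn(nrow(rt), 2)
  pairs <- data.frame(chain_a = rt$chain[comb[1, ]],
                      res_a = rt$resno[comb[1, ]],
                      chain_b = rt$chain[comb[2, ]],
                      res_b = rt$resno[comb[2, ]])
  fwd <- compute_sasd(cx, pairs, grid = grid)
  rev_pairs <- data.frame(chain_a = pairs$chain_b, res_a = pairs$res_b,
                          chain_b = pairs$chain_a, res_b = pairs$res_a)
  bwd <- compute_sasd(cx, rev_pairs, grid = grid)
  expect_equal(fwd$sasd, bwd$sasd, tolerance = 1e-9)
  ok <- fwd$status == "ok"
  expect_true(any(ok))
  expect_true(all(fwd$sasd[ok] >= fwd$ed[ok] - 2 * grid$spacing))
})

test_that("path lengths agree exactly with an independent oracle", {
  skip_if_not_installed("igraph")
  cx <- make_toy_complex(2, 15, 4, seed = 9)
  grid <- build_grid(cx)
  rt <- crosslinkable_residues(cx)
  pairs <- data.frame(chain_a = rt$chain[1], res_a = rt$resno[1],
                      chain_b = rt$chain[-1], res_b = rt$resno[-1])
  d <- compute_sasd(cx, pairs, grid = grid)
  oracle <- make_sasd_oracle(grid)
  for (i in seq_len(nrow(pairs))) {
    ora <- oracle_sasd(oracle, grid, cx, pairs$chain_a[i],
                       pairs$res_a[i], pairs$chain_b[i], pairs$res_b[i])
    if (d$status[i] == "ok") {
      expect_equal(d$sasd[i], ora, tolerance = 1e-9)
    } else {
      expect_true(is.na(ora))
    }
  }
})

test_that("theoretical crosslink enumeration matches the pairwise oracle", {
  cx <- make_toy_complex(2, 14, 6, seed = 4)
  grid <- build_grid(cx)
  theo <- theoretical_crosslinks(cx, max_bound = 32, grid = grid)
  # oracle: exhaustive pairwise SASD over all lysine pairs
  rt <- crosslinkable_residues(cx)
  comb <- utils::combn(nrow(rt), 2)
  pairs <- data.frame(chain_a = rt$chain[comb[1, ]],
                      res_a = rt$resno[comb[1, ]],
                      chain_b = rt$chain[comb[2, ]],
                      res_b = rt$resno[comb[2, ]])
  d <- compute_sasd(cx, pairs, grid = grid)
  expect_equal(nrow(theo), sum(d$status == "ok" & d$sasd <= 32))
  expect_true(all(theo$sasd <= 32))
  expect_equal(theo$classification,
               ifelse(theo$chain_a == theo$chain_b, "intra", "inter"))
  # a vanishing bound leaves nothing
  expect_equal(nrow(theoretical_crosslinks(cx, max_bound = 0.1,
                                           grid = grid)), 0)
  expect_error(theoretical_crosslinks(cx, max_bound = 0), "positive")
  # batch distance table round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_table(d, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(d))
  expect_equal(back$sasd, d$sasd, tolerance = 1e-6)
  expect_equal(back$status, d$status)
})

test_that("SASD does not increase under grid refinement (within a voxel)", {
  cx <- make_toy_complex(2, 15, 4, seed = 9)
  rt <- crosslinkable_residues(cx)
  pairs <- data.frame(chain_a = rt$chain[1], res_a = rt$resno[1],
                      chain_b = rt$chain[2], res_b = rt$resno[2])
  d1 <- compute_sasd(cx, pairs, spacing = 1.2)
  d2 <- compute_sasd(cx, pairs, spacing = 0.6)
  expect_equal(d1$status, "ok")
  expect_equal(d2$status, "ok")
  expect_lte(d2$sasd, d1$sasd + 1.2)
})
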