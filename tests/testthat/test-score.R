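# cMNXL terms: expected-distance density, violation and non-accessibility
# penalties, the decomposition invariant, and homo-complex resolution.

test_that("expected-distance term is the normal density with a hard cutoff", {
  p_sasd <- cmnxl_params("sasd")
  # density at the mean: 1 / (sigma * sqrt(2*pi))
  expect_equal(score_exdist(21.92, p_sasd), 1 / (4.87 * sqrt(2 * pi)))
  expect_equal(score_exdist(21.92, p_sasd), 0.08192, tolerance = 1e-4)
  expect_equal(score_exdist(33, p_sasd), 0)
  # the boundary belongs to the density branch, not the violation branch
  expect_equal(score_exdist(32, p_sasd), dnorm(32, 21.92, 4.87))
  p_ed <- cmnxl_params("ed")
  expect_equal(score_exdist(18.35, p_ed), 1 / (4.11 * sqrt(2 * pi)))
  expect_equal(score_exdist(18.35, p_ed), 0.09707, tolerance = 1e-4)
  expect_error(score_exdist(-1, p_sasd), "non-negative")
})

test_that("violation term penalizes beyond-bound and no-path results", {
  p <- cmnxl_params("sasd")
  expect_equal(score_violation("ok", 33, p), -0.1)
  expect_equal(score_violation("ok", 31.9, p), 0)
  expect_equal(score_violation("ok", 32, p), 0)
  expect_equal(score_violation("no_path", NA_real_, p), -0.1)
  expect_error(score_violation("non_accessible", 10, p),
               "non-accessibility")
})

test_that("non-accessibility counts split by classification", {
  p <- cmnxl_params("sasd")
  r <- score_nona("non_accessible", "intra", p)
  expect_equal(r$intra_count, 1)
  expect_equal(r$score, -0.3)
  r0 <- score_nona(c("ok", "ok"), c("inter", "intra"), p)
  expect_equal(r0$score, 0)
  r3 <- score_nona(rep("non_accessible", 3),
                   c("inter", "inter", "intra"), p)
  expect_equal(c(r3$inter_count, r3$intra_count), c(2, 1))
  expect_equal(r3$score, -0.9)
  expect_error(score_nona("ok", "unresolved", p), "unresolved")
})

test_that("cMNXL decomposition always equals the weighted term sum", {
  p <- cmnxl_params("sasd")
  for (sd in c(3, 11)) {
    cx <- make_toy_complex(2, 16, 8, seed = sd)
    grid <- build_grid(cx)
    theo <- theoretical_crosslinks(cx, grid = grid)
    s <- cmnxl(cx, theo, p, grid = grid)
    expect_equal(s$total,
                 s$exdist + s$nov + p$nona_weight *
                   (s$nona_inter_count + s$nona_intra_count) *
                   p$nona_penalty)
    expect_gte(s$exdist, 0)
    expect_lte(s$nov, 0)
    expect_lte(s$nona_term, 0)
    expect_equal(s$total, sum(s$per_crosslink$contribution))
  }
})

test_that("a single buried intra crosslink scores the weighted penalty", {
  cage <- make_cage_complex(seed = 2)
  same_chain <- cage$exposed[cage$exposed$chain == cage$buried$chain, ]
  xl <- crosslinks(cage$buried$chain, cage$buried$resno,
                   same_chain$chain[1], same_chain$resno[1])
  expect_equal(xl$classification, "intra")
  s <- cmnxl(cage$complex, xl)
  expect_equal(s$total, -0.3)
  expect_equal(s$nona_intra_count, 1)
  expect_equal(s$exdist, 0)
})

test_that("an empty crosslink set scores zero with a warning", {
  cx <- make_toy_complex(2, 12, 4, seed = 7)
  expect_warning(s <- cmnxl(cx, crosslinks(character(0), integer(0),
                                           character(0), integer(0))),
                 "empty")
  expect_equal(s$total, 0)
})

test_that("accessible intra crosslinks contribute nothing", {
  cx <- make_toy_complex(2, 16, 8, seed = 3)
  grid <- build_grid(cx)
  theo <- theoretical_crosslinks(cx, grid = grid)
  intra <- theo[theo$classification == "intra", ]
  skip_if(nrow(intra) == 0, "fixture produced no intra links")
  s <- cmnxl(cx, intra, grid = grid)
  expect_equal(s$total, 0)
})

test_that("pulling subunits apart never increases the score", {
  cx <- make_toy_complex(2, 16, 8, seed = 3)
  grid <- build_grid(cx)
  theo <- theoretical_crosslinks(cx, grid = grid)
  # links at or beyond the density mean: separation can only lower the
  # density, then turn the link into a violation
  sam <- theo[theo$classification == "inter" & theo$sasd >= 21.92, ]
  skip_if(nrow(sam) < 2, "fixture produced too few long inter links")
  totals <- vapply(c(0, 6, 12, 25, 45), function(shift) {
    m <- xlscore:::.transform_chains(cx, "B", trans = c(shift, 0, 0))
    cmnxl(m, sam)$total
  }, numeric(1))
  expect_true(all(diff(totals) <= 1e-9))
  # far separation turns every inter link into a violation or burial
  expect_lte(totals[length(totals)], -0.1 * nrow(sam))
})

test_that("the ED metric variant keeps grid-based accessibility", {
  cage <- make_cage_complex(seed = 2)
  other <- cage$exposed[cage$exposed$chain != cage$buried$chain, ]
  xl <- crosslinks(cage$buried$chain, cage$buried$resno,
                   other$chain[1], other$resno[1])
  s <- cmnxl(cage$complex, xl, cmnxl_params("ed"))
  expect_equal(s$nona_inter_count, 1)
  expect_equal(s$total, -0.3)
})

test_that("homo-complex resolution picks the lowest-SASD combination", {
  cx <- make_toy_complex(2, 16, 8, seed = 6, identical_subunits = TRUE)
  expect_equal(length(unique(cx$subunits$entity)), 1)
  grid <- build_grid(cx)
  rt <- crosslinkable_residues(cx)
  r_a <- sort(unique(rt$resno))[1]
  r_b <- sort(unique(rt$resno))[2]
  xl <- crosslinks("?", r_a, "?", r_b)
  res <- resolve_crosslinks(cx, xl, grid = grid)
  expect_true(all(res$classification != "unresolved"))
  # oracle: exhaustive SASD over all four chain combinations
  combos <- data.frame(chain_a = c("A", "A", "B", "B"),
                       res_a = r_a,
                       chain_b = c("A", "B", "A", "B"),
                       res_b = r_b)
  d <- compute_sasd(cx, combos, grid = grid)
  sasd <- ifelse(d$status == "ok", d$sasd, Inf)
  best <- which.min(sasd)
  chosen <- paste(res$chain_a, res$chain_b)
  expect_true(paste(combos$chain_a[best], combos$chain_b[best]) %in%
                chosen)
  # reciprocal copy shifts are reproduced (homodimer: two rows)
  expect_equal(nrow(res), 2)
  expect_equal(unique(res$classification),
               if (combos$chain_a[best] == combos$chain_b[best])
                 "intra" else "inter")
})

test_that("resolution on a hetero-complex is a contract error", {
  cx <- flat_complex(
    atom_row("A", 1, "CA", 0, 0, 0), atom_row("A", 2, "CA", 3.8, 0, 0),
    atom_row("B", 1, "CA", 0, 6, 0), atom_row("B", 2, "CA", 3.8, 6, 0),
    atom_row("B", 3, "CA", 7.6, 6, 0))
  xl <- crosslinks("?", 1, "?", 2)
  expect_error(resolve_crosslinks(cx, xl), "homo")
})
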