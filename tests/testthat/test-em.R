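# Simulated density maps, mutual information, clash penalty, the density
# fitness F = n*MI - PS and the combined crosslink + density score.

test_that("a single atom blurs to a radially symmetric blob", {
  cx <- flat_complex(atom_row("A", 1, "CA", 0, 0, 0),
                     atom_row("B", 1, "CA", 40, 0, 0))
  m <- simulate_map(cx, resolution = 10, voxel_size = 2)
  # maximum at an atom position
  top <- which(m$data == max(m$data), arr.ind = TRUE)[1, ]
  pos <- m$origin + (top - 1) * m$voxel_size
  d_to_atoms <- sqrt(pmin(sum(pos^2), sum((pos - c(40, 0, 0))^2)))
  expect_lte(d_to_atoms, m$voxel_size * sqrt(3) / 2 + 1e-9)
  expect_error(simulate_map(cx, resolution = 3, voxel_size = 2),
               "twice the voxel")
})

test_that("integrated density is proportional to total atomic number", {
  mk <- function(elesy) flat_complex(
    atom_row("A", 1, "CA", 0, 0, 0, elesy = elesy[1]),
    atom_row("B", 1, "CA", 12, 0, 0, elesy = elesy[2]))
  m_cc <- simulate_map(mk(c("C", "C")), 8, 1)
  m_ss <- simulate_map(mk(c("S", "S")), 8, 1)
  int_cc <- sum(m_cc$data) * m_cc$voxel_size^3
  int_ss <- sum(m_ss$data) * m_ss$voxel_size^3
  # Z(C) = 6, Z(S) = 16; integrals follow the atomic numbers
  expect_equal(int_ss / int_cc, 16 / 6, tolerance = 0.01)
  # absolute mass: each atom integrates to its atomic number, up to the
  # Gaussian tails clipped at the 2-sigma map margin
  expect_equal(int_cc, 12, tolerance = 0.08)
})

test_that("doubling the nominal resolution doubles the blob FWHM", {
  cx <- flat_complex(atom_row("A", 1, "CA", 0, 0, 0),
                     atom_row("B", 1, "CA", 60, 0, 0))
  fwhm_of <- function(res) {
    m <- simulate_map(cx, res, voxel_size = res / 8)
    # 1D profile through the first atom along x
    iy <- round((0 - m$origin[2]) / m$voxel_size) + 1
    iz <- round((0 - m$origin[3]) / m$voxel_size) + 1
    prof <- m$data[, iy, iz]
    x <- m$origin[1] + (seq_along(prof) - 1) * m$voxel_size
    keep <- x < 30
    prof <- prof[keep]; x <- x[keep]
    half <- max(prof) / 2
    above <- range(x[prof >= half])
    diff(above)
  }
  f10 <- fwhm_of(10)
  f20 <- fwhm_of(20)
  expect_equal(f20 / f10, 2, tolerance = 0.1)
  expect_equal(f10, 10, tolerance = 1)
})

test_that("mutual information: identity, symmetry and independence", {
  cx <- make_toy_complex(2, 12, 4, seed = 7)
  m <- simulate_map(cx, 15)
  h <- mutual_information(m, m)
  # MI(X, X) equals the marginal entropy of the binned intensities
  v <- as.numeric(m$data)
  b <- pmin(pmax(floor((v - min(v)) / diff(range(v)) * 20) + 1, 1), 20)
  p <- tabulate(b, 20) / length(v)
  expect_equal(h, -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
  m2 <- simulate_map(xlscore:::.transform_chains(cx, "B",
                                                 trans = c(4, 2, 1)), 15)
  expect_equal(mutual_information(m, m2), mutual_information(m2, m),
               tolerance = 1e-12)
  # independent random maps carry (almost) no information
  set.seed(3)
  ra <- density_map(array(runif(40^3), c(40, 40, 40)), c(0, 0, 0), 1)
  rb <- density_map(array(runif(40^3), c(40, 40, 40)), c(0, 0, 0), 1)
  expect_lt(mutual_information(ra, rb), 0.05)
  expect_warning(
    mi0 <- mutual_information(
      density_map(array(1, c(5, 5, 5)), c(0, 0, 0), 1), ra),
    "constant")
  expect_equal(mi0, 0)
})

test_that("clash penalty is zero for the native and maximal when superposed", {
  cx <- make_toy_complex(2, 16, 6, seed = 5, identical_subunits = TRUE)
  expect_equal(clash_penalty(cx), 0)
  ctr <- function(ch) colMeans(cx$atoms[cx$atoms$chain == ch,
                                        c("x", "y", "z")])
  toward_a <- ctr("A") - ctr("B")
  # slide the identical copy exactly onto chain A: every atom clashes
  sup <- xlscore:::.transform_chains(cx, "B", trans = toward_a)
  expect_equal(clash_penalty(sup, scale = 2), 2)
  # monotone non-decreasing as subunits interpenetrate
  u <- toward_a / sqrt(sum(toward_a^2))
  pen <- vapply(seq(0, 12, by = 2), function(shift) {
    m <- xlscore:::.transform_chains(cx, "B", trans = shift * u)
    clash_penalty(m)
  }, numeric(1))
  expect_true(all(diff(pen) >= -1e-12))
  expect_gt(pen[length(pen)], 0)
})

test_that("F is linear in MI with slope n and combined adds half the cMNXL", {
  cx <- make_toy_complex(2, 12, 4, seed = 7)
  target <- simulate_map(cx, 15)
  fs <- f_score(cx, target)
  expect_equal(fs$f, fs$n_subunits * fs$mi - fs$ps, tolerance = 1e-12)
  expect_equal(fs$n_subunits, 2)
  expect_equal(fs$ps, 0)
  expect_equal(combined_score(1, 2), 2)
  expect_equal(combined_score(fs, 0), fs$f)
  # unit sensitivity to the crosslink score is the crosslink weight
  expect_equal(combined_score(fs, 3) - combined_score(fs, 2), 0.5)
})

test_that("the self-map maximizes MI over perturbed models", {
  cx <- make_toy_complex(2, 14, 4, seed = 8)
  target <- simulate_map(cx, 15)
  mi_self <- f_score(cx, target)$mi
  set.seed(4)
  rec <- decoy_recipe(n_decoys = 1, rng_seed = 4)
  worse <- vapply(1:8, function(i) {
    m <- xlscore:::.perturb_complex(cx, rec)
    f_score(m, target)$mi
  }, numeric(1))
  expect_true(all(worse <= mi_self + 1e-9))
})

test_that("MRC maps round trip through disk", {
  cx <- make_toy_complex(2, 12, 4, seed = 7)
  m <- simulate_map(cx, 15)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  back <- read_mrc(f, resolution = 15)
  expect_equal(dim(back$data), dim(m$data))
  expect_equal(back$origin, m$origin, tolerance = 1e-5)
  expect_equal(back$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(as.numeric(back$data), as.numeric(m$data),
               tolerance = 1e-6)
})
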