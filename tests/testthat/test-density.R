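# Density synthesis, footprint masks, observed/calculated scaling, and
# CCP4/MRC map round trips.

one_carbon <- function(b = 20) {
  list(top = ligand_topology("C", matrix(integer(0), ncol = 2),
                             numeric(0)),
       conf = conformer(matrix(0, 1, 3), b_factors = b))
}

test_that("calc_density conserves electrons and peaks at the atom", {
  oc <- one_carbon()
  g <- calc_density(list(oc$conf), 1, oc$top, 1.0)
  expect_equal(sum(g$values) * prod(g$spacing), 6, tolerance = 0.01)
  peak <- arrayInd(which.max(g$values), dim(g$values))
  peak_xyz <- g$origin + (peak - 1) * g$spacing
  expect_true(all(abs(peak_xyz) <= g$spacing / 2 + 1e-9))

  ar <- fixture_ligands()[[3]]
  gl <- calc_density(list(ar$conformer_a), 1, ar$topology, 1.2)
  expect_equal(sum(gl$values) * prod(gl$spacing), 6 * 3 + 8,
               tolerance = 0.01)
})

test_that("calc_density is linear in the weights", {
  oc <- one_carbon()
  g1 <- calc_density(list(oc$conf), 1, oc$top, 1.0)
  gh <- calc_density(list(oc$conf), 0.5, oc$top, 1.0, grid = g1)
  expect_equal(gh$values, g1$values / 2, tolerance = 1e-12)

  ar <- fixture_ligands()[[3]]
  ga <- calc_density(list(ar$conformer_a), 1, ar$topology, 1.0)
  gb <- calc_density(list(ar$conformer_b), 1, ar$topology, 1.0,
                     grid = ga)
  gmix <- calc_density(list(ar$conformer_a, ar$conformer_b), c(0.3, 0.7),
                       ar$topology, 1.0, grid = ga)
  expect_equal(gmix$values, 0.3 * ga$values + 0.7 * gb$values,
               tolerance = 1e-10)
})

test_that("calc_density rejects invalid input", {
  oc <- one_carbon()
  expect_error(calc_density(list(), numeric(0), oc$top, 1.0), "empty")
  bad <- oc$conf
  expect_error(conformer(matrix(0, 1, 3), b_factors = -3), "B-factors")
  expect_error(calc_density(list(oc$conf), c(0.6, 0.6), oc$top, 1.0),
               "one weight")
  expect_error(calc_density(list(oc$conf, oc$conf), c(0.6, 0.6), oc$top,
                            1.0), "sum")
})

test_that("footprint_mask matches brute-force lattice enumeration", {
  oc <- one_carbon()
  g <- density_grid(array(0, c(21, 21, 21)), spacing = 0.5,
                    origin = c(-5, -5, -5), resolution = 1)
  m <- footprint_mask(list(oc$conf), g, radius = 1.5)
  # brute force: all lattice points within 1.5 A of the origin
  idx <- which(outer(outer((-10:10 * 0.5)^2, (-10:10 * 0.5)^2, `+`),
                     (-10:10 * 0.5)^2, `+`) <= 1.5^2)
  expect_identical(as.integer(m), sort(idx))
  # monotone in radius, empty for empty input
  m2 <- footprint_mask(list(oc$conf), g, radius = 2.0)
  expect_true(all(as.integer(m) %in% as.integer(m2)))
  expect_length(footprint_mask(list(), g, radius = 1.5), 0)
})

test_that("scale_calc_to_obs recovers least-squares scale", {
  oc <- one_carbon()
  calc <- calc_density(list(oc$conf), 1, oc$top, 1.0)
  mask <- footprint_mask(list(oc$conf), calc, 2.0)
  obs2 <- mcligand:::.grid_set_values(calc, calc$values * 2)
  expect_equal(scale_calc_to_obs(calc, obs2, mask), 2)
  expect_equal(scale_calc_to_obs(calc, calc, mask), 1)
  set.seed(9)
  noisy <- mcligand:::.grid_set_values(
    calc, calc$values * 3 + array(rnorm(length(calc$values), 0, 0.01),
                                  dim(calc$values)))
  s <- scale_calc_to_obs(calc, noisy, mask)
  # closed-form least-squares oracle on the masked voxels
  x <- calc$values[as.integer(mask)]
  y <- noisy$values[as.integer(mask)]
  expect_equal(s, sum(x * y) / sum(x * x))
  expect_equal(s, 3, tolerance = 0.01)
  # scaling never increases the masked residual
  expect_lte(sum((s * x - y)^2), sum((x - y)^2))
  zero <- mcligand:::.grid_set_values(calc, array(0, dim(calc$values)))
  expect_error(scale_calc_to_obs(zero, calc, mask), "zero")
})

test_that("RSCC of a model against its own map exceeds 0.99", {
  ar <- fixture_ligands()[[1]]
  g <- calc_density(list(ar$conformer_a, ar$conformer_b), c(0.5, 0.5),
                    ar$topology, 1.0)
  mask <- footprint_mask(list(ar$conformer_a, ar$conformer_b), g, 1.5)
  g2 <- calc_density(list(ar$conformer_a, ar$conformer_b), c(0.5, 0.5),
                     ar$topology, 1.0, grid = g)
  expect_gt(rscc(g, g2, mask), 0.99)
})

test_that("CCP4 maps round-trip through write/read", {
  set.seed(4)
  g <- density_grid(array(rnorm(16^3), c(16, 16, 16)),
                    spacing = c(0.4, 0.5, 0.6),
                    origin = c(1.5, -2, 3), resolution = 1.3)
  f <- tempfile(fileext = ".ccp4")
  write_map(g, f)
  g2 <- read_map(f, resolution = 1.3)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)
})

test_that("axis-permuted CCP4 files are canonicalized on read", {
  set.seed(5)
  vals <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  g <- density_grid(vals, spacing = c(0.5, 0.6, 0.7),
                    origin = c(0, 0, 0))
  # write a file with column axis = y, row axis = x (MAPC=2, MAPR=1)
  f <- tempfile(fileext = ".ccp4")
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  perm_vals <- aperm(vals, c(2, 1, 3))   # file order: y, x, z
  d <- dim(perm_vals)
  wi(d); wi(2); wi(c(0, 0, 0)); wi(d)
  wf(d * c(0.6, 0.5, 0.7)); wf(c(90, 90, 90))
  wi(c(2, 1, 3))
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1); wi(0); wi(rep(0, 25)); wf(c(0, 0, 0))
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)
  wf(sd(vals)); wi(0); writeBin(raw(800), con)
  wf(as.numeric(perm_vals))
  close(con)
  g2 <- read_map(f)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
})

test_that("malformed map files raise errors", {
  f <- tempfile(fileext = ".ccp4")
  writeBin(raw(100), f)
  expect_error(read_map(f), "truncated")
  g <- density_grid(array(0, c(4, 4, 4)), 0.5)
  f2 <- tempfile(fileext = ".ccp4")
  write_map(g, f2)
  raw_all <- readBin(f2, "raw", file.size(f2))
  raw_all[209:212] <- as.raw(0)  # clobber the MAP stamp
  writeBin(raw_all, f2)
  expect_error(read_map(f2), "MAP stamp")
})
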