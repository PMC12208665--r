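# RSCC, EDIA/EDIAm and RMSD metrics.

test_that("rscc behaves as a Pearson correlation on the mask", {
  ar <- fixture_ligands()[[1]]
  g <- calc_density(list(ar$conformer_a), 1, ar$topology, 1.0)
  mask <- footprint_mask(list(ar$conformer_a), g, 1.5)
  expect_equal(rscc(g, g, mask), 1.0)
  aff <- mcligand:::.grid_set_values(g, 2.5 * g$values + 7)
  expect_equal(rscc(g, aff, mask), 1.0)
  neg <- mcligand:::.grid_set_values(g, -g$values)
  expect_equal(rscc(g, neg, mask), -1.0)
  # symmetric, and invariant under rescaling either argument
  set.seed(2)
  noisy <- mcligand:::.grid_set_values(
    g, g$values + array(rnorm(length(g$values), 0, g$sigma),
                        dim(g$values)))
  expect_equal(rscc(g, noisy, mask), rscc(noisy, g, mask))
  expect_equal(rscc(g, noisy, mask),
               rscc(mcligand:::.grid_set_values(g, 3 * g$values + 1),
                    noisy, mask))
  flat <- mcligand:::.grid_set_values(g, array(1, dim(g$values)))
  expect_error(rscc(g, flat, mask), "variance")
})

test_that("edia_z truncates at zeta and floors at zero", {
  g <- density_grid(array(c(-1, 1), c(2, 2, 2)), spacing = 0.5)
  expect_equal(g$mu, 0)
  expect_equal(g$sigma, 1)
  expect_equal(edia_z(10, g$mu, g$sigma), 1.2)
  expect_equal(edia_z(-2, g$mu, g$sigma), 0)
  expect_equal(edia_z(0.7, g$mu, g$sigma), 0.7)
  expect_equal(edia_z(1.2, g$mu, g$sigma), 1.2)
  expect_equal(edia_z(c(-5, 0.3, 99), 0, 1), c(0, 0.3, 1.2))
  expect_error(edia_z(1, 0, 0), "sigma")
})

test_that("an isolated atom in its own map is well supported", {
  top1 <- ligand_topology("C", matrix(integer(0), ncol = 2), numeric(0))
  cf <- conformer(matrix(0, 1, 3), b_factors = 20)
  g <- calc_density(list(cf), 1, top1, 1.0)
  e <- edia_atom(c(0, 0, 0), "C", g, b_factor = 20)
  expect_gte(e, 0.8)
  expect_error(edia_atom(c(50, 50, 50), "C", g), "outside")
})

test_that("EDIA is invariant under joint translation of atom and map", {
  top1 <- ligand_topology("C", matrix(integer(0), ncol = 2), numeric(0))
  cf <- conformer(matrix(0, 1, 3), b_factors = 18)
  g0 <- calc_density(list(cf), 1, top1, 1.0)
  shift <- c(1.0, -0.5, 0.25)
  cf2 <- conformer(matrix(shift, 1, 3), b_factors = 18)
  g2 <- calc_density(list(cf2), 1, top1, 1.0,
                     grid = density_grid(array(0, dim(g0$values)),
                                         g0$spacing, g0$origin + shift,
                                         1.0))
  e0 <- edia_atom(c(0, 0, 0), "C", g0, b_factor = 18)
  e2 <- edia_atom(shift, "C", g2, b_factor = 18)
  expect_equal(e0, e2, tolerance = 1e-3)
})

test_that("EDIAm combines per-atom scores monotonically", {
  ar <- fixture_ligands()[[3]]
  top <- ar$topology
  g <- calc_density(list(ar$conformer_a), 1, top, 1.0)
  ed <- ediam(list(ar$conformer_a), top, g)
  expect_true(is.finite(ed$ediam))
  expect_equal(dim(ed$per_atom), c(1, 4))
  # one-atom model: EDIAm equals that atom's EDIA (both combiners)
  top1 <- ligand_topology("C", matrix(integer(0), ncol = 2), numeric(0))
  cf <- conformer(matrix(0, 1, 3), b_factors = 20)
  g1 <- calc_density(list(cf), 1, top1, 1.0)
  e1 <- ediam(list(cf), top1, g1)
  expect_equal(e1$ediam, as.numeric(e1$per_atom))
  em <- ediam(list(cf), top1, g1, combine = "mean")
  expect_equal(em$ediam, as.numeric(em$per_atom))
  expect_error(ediam(list(), top, g), "empty")
  # resolution beyond 2 A warns but computes
  g_lr <- calc_density(list(ar$conformer_a), 1, top, 2.4)
  expect_warning(ediam(list(ar$conformer_a), top, g_lr), "2 A")
})

test_that("a complete model outscores one with a conformer wiped from the map", {
  ar <- fixture_ligands()[[3]]
  top <- ar$topology
  both <- calc_density(list(ar$conformer_a, ar$conformer_b), c(0.5, 0.5),
                       top, 1.0)
  a_only <- calc_density(list(ar$conformer_a), 0.5, top, 1.0, grid = both)
  model <- list(ar$conformer_a, ar$conformer_b)
  expect_gt(ediam(model, top, both)$ediam,
            ediam(model, top, a_only)$ediam)
})

test_that("rmsd matches a brute-force loop and is a metric", {
  set.seed(6)
  a <- conformer(matrix(rnorm(30), 10, 3))
  b <- conformer(matrix(rnorm(30), 10, 3))
  brute <- sqrt(sum(sapply(1:10, function(i)
    sum((a$xyz[i, ] - b$xyz[i, ])^2))) / 10)
  expect_equal(rmsd(a, b), brute)
  expect_equal(rmsd(a, a), 0)
  shift <- conformer(a$xyz + rep(c(1, 0, 0), each = 10))
  expect_equal(rmsd(a, shift), 1.0)
  expect_error(rmsd(a, conformer(matrix(0, 4, 3))), "mismatch")
  # symmetry + triangle inequality over random triples
  for (i in 1:20) {
    x <- conformer(matrix(rnorm(15), 5, 3))
    y <- conformer(matrix(rnorm(15), 5, 3))
    z <- conformer(matrix(rnorm(15), 5, 3))
    expect_equal(rmsd(x, y), rmsd(y, x))
    expect_lte(rmsd(x, z), rmsd(x, y) + rmsd(y, z) + 1e-12)
  }
})

test_that("closest_conformer_rmsd takes the minimum over the model", {
  ar <- fixture_ligands()[[3]]
  ref <- ar$conformer_a
  shift <- function(d) conformer(ref$xyz + rep(c(d, 0, 0), each = 4))
  model <- list(shift(0.4), shift(1.0), shift(2.0))
  expect_equal(closest_conformer_rmsd(model, ref), 0.4)
  expect_equal(closest_conformer_rmsd(c(model, list(ref)), ref), 0)
  expect_equal(closest_conformer_rmsd(list(shift(0.7)), ref),
               rmsd(shift(0.7), ref))
  expect_error(closest_conformer_rmsd(list(), ref), "empty")
})

test_that("validation reports serialize to JSON and TSV", {
  ar <- fixture_ligands()[[3]]
  g <- calc_density(list(ar$conformer_a), 1, ar$topology, 1.0)
  mask <- footprint_mask(list(ar$conformer_a), g, 1.5)
  rep <- validation_report(list(ar$conformer_a), ar$topology, g, mask,
                           1.0, reference = ar$conformer_b)
  expect_s3_class(rep, "validation_report")
  expect_gt(rep$rscc, 0.99)
  expect_equal(rep$rmsd_to_reference, rmsd(ar$conformer_a,
                                           ar$conformer_b))
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  write_report(rep, jf, tf, atom_names = ar$topology$atom_names)
  back <- jsonlite::read_json(jf)
  expect_equal(back$rscc, rep$rscc, tolerance = 1e-9)
  tab <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("conformer", "atom", "edia"))
})
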