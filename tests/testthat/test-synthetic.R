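# Synthetic benchmark: archetypes, truth-map simulation, and the
# benchmark emitter.

test_that("the four archetypes cover the intended disorder classes", {
  ars <- fixture_ligands()
  expect_length(ars, 4)
  ids <- vapply(ars, `[[`, character(1), "id")
  expect_setequal(ids, c("ring_flip", "linear", "torsion_shift",
                         "macrocycle"))
  mac <- ars[[which(ids == "macrocycle")]]
  expect_true(mac$topology$is_macrocycle)
  expect_gte(max(mac$topology$ring_sizes), 12)
  for (ar in ars) {
    expect_gte(rmsd(ar$conformer_a, ar$conformer_b), 0.5)
    expect_true(validate_connectivity(ar$conformer_a, ar$topology))
    expect_true(validate_connectivity(ar$conformer_b, ar$topology))
    expect_identical(nrow(ar$conformer_a$xyz),
                     nrow(ar$conformer_b$xyz))
  }
})

test_that("truth maps conserve occupancy-weighted electrons", {
  ar <- fixture_ligands()[[3]]
  case <- benchmark_case(ar, 0.7, 0.3, 1.0, noise_alpha = 0)
  m <- build_truth_map(case)
  za <- sum(mcligand:::.element_z(ar$topology$elements))
  total <- sum(m$values) * prod(m$spacing)
  # q_a * Z + q_b * Z = Z for a shared topology
  expect_equal(total, za, tolerance = 0.01)
  # against separately integrated single-conformer maps
  ma <- build_truth_map(benchmark_case(ar, 1, 0, 1.0, noise_alpha = 0))
  mb <- build_truth_map(benchmark_case(ar, 0, 1, 1.0, noise_alpha = 0))
  expect_equal(total,
               0.7 * sum(ma$values) * prod(ma$spacing) +
                 0.3 * sum(mb$values) * prod(mb$spacing),
               tolerance = 1e-6)
})

test_that("zero-noise single-conformer cases equal plain calc_density", {
  ar <- fixture_ligands()[[1]]
  case <- benchmark_case(ar, 1, 0, 1.5, noise_alpha = 0)
  m <- build_truth_map(case)
  ca <- ar$conformer_a
  ca$b_factors <- rep(mcligand:::.benchmark_b_factor(1.5),
                      length(ca$b_factors))
  ref <- calc_density(list(ca), 1, ar$topology, 1.5, grid = m)
  expect_equal(m$values, ref$values)
})

test_that("noise scales linearly with resolution", {
  ar <- fixture_ligands()[[3]]
  noise_sd <- function(res) {
    clean <- build_truth_map(benchmark_case(ar, 0.5, 0.5, res,
                                            noise_alpha = 0))
    noisy <- build_truth_map(benchmark_case(ar, 0.5, 0.5, res,
                                            noise_seed = 42))
    sd(noisy$values - clean$values) / clean$sigma
  }
  expect_equal(noise_sd(2.4) / noise_sd(0.8), 3, tolerance = 0.05)
})

test_that("truth maps stay close to their noiseless model at 1 A", {
  ar <- fixture_ligands()[[2]]
  noisy <- build_truth_map(benchmark_case(ar, 0.5, 0.5, 1.0,
                                          noise_seed = 17))
  clean <- build_truth_map(benchmark_case(ar, 0.5, 0.5, 1.0,
                                          noise_alpha = 0))
  mask <- footprint_mask(list(ar$conformer_a, ar$conformer_b), clean,
                         1.5)
  expect_gte(rscc(noisy, clean, mask), 0.95)
})

test_that("truth maps are reproducible for a fixed seed", {
  ar <- fixture_ligands()[[1]]
  m1 <- build_truth_map(benchmark_case(ar, 0.6, 0.4, 1.2,
                                       noise_seed = 99))
  m2 <- build_truth_map(benchmark_case(ar, 0.6, 0.4, 1.2,
                                       noise_seed = 99))
  expect_identical(m1$values, m2$values)
  m3 <- build_truth_map(benchmark_case(ar, 0.6, 0.4, 1.2,
                                       noise_seed = 100))
  expect_false(identical(m3$values, m1$values))
})

test_that("a reduced benchmark emits a complete, reloadable grid", {
  outdir <- file.path(tempdir(), "bench_small")
  on.exit(unlink(outdir, recursive = TRUE))
  man <- generate_benchmark(outdir,
                            archetypes = fixture_ligands()[3],
                            splits = c(0.5, 0.8),
                            resolutions = c(1.0, 2.0),
                            seed = 7)
  expect_equal(nrow(man), 1 * 2 * 2)
  expect_true(all(file.exists(file.path(outdir, man$map_file))))
  expect_true(all(file.exists(file.path(outdir, man$truth_file))))
  expect_true(all(file.exists(file.path(outdir, man$input_file))))
  # every (split, resolution) cell appears exactly once
  expect_equal(nrow(unique(man[, c("q_a", "resolution")])), 4)
  # truth model reloads as a two-conformer ligand with the stated split
  tr <- mcligand:::.read_ligand_pdb(file.path(outdir, man$truth_file[1]))
  expect_length(tr, 2)
  expect_equal(sort(vapply(tr, `[[`, numeric(1), "occupancy")),
               sort(c(man$q_a[1], man$q_b[1])))
  # input model is single-conformer at occupancy 1
  ip <- mcligand:::.read_ligand_pdb(file.path(outdir, man$input_file[1]))
  expect_length(ip, 1)
  expect_equal(ip[[1]]$occupancy, 1)
  # map reload matches regeneration; rerun is byte-identical
  g <- read_map(file.path(outdir, man$map_file[1]), man$resolution[1])
  ar <- fixture_ligands()[[3]]
  ref <- build_truth_map(benchmark_case(ar, man$q_a[1], man$q_b[1],
                                        man$resolution[1],
                                        noise_seed = man$noise_seed[1]))
  expect_equal(g$values, ref$values, tolerance = 1e-5)
  f1 <- file.path(outdir, man$map_file[1])
  md5_a <- tools::md5sum(f1)
  generate_benchmark(outdir, archetypes = fixture_ligands()[3],
                     splits = c(0.5, 0.8), resolutions = c(1.0, 2.0),
                     seed = 7)
  expect_identical(tools::md5sum(f1), md5_a)
})
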