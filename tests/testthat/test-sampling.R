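# Sampling plans, strategy constraint contracts, flip sampling and
# RMSD deduplication.

test_that("budgets follow the heavy-atom-count rule", {
  top20 <- ligand_topology(rep("C", 20), cbind(1:19, 2:20))
  top30 <- ligand_topology(rep("C", 30), cbind(1:29, 2:30))
  p20 <- build_plan(top20, seed = 1)
  p30 <- build_plan(top30, seed = 1)
  expect_identical(p20$n, 5000L)
  expect_identical(p30$n, 7000L)
  expect_identical(sum(p20$allocation), 5000L)
  expect_identical(sum(p30$allocation), 7000L)
  # 24 heavy atoms is still "fewer than 25"
  top24 <- ligand_topology(rep("C", 24), cbind(1:23, 2:24))
  expect_identical(build_plan(top24, seed = 1)$n, 5000L)
  # benzene: exactly the three preliminary strategies -> even 4/4/4 split
  ring <- ligand_topology(rep("C", 6), rbind(cbind(1:5, 2:6), c(6, 1)))
  expect_identical(build_plan(ring, n_override = 12, seed = 1)$allocation,
                   c(unconstrained = 4L, fixed_terminal = 4L, blob = 4L))
  # remainder goes to the unconstrained search
  expect_identical(build_plan(ring, n_override = 11, seed = 1)$allocation,
                   c(unconstrained = 5L, fixed_terminal = 3L, blob = 3L))
  expect_error(build_plan(top20, n_override = 0), "positive")
})

test_that("strategy activation follows the topology flags", {
  # a linear 20-mer has a >= 4-atom branch off its graph center
  top <- ligand_topology(rep("C", 20), cbind(1:19, 2:20))
  expect_setequal(build_plan(top, seed = 1)$strategies,
                  c("unconstrained", "fixed_terminal", "blob", "branch"))
  ring <- ligand_topology(rep("C", 6), rbind(cbind(1:5, 2:6), c(6, 1)))
  expect_setequal(build_plan(ring, seed = 1)$strategies,
                  c("unconstrained", "fixed_terminal", "blob"))
  expect_true("flip" %in% build_plan(ring, flip = TRUE, seed = 1)$strategies)
})

test_that("strategy constraints hold for every emitted conformer", {
  ar <- fixture_ligands()[[2]]  # octane: has a 4-atom branch
  top <- ar$topology
  seed_conf <- ar$conformer_a
  plan <- build_plan(top, n_override = 480, seed = 19)
  pool <- sample_conformers(plan, top, seed_conf)
  src <- vapply(pool, `[[`, character(1), "source")
  expect_gte(sum(src == "blob"), 100)
  expect_gte(sum(src == "fixed_terminal"), 100)
  expect_gte(sum(src == "branch"), 100)

  centroid0 <- colMeans(seed_conf$xyz)
  R <- sqrt(max(rowSums(sweep(seed_conf$xyz, 2, centroid0)^2)))
  terms <- mcligand:::.terminal_atoms(top)
  tp <- t(combn(terms, 2))
  d0 <- sqrt(rowSums((seed_conf$xyz[tp[, 1], , drop = FALSE] -
                      seed_conf$xyz[tp[, 2], , drop = FALSE])^2))
  branch_members <- unlist(lapply(top$side_chains, function(sc)
    if (sc$size >= 4) sc$members))
  core <- setdiff(seq_len(top$heavy_atom_count), branch_members)

  for (cf in pool) {
    if (cf$source == "blob") {
      r <- sqrt(rowSums(sweep(cf$xyz, 2, centroid0)^2))
      expect_true(all(r <= R + 1e-6))
    } else if (cf$source == "fixed_terminal") {
      d <- sqrt(rowSums((cf$xyz[tp[, 1], , drop = FALSE] -
                         cf$xyz[tp[, 2], , drop = FALSE])^2))
      expect_true(all(abs(d - d0) <= 0.1 + 1e-9))
    } else if (cf$source == "branch") {
      expect_true(all(abs(cf$xyz[core, ] - seed_conf$xyz[core, ]) <=
                        0.1))
    }
  }
})

test_that("long-chain search fixes the chain and moves the core", {
  # benzene ring with a 32-atom tail: long_chain active
  n <- 38
  bonds <- rbind(cbind(1:5, 2:6), c(6, 1), c(1, 7),
                 cbind(7:(n - 1), 8:n))
  top <- ligand_topology(rep("C", n), bonds)
  expect_true(classify_topology(top)[["long_chain_search"]])
  th <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  chain <- mcligand:::.zigzag_chain(n - 6)
  chain <- sweep(chain, 2, c(1.39 + 1.5, 0, 0), `+`)
  seed_conf <- conformer(rbind(ring, chain))
  plan <- build_plan(top, n_override = 50, seed = 31)
  pool <- sample_conformers(plan, top, seed_conf)
  lc <- Filter(function(cf) cf$source == "long_chain", pool)
  expect_gt(length(lc), 0)
  long_members <- unlist(lapply(top$side_chains, function(sc)
    if (sc$size > 30) sc$members))
  for (cf in lc)
    expect_true(all(abs(cf$xyz[long_members, ] -
                          seed_conf$xyz[long_members, ]) <= 0.1))
})

test_that("sampling is deterministic under a fixed seed", {
  ar <- fixture_ligands()[[3]]
  plan <- build_plan(ar$topology, n_override = 60, seed = 5)
  p1 <- sample_conformers(plan, ar$topology, ar$conformer_a)
  p2 <- sample_conformers(plan, ar$topology, ar$conformer_a)
  expect_identical(lapply(p1, `[[`, "xyz"), lapply(p2, `[[`, "xyz"))
  # and independent of the worker count
  p5 <- sample_conformers(plan, ar$topology, ar$conformer_a, cores = 5)
  expect_identical(lapply(p1, `[[`, "xyz"), lapply(p5, `[[`, "xyz"))
})

test_that("flip sampling emits 3 base flips plus fine rotations", {
  ar <- fixture_ligands()[[2]]
  fl <- flip_sample(ar$conformer_a)
  expect_length(fl, 33)
  src <- vapply(fl, `[[`, character(1), "source")
  expect_identical(sum(src == "flip_base"), 3L)
  ctr <- colMeans(ar$conformer_a$xyz)
  for (cf in fl)
    expect_equal(colMeans(cf$xyz), ctr, tolerance = 1e-6)
})

test_that("a 180-degree flip is an involution", {
  ar <- fixture_ligands()[[2]]
  xyz <- ar$conformer_a$xyz
  ctr <- colMeans(xyz)
  axes <- eigen(crossprod(sweep(xyz, 2, ctr)), symmetric = TRUE)$vectors
  for (ax in 1:3) {
    once <- mcligand:::.rotate_points(xyz, ctr, axes[, ax], 180)
    twice <- mcligand:::.rotate_points(once, ctr, axes[, ax], 180)
    expect_equal(twice, xyz, tolerance = 1e-6)
  }
  line <- conformer(cbind(0:4 * 1.5, 0, 0))
  expect_error(flip_sample(line), "collinear")
})

test_that("deduplication enforces the RMSD threshold", {
  base <- fixture_ligands()[[3]]$conformer_a
  shift <- function(d) conformer(base$xyz + rep(c(d, 0, 0),
                                                each = nrow(base$xyz)))
  # identical pair: one survives
  expect_length(deduplicate(list(base, base), seed = 1), 1)
  # 0.5 A apart: both survive; 0.1 A: one survives
  expect_length(deduplicate(list(base, shift(0.5)), seed = 1), 2)
  expect_length(deduplicate(list(base, shift(0.1)), seed = 1), 1)
})

test_that("deduplication is idempotent, seeded and pairwise-separated", {
  ar <- fixture_ligands()[[3]]
  plan <- build_plan(ar$topology, n_override = 150, seed = 13)
  pool <- sample_conformers(plan, ar$topology, ar$conformer_a)
  d1 <- deduplicate(pool, seed = 3)
  expect_lt(length(d1), length(pool))
  # no surviving pair below the threshold
  for (i in seq_along(d1))
    for (j in seq_len(i - 1))
      expect_gte(rmsd(d1[[i]], d1[[j]]), 0.2)
  # idempotent and deterministic
  expect_identical(lapply(deduplicate(d1, seed = 3), `[[`, "xyz"),
                   lapply(d1, `[[`, "xyz"))
  expect_identical(lapply(deduplicate(pool, seed = 3), `[[`, "xyz"),
                   lapply(d1, `[[`, "xyz"))
  # which member of an identical pair is dropped depends on the seed
  a <- ar$conformer_a
  a$source <- "copy1"
  b <- ar$conformer_a
  b$source <- "copy2"
  kept <- vapply(1:10, function(s)
    deduplicate(list(a, b), seed = s)[[1]]$source, character(1))
  expect_setequal(unique(kept), c("copy1", "copy2"))
})
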