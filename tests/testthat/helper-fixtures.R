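# Shared fixtures: all built programmatically at test time.

# a toy protein (3 atoms) + the archetype ligand as residue A,101
write_structure_fixture <- function(archetype, path,
                                    occ = 0.9, conf = "a") {
  lig <- if (conf == "a") archetype$conformer_a else archetype$conformer_b
  n <- nrow(lig$xyz)
  prot <- matrix(c(20, 20, 20, 21.5, 20, 20, 22, 21, 20), 3, 3,
                 byrow = TRUE)
  xyz <- rbind(prot, lig$xyz)
  suppressMessages(bio3d::write.pdb(
    file = path, xyz = as.vector(t(xyz)),
    type = c(rep("ATOM", 3), rep("HETATM", n)),
    resno = c(1, 1, 1, rep(101, n)),
    resid = c(rep("GLY", 3), rep("LIG", n)),
    eleno = seq_len(3 + n),
    elety = c("N", "CA", "C", archetype$topology$atom_names),
    chain = rep("A", 3 + n),
    o = c(1, 1, 1, rep(occ, n)), b = rep(20, 3 + n),
    elesy = c("N", "C", "C", archetype$topology$elements)))
  path
}

# random occupancy design matrices for solver tests (rows = candidate
# maps, obs = mixture of some rows + noise)
random_design <- function(n_cand, n_vox = 30, k_true = 2, noise = 0.05,
                          seed = 1) {
  set.seed(seed)
  A <- matrix(abs(rnorm(n_cand * n_vox)), n_cand, n_vox)
  truth <- sample(n_cand, min(k_true, n_cand))
  w <- rep(0, n_cand)
  w[truth] <- diff(c(0, sort(runif(length(truth) - 1)), 1)) *
    runif(1, 0.6, 1)
  b <- as.numeric(crossprod(A, w)) + rnorm(n_vox, 0, noise)
  structure(list(maps = A, obs = b, gram = NULL),
            class = "occupancy_design")
}

# Independent MIQP oracle: enumerate all supports of size <= cardinality,
# screen each small box-and-sum QP by projected-gradient iteration (plain
# R, vectorized across supports of equal size), then polish the leading
# supports exactly by trying the KKT equality systems of the nearby
# active-set hypotheses and keeping the best feasible one.
oracle_miqp <- function(design, cardinality = 3, t_min = 0.2,
                        iters = 220, top = 8) {
  A <- design$maps
  b <- design$obs
  n <- nrow(A)
  G <- tcrossprod(A)
  c0 <- as.numeric(A %*% b)
  bsq <- sum(b^2)
  cand <- list()
  for (k in seq_len(min(cardinality, n))) {
    if (k * t_min > 1 + 1e-12) break
    if (k == 1) {
      # closed form: clamp the unconstrained optimum to [t_min, 1]
      w1 <- pmin(pmax(c0 / pmax(diag(G), 1e-300), t_min), 1)
      obj1 <- w1^2 * diag(G) - 2 * c0 * w1 + bsq
      for (idx in order(obj1)[seq_len(min(top, n))])
        cand <- c(cand, list(list(sel = idx, w = w1[idx],
                                  obj = obj1[idx])))
      next
    }
    subs <- utils::combn(n, k)
    m <- ncol(subs)
    Gk <- array(0, c(m, k, k))
    Ck <- matrix(0, m, k)
    for (i in seq_len(k)) {
      Ck[, i] <- c0[subs[i, ]]
      for (j in seq_len(k))
        Gk[, i, j] <- G[cbind(subs[i, ], subs[j, ])]
    }
    L <- 2 * apply(Gk, 1, function(g) sum(abs(g)))  # row-sum bound
    step <- 1 / pmax(L, 1e-12)
    proj <- function(W) {
      W <- pmin(pmax(W, t_min), 1)
      s <- rowSums(W)
      over <- which(s > 1 + 1e-14)
      if (length(over)) {
        lo <- rep(0, length(over)); hi <- rep(1, length(over))
        V <- W[over, , drop = FALSE]
        for (it in 1:40) {
          tau <- (lo + hi) / 2
          hi_mask <- rowSums(pmin(pmax(V - tau, t_min), 1)) > 1
          lo[hi_mask] <- tau[hi_mask]
          hi[!hi_mask] <- tau[!hi_mask]
        }
        W[over, ] <- pmin(pmax(V - (lo + hi) / 2, t_min), 1)
      }
      W
    }
    W <- proj(matrix(1 / k, m, k))
    for (it in seq_len(iters)) {
      grad <- matrix(0, m, k)
      for (i in seq_len(k))
        for (j in seq_len(k))
          grad[, i] <- grad[, i] + 2 * Gk[, i, j] * W[, j]
      grad <- grad - 2 * Ck
      W <- proj(W - step * grad)
    }
    obj <- numeric(m)
    for (i in seq_len(k)) {
      acc <- numeric(m)
      for (j in seq_len(k)) acc <- acc + Gk[, i, j] * W[, j]
      obj <- obj + W[, i] * acc - 2 * Ck[, i] * W[, i]
    }
    for (idx in order(obj)[seq_len(min(top, m))])
      cand <- c(cand, list(list(sel = subs[, idx], w = W[idx, ],
                                obj = obj[idx] + bsq)))
  }
  best <- list(obj = bsq, sel = integer(0), w = numeric(0))
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "obj"))]
  for (cd in head(cand, top)) {
    sel <- cd$sel
    Gs <- G[sel, sel, drop = FALSE]
    w <- .oracle_polish(Gs, c0[sel], cd$w, t_min)
    objp <- sum(w * (Gs %*% w)) - 2 * sum(c0[sel] * w) + bsq
    if (objp < best$obj - 1e-12) best <- list(obj = objp, sel = sel,
                                              w = w)
  }
  wfull <- rep(0, n)
  wfull[best$sel] <- best$w
  list(weights = wfull, selected = best$sel, objective = best$obj)
}

# exact KKT polish: from a near-optimal point, try the equality systems of
# the implied active set with the sum constraint both on and off (and, on
# failure, loosened bound detection), keeping the best feasible solution
.oracle_polish <- function(G, c0, w, t_min, tol = 5e-3) {
  k <- length(w)
  obj <- function(x) sum(x * (G %*% x)) - 2 * sum(c0 * x)
  feasible <- function(x) !is.null(x) &&
    all(x >= t_min - 1e-9) && all(x <= 1 + 1e-9) && sum(x) <= 1 + 1e-9
  try_one <- function(at_lo, at_hi, sum_on) {
    wfix <- ifelse(at_lo, t_min, ifelse(at_hi, 1, NA))
    free <- which(is.na(wfix))
    out <- wfix
    if (length(free) == 0) {
      if (sum_on && abs(sum(wfix) - 1) > 1e-9) return(NULL)
      return(wfix)
    }
    fixed <- setdiff(seq_len(k), free)
    cross <- if (length(fixed))
      as.numeric(G[free, fixed, drop = FALSE] %*% wfix[fixed]) else 0
    if (sum_on) {
      Amat <- rbind(cbind(2 * G[free, free, drop = FALSE], 1),
                    c(rep(1, length(free)), 0))
      rhs <- c(2 * c0[free] - 2 * cross,
               1 - sum(wfix[fixed]))
      sol <- tryCatch(solve(Amat, rhs), error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      out[free] <- sol[seq_along(free)]
    } else {
      sol <- tryCatch(solve(G[free, free, drop = FALSE],
                            c0[free] - cross), error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      out[free] <- sol
    }
    out
  }
  # bounds the iterate sits exactly on are certain; bounds it merely
  # approaches are marginal and tried both pinned and free
  lo_marg <- which(w > t_min + 1e-9 & w <= t_min + tol)
  hi_marg <- which(w < 1 - 1e-9 & w >= 1 - tol)
  marg <- c(lo_marg, hi_marg)
  base_lo <- w <= t_min + 1e-9
  base_hi <- w >= 1 - 1e-9
  combos <- if (length(marg) == 0) list(logical(0)) else
    asplit(as.matrix(expand.grid(rep(list(c(FALSE, TRUE)),
                                     min(length(marg), 6)))), 1)
  cands <- list()
  for (cb in combos) {
    at_lo <- base_lo
    at_hi <- base_hi
    if (length(marg)) {
      pin <- marg[which(as.logical(cb))]
      at_lo[intersect(pin, lo_marg)] <- TRUE
      at_hi[intersect(pin, hi_marg)] <- TRUE
    }
    cands <- c(cands, list(try_one(at_lo, at_hi, sum_on = TRUE),
                           try_one(at_lo, at_hi, sum_on = FALSE)))
  }
  cands <- c(cands,
             list(try_one(rep(FALSE, k), rep(FALSE, k), sum_on = FALSE),
                  try_one(rep(FALSE, k), rep(FALSE, k), sum_on = TRUE)))
  cands <- Filter(feasible, cands)
  if (length(cands) == 0) return(w)
  cands[[which.min(vapply(cands, obj, numeric(1)))]]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# sum of fitted occupancy assigned to each of two truth conformers, by
# nearest-RMSD assignment (recovery bookkeeping for the benchmark tests)
recovered_split <- function(fit, conf_a, conf_b) {
  qa <- 0; qb <- 0
  for (cf in fit$conformers) {
    if (rmsd(cf, conf_a) <= rmsd(cf, conf_b)) qa <- qa + cf$occupancy
    else qb <- qb + cf$occupancy
  }
  c(a = qa, b = qb)
}
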