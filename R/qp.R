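# Occupancy estimation: convex QP over the simplex-with-slack for weight
# estimation and screening, and exact cardinality-constrained MIQP (subset
# enumeration + closed-form small QP) for final model selection.
#
# Both minimize rss(w) = ||rho_calc' w - rho_obs||^2 over masked voxels,
# written as w' G w - 2 c' w + |rho_obs|^2 with G = M M', c = M rho_obs.

#' Build an occupancy design matrix
#'
#' Restricts each candidate conformer's calculated density and the observed
#' density to the footprint mask, the common ground on which occupancy
#' weights are fit.
#'
#' @param conformers candidate [conformer()] list.
#' @param topology shared [ligand_topology()].
#' @param obs observed [density_grid()].
#' @param mask [footprint_mask()] on `obs`.
#' @param resolution nominal resolution (Angstrom).
#' @param scale optional scale applied to the calculated rows so observed
#'   and calculated densities are on a common scale (see
#'   [scale_calc_to_obs()]); default 1.
#' @return object of class `occupancy_design`: list with `maps` (candidate
#'   rows x masked voxels), `obs` (masked observed vector), `gram`.
#' @export
occupancy_design <- function(conformers, topology, obs, mask, resolution,
                             scale = 1) {
  if (length(conformers) == 0) stop("no candidate conformers")
  M <- .density_rows(conformers, topology, obs, mask, resolution) * scale
  y <- as.numeric(obs$values[as.integer(mask)])
  structure(list(maps = M, obs = y, gram = NULL),
            class = "occupancy_design")
}

.design_gram <- function(design) {
  if (is.null(design$gram)) design$gram <- tcrossprod(design$maps)
  design
}

# Euclidean projection onto {w >= lower, sum(w) <= cap}. With lower = 0 and
# cap = 1 this is the simplex-with-slack projection (sort-based).
.project_capped <- function(v, cap = 1, lower = 0) {
  w <- pmax(v, lower)
  if (sum(w) <= cap) return(w)
  # find tau with sum(pmax(v - tau, lower)) = cap by sorting breakpoints
  u <- sort(v - lower, decreasing = TRUE)
  css <- cumsum(u)
  k <- seq_along(u)
  rho <- max(which(u - (css - (cap - length(v) * lower)) / k > 0))
  tau <- (css[rho] - (cap - length(v) * lower)) / rho
  pmax(v - tau, lower)
}

# KKT residual for min w'Gw - 2c'w s.t. w >= 0, sum(w) <= cap.
.qp_kkt_residual <- function(w, G, c0, cap = 1) {
  g <- 2 * (as.numeric(G %*% w) - c0)
  on <- w > 1e-10
  lambda <- if (sum(w) >= cap - 1e-10) max(0, max(-g[on], -Inf)) else 0
  r_stat <- if (any(on)) max(abs(g[on] + lambda)) else 0
  r_dual <- max(0, -(min(g + lambda)))
  r_comp <- lambda * max(0, cap - sum(w))
  max(r_stat, r_dual, r_comp)
}

# Solve min w'Gw - 2c'w s.t. w >= 0, sum(w) <= cap: a short FISTA warm
# start identifies a near-optimal face, then an exact primal active-set
# refinement (direct KKT solves, one support change per round) drives the
# KKT residual to solver precision. Scale-invariant stopping: residual
# below tol * max(1, max|c|).
.qp_solve_core <- function(G, c0, cap = 1, tol = 1e-8,
                           warm_iter = 1000L) {
  n <- length(c0)
  if (n == 1) {
    w <- min(cap, max(0, c0 / max(G[1, 1], 1e-300)))
    return(list(w = w, status = "optimal"))
  }
  scale <- max(1, max(abs(c0)))
  L <- 2 * .spectral_norm(G)
  if (L <= 0) return(list(w = rep(0, n), status = "optimal"))
  step <- 1 / L
  w <- rep(0, n); yv <- w; tk <- 1
  for (it in seq_len(warm_iter)) {
    grad <- 2 * (as.numeric(G %*% yv) - c0)
    w_new <- .project_capped(yv - step * grad, cap)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- w_new + ((tk - 1) / t_new) * (w_new - w)
    if (sum((w_new - w) * grad) > 0) { yv <- w_new; t_new <- 1 }
    w <- w_new; tk <- t_new
    if (it %% 100 == 0 && .qp_kkt_residual(w, G, c0, cap) < tol * scale)
      return(list(w = w, status = "optimal"))
  }
  res <- .qp_active_set(G, c0, cap, tol * scale,
                        S0 = which(w > 1e-6),
                        sum0 = sum(w) >= cap - 1e-6)
  if (!is.null(res)) return(res)
  # degenerate face: fall back to long projected-gradient iteration
  for (it in seq_len(100000L)) {
    grad <- 2 * (as.numeric(G %*% yv) - c0)
    w_new <- .project_capped(yv - step * grad, cap)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- w_new + ((tk - 1) / t_new) * (w_new - w)
    if (sum((w_new - w) * grad) > 0) { yv <- w_new; t_new <- 1 }
    w <- w_new; tk <- t_new
    if (it %% 200 == 0 && .qp_kkt_residual(w, G, c0, cap) < tol * scale)
      return(list(w = w, status = "optimal"))
  }
  list(w = w, status = "max_iter")
}

.spectral_norm <- function(G) {
  n <- nrow(G)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (i in 1:60) {
    v2 <- as.numeric(G %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) return(0)
    v <- v2 / nv
    lam <- nv
  }
  lam
}

# Primal active-set refinement: maintain a support S (w_i > 0) and a flag
# for the sum constraint; solve the equality-constrained KKT system on S
# exactly, then move one violated constraint per round. Returns NULL on
# cycling/singularity (caller falls back to the warm-start iterate).
.qp_active_set <- function(G, c0, cap, abstol, S0 = integer(0),
                           sum0 = FALSE, max_rounds = 400L) {
  n <- length(c0)
  S <- sort(S0)
  if (length(S) == 0) S <- which.max(c0)
  sum_active <- sum0
  for (round in seq_len(max_rounds)) {
    k <- length(S)
    sol <- tryCatch({
      if (sum_active) {
        A <- rbind(cbind(2 * G[S, S, drop = FALSE], 1), c(rep(1, k), 0))
        solve(A, c(2 * c0[S], cap))
      } else {
        c(solve(G[S, S, drop = FALSE], c0[S]), 0)
      }
    }, error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    wS <- sol[seq_len(k)]
    lambda <- sol[k + 1]
    if (any(wS < -1e-12)) {            # drop the most negative weight
      S <- setdiff(S, S[which.min(wS)])
      if (length(S) == 0) {
        sum_active <- FALSE
        w <- rep(0, n)
        g <- -2 * c0
        viol <- which(g < -abstol)
        if (length(viol) == 0) return(list(w = w, status = "optimal"))
        S <- viol[which.min(g[viol])]
      }
      next
    }
    if (!sum_active && length(wS) && sum(wS) > cap + 1e-12) {
      sum_active <- TRUE
      next
    }
    if (sum_active && lambda < -1e-12) {
      sum_active <- FALSE
      next
    }
    w <- rep(0, n)
    if (length(S)) w[S] <- pmax(wS, 0)
    g <- 2 * (as.numeric(G %*% w) - c0) + lambda
    viol <- which(g < -abstol & w <= 0)
    if (length(viol) == 0) {
      if (.qp_kkt_residual(w, G, c0, cap) < abstol)
        return(list(w = w, status = "optimal"))
      return(NULL)
    }
    add <- viol[which.min(g[viol])]
    if (add %in% S) return(NULL)
    S <- sort(c(S, add))
  }
  NULL
}

.solution <- function(w, design, status, zero_below = 1e-4) {
  w[w < zero_below] <- 0
  resid <- as.numeric(crossprod(design$maps, w)) - design$obs
  structure(list(weights = w, selected = which(w > 0),
                 objective = sum(resid^2), status = status),
            class = "occupancy_solution")
}

#' @export
print.occupancy_solution <- function(x, ...) {
  cat("Occupancy solution:", length(x$selected), "of", length(x$weights),
      "candidates selected;", "rss =", format(x$objective, digits = 6),
      "\n")
  if (length(x$selected))
    cat("  weights:", paste(format(x$weights[x$selected], digits = 3),
                            collapse = ", "),
        " (sum", format(sum(x$weights), digits = 3), ")\n")
  invisible(x)
}

#' Occupancy estimation by quadratic programming
#'
#' Finds the global minimizer of `||rho_calc' w - rho_obs||^2` subject to
#' `w >= 0` and `sum(w) <= 1`, i.e. the conformer weights that jointly best
#' explain the observed density without exceeding full occupancy. Solved by
#' accelerated projected gradient with an exact active-set polish; weights
#' below `1e-4` are zeroed.
#'
#' @param design an [occupancy_design()].
#' @param tol KKT residual tolerance (relative to the data scale).
#' @return object of class `occupancy_solution` with `weights`, `selected`,
#'   `objective` (residual sum of squares), `status`.
#' @export
solve_qp <- function(design, tol = 1e-8) {
  stopifnot(inherits(design, "occupancy_design"))
  design <- .design_gram(design)
  c0 <- as.numeric(design$maps %*% design$obs)
  res <- .qp_solve_core(design$gram, c0, cap = 1, tol = tol)
  if (res$status != "optimal")
    stop("QP did not converge to the requested KKT tolerance (status: ",
         res$status, ")")
  .solution(res$w, design, res$status)
}

#' Parsimonious conformer selection by exact MIQP
#'
#' Minimizes the same residual as [solve_qp()] subject to a cardinality
#' constraint (at most `cardinality` conformers with nonzero weight) and a
#' minimum-occupancy floor: every selected weight lies in
#' `[t_min, 1]`, enforced through the mixed-integer constraint
#' `z_i t_min <= w_i <= z_i`, `z_i` binary. Solved exactly by enumerating
#' all supports of size `<= cardinality`, each as a closed-form
#' box-and-sum-constrained QP; ties between equal-objective supports break
#' to the lexicographically smallest index set.
#'
#' @param design an [occupancy_design()].
#' @param cardinality maximum number of selected conformers (3 for X-ray
#'   and event maps, 2 for cryo-EM).
#' @param t_min minimum occupancy of any selected conformer (default 0.20).
#' @return an `occupancy_solution`; every nonzero weight is `>= t_min` and
#'   at most `cardinality` weights are nonzero.
#' @export
solve_miqp <- function(design, cardinality = 3, t_min = 0.20) {
  stopifnot(inherits(design, "occupancy_design"))
  n <- nrow(design$maps)
  if (cardinality < 1) stop("cardinality must be >= 1")
  cardinality <- min(cardinality, n)
  if (t_min <= 0 || t_min >= 1) stop("t_min must be in (0, 1)")
  design <- .design_gram(design)
  c0 <- as.numeric(design$maps %*% design$obs)
  bsq <- sum(design$obs^2)
  res <- cpp_miqp_enum(design$gram, c0, bsq, t_min, as.integer(cardinality))
  .solution(res$weights, design, "optimal", zero_below = 0)
}

#' Screen a candidate pool by batched QP
#'
#' Large candidate pools are screened in batches: each batch is solved as
#' a QP against the observed density, candidates with nonzero weight
#' survive, and all survivors are pooled and re-solved once globally. This
#' bounds the Gram matrix size for pools of several thousand conformers
#' while restoring global optimality among survivors; the surviving set is
#' typically small (tens of conformers) and is not hard-capped. Design
#' rows are built batch by batch, and when the footprint mask exceeds
#' `max_screen_voxels` the screening uses a deterministic stride
#' subsample of it, keeping time and memory bounded for wide ensembles.
#'
#' @param conformers candidate [conformer()] list.
#' @param topology shared [ligand_topology()].
#' @param obs observed [density_grid()].
#' @param mask [footprint_mask()] on `obs`.
#' @param resolution nominal resolution (Angstrom).
#' @param scale observed/calculated scale factor (see
#'   [scale_calc_to_obs()]).
#' @param batch_size batch size (default 300).
#' @param tol KKT tolerance passed to [solve_qp()].
#' @param max_screen_voxels mask subsampling threshold.
#' @return list with `survivors` (indices into the pool) and `solution`
#'   (the final pooled `occupancy_solution` over the survivors).
#' @export
qp_screen <- function(conformers, topology, obs, mask, resolution,
                      scale = 1, batch_size = 300, tol = 1e-8,
                      max_screen_voxels = 20000) {
  if (length(conformers) == 0) stop("no candidate conformers")
  n <- length(conformers)
  midx <- as.integer(mask)
  if (length(midx) > max_screen_voxels) {
    stride <- ceiling(length(midx) / max_screen_voxels)
    midx <- midx[seq(1, length(midx), by = stride)]
  }
  smask <- structure(midx, grid_dim = dim(obs$values),
                     class = "footprint_mask")
  batch_design <- function(idx)
    occupancy_design(conformers[idx], topology, obs, smask, resolution,
                     scale = scale)
  if (n <= batch_size) {
    des <- batch_design(seq_len(n))
    sol <- solve_qp(des, tol = tol)
    surv <- sol$selected
    if (length(surv) == 0)
      surv <- which.max(as.numeric(des$maps %*% des$obs))
    return(list(survivors = surv,
                solution = solve_qp(.design_subset(des, surv), tol = tol)))
  }
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  surv <- unlist(lapply(batches, function(idx) {
    sol <- solve_qp(batch_design(idx), tol = tol)
    idx[sol$selected]
  }), use.names = FALSE)
  if (length(surv) == 0) surv <- 1L
  surv <- sort(surv)
  des <- batch_design(surv)
  list(survivors = surv, solution = solve_qp(des, tol = tol))
}

.design_subset <- function(design, idx) {
  structure(list(maps = design$maps[idx, , drop = FALSE],
                 obs = design$obs, gram = NULL),
            class = "occupancy_design")
}
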