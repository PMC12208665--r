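# The end-to-end multiconformer fit: sample -> deduplicate -> QP screen ->
# rigid perturbation -> QP -> MIQP -> cull -> validate, returned as a
# classed model object with the usual methods.

#' Fit a multiconformer ligand model to a density map
#'
#' Runs the full pipeline: biased conformer sampling around the input
#' ligand, RMSD deduplication, batched QP screening of the candidate pool
#' against the observed density, rigid-body enrichment of the survivors,
#' a second QP, and final cardinality-constrained MIQP selection (at most
#' 3 conformers for X-ray/event maps, 2 for cryo-EM, each with occupancy
#' at least `t_min`). Conformers below the occupancy floor are culled and
#' the survivors are relabeled altloc A, B, C by descending occupancy.
#' For PanDDA event maps, final occupancies are scaled by `(1 - bdc)`,
#' the estimated bound-state fraction.
#'
#' @param structure path to a PDB/PDBx-mmCIF file, or a list with
#'   `topology` and `conformer` (as returned by [load_ligand()]).
#' @param map path to a CCP4/MRC map, or a [density_grid()].
#' @param smiles ligand SMILES bond-order template (required when
#'   `structure` is a file path).
#' @param selection ligand selection `"CHAIN,RESNUM"` (file input only).
#' @param resolution nominal map resolution in Angstrom (required unless
#'   the grid already carries one).
#' @param mode `"xray"` (default), `"event"` (PanDDA event map; supply
#'   `bdc`), or `"cryoem"` (cardinality 2).
#' @param bdc background density correction factor in `[0, 1)`; event
#'   mode only.
#' @param n_conformers sampling budget override (default 5000 below 25
#'   heavy atoms, 7000 otherwise).
#' @param flip enable 180-degree flip sampling.
#' @param t_min minimum occupancy of a selected conformer (default 0.20).
#' @param cardinality maximum conformer count; defaults by mode.
#' @param occupancy_floor post-selection cull threshold (default 0.1).
#' @param mask_radius footprint mask radius in Angstrom (default 1.5).
#' @param batch_size QP screening batch size (default 300).
#' @param seed integer seed governing all randomness.
#' @param cores worker processes for strategy-parallel sampling (max 5;
#'   never changes the result).
#' @return an object of class `mcligand` with `print`, `summary`, `coef`
#'   (occupancies), `predict` (model density), `residuals`, `plot` and
#'   `simulate` methods.
#' @examples
#' \donttest{
#' ar <- fixture_ligands()[[3]]
#' case <- benchmark_case(ar, 0.5, 0.5, 1.0)
#' fit <- mcligand(list(topology = ar$topology,
#'                      conformer = ar$conformer_a),
#'                 build_truth_map(case), resolution = 1.0,
#'                 n_conformers = 300, seed = 7)
#' coef(fit)
#' }
#' @export
mcligand <- function(structure, map, smiles = NULL, selection = NULL,
                     resolution = NULL,
                     mode = c("xray", "event", "cryoem"), bdc = NULL,
                     n_conformers = NULL, flip = FALSE, t_min = 0.20,
                     cardinality = NULL, occupancy_floor = 0.1,
                     mask_radius = 1.5, batch_size = 300, seed = 1L,
                     cores = 1L) {
  mode <- match.arg(mode)
  cl <- match.call()
  timings <- c()
  tick <- function(stage, t0) {
    timings[[stage]] <<- round(as.numeric(Sys.time()) - t0, 3)
  }
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    tick(name, t0)
    out
  }
  if (mode == "event") {
    if (is.null(bdc)) stop("event mode requires a BDC value")
    if (bdc < 0 || bdc >= 1) stop("BDC must be in [0, 1)")
  }
  cardinality <- cardinality %||% if (mode == "cryoem") 2L else 3L

  lig <- stage("load", {
    if (is.character(structure)) {
      if (is.null(smiles) || is.null(selection))
        stop("file input requires `smiles` and `selection`")
      load_ligand(structure, selection, smiles)
    } else structure
  })
  topology <- lig$topology
  seed_conf <- lig$conformer
  obs <- stage("map", {
    g <- if (is.character(map)) read_map(map, resolution %||% NA_real_)
         else map
    if (!is.finite(g$resolution %||% NA_real_)) {
      if (is.null(resolution)) stop("resolution required")
      g$resolution <- resolution
    }
    g
  })
  resolution <- obs$resolution

  plan <- build_plan(topology, n_override = n_conformers, flip = flip,
                     seed = seed)
  pool <- stage("sample",
                sample_conformers(plan, topology, seed_conf, cores = cores))
  pool <- stage("dedup", deduplicate(pool, threshold = 0.2,
                                     seed = seed + 77L))
  mask <- stage("mask", footprint_mask(pool, obs, radius = mask_radius))

  # common observed/calculated scale from the input conformer at full
  # occupancy
  seed_row <- .density_rows(list(seed_conf), topology, obs, mask,
                            resolution)[1, ]
  den <- sum(seed_row^2)
  if (den == 0) stop("[scale] input conformer has no density on the mask")
  s <- sum(seed_row * obs$values[as.integer(mask)]) / den

  scr <- stage("qp_screen",
               qp_screen(pool, topology, obs, mask, resolution,
                         scale = s, batch_size = batch_size))
  survivors <- pool[scr$survivors]

  enriched <- stage("perturb", perturb_conformers(survivors))
  scr2 <- stage("qp",
                qp_screen(enriched, topology, obs, mask, resolution,
                          scale = s, batch_size = batch_size))
  keep2 <- scr2$survivors
  final_pool <- enriched[keep2]
  design3 <- stage("design",
                   occupancy_design(final_pool, topology, obs, mask,
                                    resolution, scale = s))
  sol <- stage("miqp", solve_miqp(design3, cardinality = cardinality,
                                  t_min = t_min))
  sel <- sol$selected
  weights <- sol$weights[sel]
  model <- final_pool[sel]
  if (length(model) == 0) {
    # degenerate map: fall back to the input conformer at its solo QP
    # weight so the output is never empty
    w1 <- min(1, max(0, sum(seed_row * s * obs$values[as.integer(mask)]) /
                       max(sum((seed_row * s)^2), 1e-300)))
    model <- list(seed_conf)
    weights <- w1
    warning("no conformer met the selection constraints; ",
            "returning the input conformer")
  }
  for (i in seq_along(model)) model[[i]]$occupancy <- weights[i]
  model <- cull_low_occupancy(model, floor = occupancy_floor)
  ord <- order(vapply(model, `[[`, numeric(1), "occupancy"),
               decreasing = TRUE)
  model <- model[ord]
  for (i in seq_along(model)) model[[i]]$altloc <- LETTERS[i]

  final_mask <- footprint_mask(model, obs, radius = mask_radius)
  report <- stage("validate",
                  validation_report(model, topology, obs, final_mask,
                                    resolution))
  if (mode == "event") {
    for (i in seq_along(model))
      model[[i]]$occupancy <- model[[i]]$occupancy * (1 - bdc)
  }

  structure(list(
    conformers = model,
    occupancies = vapply(model, `[[`, numeric(1), "occupancy"),
    provenance = vapply(model, `[[`, character(1), "source"),
    topology = topology,
    input_conformer = seed_conf,
    obs = obs, mask = final_mask, resolution = resolution,
    scale = s, objective = sol$objective, solution = sol,
    report = report, plan = plan,
    pool_size = length(pool), screen_survivors = length(scr$survivors),
    config = list(mode = mode, bdc = bdc, t_min = t_min,
                  cardinality = cardinality,
                  occupancy_floor = occupancy_floor,
                  mask_radius = mask_radius, seed = seed, flip = flip),
    structure_file = if (is.character(structure)) structure else NULL,
    selection = selection,
    timings = timings, call = cl
  ), class = "mcligand")
}

#' Cull low-occupancy conformers
#'
#' Removes conformers with occupancy below the floor; surviving
#' occupancies are left unchanged (occupancy redistribution is the job of
#' downstream refinement). A single conformer below the floor is retained
#' with a warning so the model is never empty.
#'
#' @param model list of [conformer()] objects (occupancies set) or an
#'   `mcligand` fit.
#' @param floor occupancy threshold (default 0.1).
#' @return same type as the input, with the culled conformers removed.
#' @export
cull_low_occupancy <- function(model, floor = 0.1) {
  if (inherits(model, "mcligand")) {
    model$conformers <- cull_low_occupancy(model$conformers, floor)
    model$occupancies <- vapply(model$conformers, `[[`, numeric(1),
                                "occupancy")
    return(model)
  }
  occ <- vapply(model, `[[`, numeric(1), "occupancy")
  keep <- occ >= floor
  if (!any(keep)) {
    warning("all conformers below the occupancy floor; retaining the ",
            "highest-occupancy one")
    keep <- seq_along(model) == which.max(occ)
  }
  model[keep]
}

# ---- methods --------------------------------------------------------------

#' @export
print.mcligand <- function(x, ...) {
  cat("Multiconformer ligand model (", x$config$mode, " mode)\n", sep = "")
  cat(sprintf("  %d conformer(s) from a pool of %d (screened to %d)\n",
              length(x$conformers), x$pool_size, x$screen_survivors))
  for (cf in x$conformers)
    cat(sprintf("    altloc %s  occupancy %.3f  [%s]\n",
                cf$altloc, cf$occupancy, cf$source))
  cat(sprintf("  sum of occupancies: %.3f\n", sum(x$occupancies)))
  cat(sprintf("  RSCC %.4f | EDIAm %.4f | rss %.4g\n",
              x$report$rscc, x$report$ediam, x$objective))
  invisible(x)
}

#' @export
summary.mcligand <- function(object, ...) {
  structure(list(fit = object), class = "summary.mcligand")
}

#' @export
print.summary.mcligand <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nSampling plan:\n")
  print(f$plan$allocation)
  cat(sprintf("\nScale (calc -> obs): %.4g; mask: %d voxels\n",
              f$scale, length(f$mask)))
  cat("Per-atom EDIA (model conformers x atoms):\n")
  print(round(f$report$per_atom_edia, 3))
  cat("\nStage timings (s):\n")
  print(unlist(f$timings))
  invisible(x)
}

#' Occupancies of the fitted conformers
#' @param object an `mcligand` fit.
#' @param ... unused.
#' @return named numeric vector (names = altloc labels).
#' @export
coef.mcligand <- function(object, ...) {
  setNames(object$occupancies,
           vapply(object$conformers, `[[`, character(1), "altloc"))
}

#' Calculated density of the fitted model
#' @param object an `mcligand` fit.
#' @param grid optional [density_grid()] whose geometry to reuse
#'   (default: the observed map's grid).
#' @param ... unused.
#' @return a [density_grid()] of the occupancy-weighted model density on
#'   the observed scale.
#' @export
predict.mcligand <- function(object, grid = NULL, ...) {
  g <- calc_density(object$conformers,
                    vapply(object$conformers, `[[`, numeric(1),
                           "occupancy"),
                    object$topology, object$resolution,
                    grid = grid %||% object$obs)
  .grid_set_values(g, g$values * object$scale)
}

#' Masked residuals of the fit
#' @param object an `mcligand` fit.
#' @param ... unused.
#' @return numeric vector: observed minus scaled calculated density at the
#'   masked voxels.
#' @export
residuals.mcligand <- function(object, ...) {
  calc <- predict(object)
  idx <- as.integer(object$mask)
  as.numeric(object$obs$values[idx]) - as.numeric(calc$values[idx])
}

#' Observed-versus-calculated density plot
#' @param x an `mcligand` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mcligand <- function(x, ...) {
  calc <- predict(x)
  idx <- as.integer(x$mask)
  xv <- as.numeric(calc$values[idx])
  yv <- as.numeric(x$obs$values[idx])
  graphics::plot(xv, yv, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "calculated density (scaled)",
                 ylab = "observed density", ...)
  graphics::abline(0, 1, col = "grey40", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("RSCC = %.3f", x$report$rscc))
  invisible(x)
}

#' Simulate replicate noisy maps from the fitted model
#'
#' Draws maps from the fitted multiconformer density using the synthetic
#' benchmark's noise model (Gaussian noise with sd
#' `alpha * d_min * sigma_clean`).
#'
#' @param object an `mcligand` fit.
#' @param nsim number of replicate maps.
#' @param seed integer seed.
#' @param alpha noise scale per Angstrom of d_min (default 0.05).
#' @param ... unused.
#' @return list of [density_grid()] objects of length `nsim`.
#' @export
simulate.mcligand <- function(object, nsim = 1, seed = 1L, alpha = 0.05,
                              ...) {
  clean <- predict(object)
  sd_noise <- alpha * object$resolution * clean$sigma
  set.seed(seed)
  lapply(seq_len(nsim), function(i)
    .grid_set_values(clean, clean$values +
      array(rnorm(length(clean$values), 0, sd_noise),
            dim(clean$values))))
}

#' Write the fitted model to PDB files
#'
#' Writes the ligand-only multiconformer PDB and, when the fit originated
#' from a structure file, the full structure with the multiconformer
#' ligand embedded (everything outside the ligand residue untouched).
#'
#' @param fit an `mcligand` fit.
#' @param ligand_file output path for the ligand-only multiconformer PDB.
#' @param model_file optional output path for the embedded full model
#'   (requires file-based input).
#' @return invisibly, the paths written.
#' @export
write_multiconformer <- function(fit, ligand_file, model_file = NULL) {
  stopifnot(inherits(fit, "mcligand"))
  sel <- if (!is.null(fit$selection)) .parse_selection(fit$selection)
         else list(chain = "A", resno = 1L)
  .write_ligand_pdb(fit$topology, fit$conformers, ligand_file,
                    chain = sel$chain, resno = sel$resno)
  written <- ligand_file
  if (!is.null(model_file)) {
    if (is.null(fit$structure_file))
      stop("embedded output requires file-based input")
    .embed_model(fit$structure_file, fit$selection, fit$topology,
                 fit$conformers, model_file)
    written <- c(written, model_file)
  }
  invisible(written)
}
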