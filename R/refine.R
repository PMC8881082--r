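# --- rigid-body pose parameterization -------------------------------------
#
# A pose is 3 rotation angles (radians) about axes parallel to x, y, z through
# the model centroid, followed by 3 translations (Angstrom). Perturbations of
# a pre-oriented model are small, so the three rotations are nearly orthogonal
# parameters.

rot_matrix <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid-body pose to a model
#'
#' Rotates about the model centroid (angles about x, y, z axes, applied in
#' that order), then translates.
#'
#' @param model an `mr_model`.
#' @param rot 3 rotation angles (radians).
#' @param trans 3 translations (Angstrom).
#' @return the moved model.
#' @export
apply_pose <- function(model, rot = c(0, 0, 0), trans = c(0, 0, 0)) {
  xyz <- model_xyz(model)
  ctr <- model$center
  xyz <- sweep(xyz, 2, ctr) %*% t(rot_matrix(rot))
  xyz <- sweep(xyz, 2, ctr + trans, `+`)
  set_model_xyz(model, xyz)
}

# --- scoring context -------------------------------------------------------
#
# Bundles everything fixed during refinement: the cell, the Fourier-term list,
# the normalized target E-values and their shells, and the (error-weighted)
# model whose pose is being refined. Model E-values are recomputed and
# renormalized at each trial pose; target normalization stays fixed.

sf_context <- function(target, model, d_min = 2, pad = 10, n_shells = 20,
                       min_terms = 50, max_grid_points = 2^24,
                       sf_method = "auto") {
  cell <- build_cell(target, model, d_min = d_min, pad = pad,
                     max_grid_points = max_grid_points)
  terms <- make_hkl(cell)
  sft <- compute_structure_factors(target, cell, terms, method = sf_method)
  shell <- shell_index(terms$s, n_shells, min_terms)
  ms <- tapply(Mod(sft$F)^2, shell, mean)
  if (any(ms <= 1e-20)) stop_rellg("target has a powerless shell", "degenerate")
  env <- new.env(parent = emptyenv())
  env$cell <- cell; env$terms <- terms; env$shell <- shell
  env$Et <- sft$F / sqrt(ms)[shell]
  env$model <- model
  env$sf_method <- sf_method
  env$shells <- data.frame(n = as.integer(table(shell)),
                           s_mean = as.numeric(tapply(terms$s, shell, mean)))
  env$n_eval <- 0L
  env
}

# normalized model E-values at a trial pose
ctx_model_E <- function(ctx, rot = c(0, 0, 0), trans = c(0, 0, 0)) {
  m <- if (all(rot == 0) && all(trans == 0)) ctx$model else
    apply_pose(ctx$model, rot, trans)
  sfm <- compute_structure_factors(m, ctx$cell, ctx$terms, method = ctx$sf_method)
  ms <- tapply(Mod(sfm$F)^2, ctx$shell, mean)
  if (any(!is.finite(ms)) || any(ms <= 1e-20))
    stop_rellg("model shell power vanished (fully downweighted?)", "degenerate")
  ctx$n_eval <- ctx$n_eval + 1L
  sfm$F / sqrt(ms)[ctx$shell]
}

ctx_llg <- function(ctx, pose, rmsd) {
  Em <- ctx_model_E(ctx, pose[1:3], pose[4:6])
  llg_total(ctx$Et, Em, ctx$terms$s, rmsd)
}

# 1-D refinement of the rmsd parameter on a log scale, E-values fixed
refine_rmsd_1d <- function(ctx, Em, bounds = c(0.05, 10)) {
  f <- function(lr) -llg_total(ctx$Et, Em, ctx$terms$s, exp(lr))
  opt <- optimize(f, interval = log(bounds), tol = 1e-6)
  list(rmsd = exp(opt$minimum), llg = -opt$objective)
}

#' Phased rigid-body refinement of a model against a target
#'
#' Maximizes the phased log-likelihood-gain over the model's rigid-body pose
#' (6 parameters; quasi-Newton with central-difference numerical gradients)
#' alternating with 1-D refinement of the radial rmsd parameter behind the
#' sigmaA curve (on a log scale, bounded to `[0.05, 10]` Angstrom), until the
#' LLG improves by less than `tol` nats or `max_cycles` is reached. The
#' starting model must already be near the correct overlap (pre-oriented);
#' this is a local optimization, not a molecular-replacement search.
#'
#' @param ctx a scoring context from `sf_context()` (internal), or see
#'   [rellg()] for the user-level entry point.
#' @param rmsd0 starting rmsd (Angstrom); e.g. the model's median error
#'   estimate when available, else 1.
#' @param tol convergence threshold on the LLG change per cycle (nats).
#' @param max_cycles maximum alternation cycles.
#' @param pose_maxit BFGS iteration cap per pose block.
#' @param step_t,step_r central-difference steps for translations (Angstrom)
#'   and rotations (radians).
#' @param refine_pose set FALSE to refine only the rmsd parameter.
#' @return list with `rot`, `trans`, `rmsd`, `llg`, `converged`, `trace`
#'   (per-cycle data frame), and `Em` (normalized model E-values at the final
#'   pose).
#' @keywords internal
refine_rigid <- function(ctx, rmsd0 = 1, tol = 0.01, max_cycles = 20,
                         pose_maxit = 25, step_t = 1e-3, step_r = 1e-4,
                         refine_pose = TRUE) {
  pose <- rep(0, 6)
  Em <- ctx_model_E(ctx)
  st <- refine_rmsd_1d(ctx, Em)
  rmsd <- st$rmsd; llg <- st$llg
  llg0 <- llg
  trace <- data.frame(cycle = 0L, llg = llg, rmsd = rmsd,
                      dtrans = 0, drot = 0)
  converged <- FALSE
  steps <- c(rep(step_r, 3), rep(step_t, 3))
  for (cyc in seq_len(max_cycles)) {
    llg_prev <- llg
    if (refine_pose) {
      fn <- function(p) -ctx_llg(ctx, p, rmsd)
      gr <- function(p) {
        g <- numeric(6)
        for (i in 1:6) {
          e <- numeric(6); e[i] <- steps[i]
          g[i] <- (fn(p + e) - fn(p - e)) / (2 * steps[i])
        }
        g
      }
      # the first cycle does the real pose work; later cycles only polish
      # after the sigmaA update, so a short quasi-Newton run suffices
      maxit <- if (cyc == 1) pose_maxit else max(5L, pose_maxit %/% 5L)
      opt <- optim(pose, fn, gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10,
                                  parscale = c(rep(0.01, 3), rep(1, 3))))
      if (-opt$value >= llg) { pose <- opt$par; llg <- -opt$value }
    }
    Em <- ctx_model_E(ctx, pose[1:3], pose[4:6])
    st <- refine_rmsd_1d(ctx, Em)
    if (st$llg >= llg) { rmsd <- st$rmsd; llg <- st$llg }
    trace <- rbind(trace, data.frame(cycle = cyc, llg = llg, rmsd = rmsd,
                                     dtrans = sqrt(sum(pose[4:6]^2)),
                                     drot = sqrt(sum(pose[1:3]^2))))
    if (llg - llg_prev < tol) { converged <- TRUE; break }
  }
  # contract: never return a state worse than the start
  if (llg < llg0) { pose <- rep(0, 6); rmsd <- trace$rmsd[1]; llg <- llg0 }
  list(rot = pose[1:3], trans = pose[4:6], rmsd = rmsd, llg = llg,
       converged = converged, trace = trace,
       Em = ctx_model_E(ctx, pose[1:3], pose[4:6]))
}
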