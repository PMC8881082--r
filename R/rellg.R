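#' Fourier shell correlation between normalized structure-factor sets
#'
#' FSC_k = sum over shell of Re(E_t conj(E_m)) / sqrt(sum |E_t|^2 sum |E_m|^2).
#' For scoring, negative values are clamped to zero (the eLLG theory assumes a
#' non-negative correlation and FSC^4 would otherwise reward anti-correlation)
#' and values are capped at one; the raw value is kept for diagnostics.
#'
#' @param E a normalized set from [normalize_to_E()] (fields `Et`, `Em`,
#'   `shell`, `shells`), or a list with those fields.
#' @return data frame with per-shell `n`, `s_mean`, `fsc` (clamped), and
#'   `fsc_raw`.
#' @export
fsc_curve <- function(E) {
  num <- tapply(Re(E$Et * Conj(E$Em)), E$shell, sum)
  d1 <- tapply(Mod(E$Et)^2, E$shell, sum)
  d2 <- tapply(Mod(E$Em)^2, E$shell, sum)
  raw <- as.numeric(num / sqrt(d1 * d2))
  data.frame(n = E$shells$n, s_mean = E$shells$s_mean,
             fsc = pmin(pmax(raw, 0), 1), fsc_raw = raw)
}

#' Expected LLG accumulated from an FSC curve
#'
#' eLLG = sum over shells of n_k FSC_k^4 / 2, the expected log-likelihood-gain
#' of a likelihood-based MR search with this model.
#'
#' @param curve data frame from [fsc_curve()] (columns `n`, `fsc`).
#' @return eLLG in nats (non-negative).
#' @examples
#' ellg_from_fsc(data.frame(n = c(100, 200), fsc = c(0.5, 0.8)))  # 44.085
#' @export
ellg_from_fsc <- function(curve) {
  f <- pmin(pmax(curve$fsc, 0), 1)
  sum(curve$n * f^4 / 2)
}

#' Expected LLG of the ideally imperfect model
#'
#' The eLLG a complete model with radial RMS coordinate error `rmsd`
#' (0.4 Angstrom by default: the best one can hope for from an independent
#' high-resolution structure determination of the same protein) would achieve
#' on the same Fourier-term set. Accumulated per term -- sigmaA evaluated at
#' each term's s rather than at shell means -- so the normalization constant
#' carries no binning sensitivity.
#'
#' @param s vector of term resolutions (1/Angstrom), e.g. from `make_hkl()`.
#' @param rmsd reference radial RMS error (Angstrom).
#' @param fp fraction of the target explained.
#' @return eLLG in nats.
#' @export
ideal_ellg <- function(s, rmsd = 0.4, fp = 1) sum(sigma_a(rmsd, s, fp)^4 / 2)

zero_result <- function(reason, call, weighting) {
  structure(list(rellg = 0, ellg = 0, ellg_ideal = NA_real_, fsc = NULL,
                 rot = rep(NA_real_, 3), trans = rep(NA_real_, 3),
                 rmsd = NA_real_, llg = NA_real_, converged = FALSE,
                 n_terms = 0L, d_min = NA_real_, weighting = weighting,
                 failure = reason, trace = NULL, call = call),
            class = "rellg")
}

#' Relative expected log-likelihood-gain of a model for molecular replacement
#'
#' Scores a predicted model against a target structure: both are placed in a
#' common virtual cell, normalized structure factors are computed to `d_min`,
#' the model pose and the radial rmsd parameter behind sigmaA are refined
#' against the phased LLG, and the expected LLG accumulated from the Fourier
#' shell correlation is divided by the eLLG of the ideally imperfect model
#' (complete, radial rmsd 0.4 Angstrom) on the same term set. The result is
#' independent of crystal form and of the size of the target.
#'
#' Failures that the scoring policy maps to a zero score (oversize grids from
#' unfolded chains, fully downweighted models, unreadable or empty models) are
#' caught and returned as zero-score results with the reason recorded in
#' `$failure`; they do not raise errors.
#'
#' @param target target structure: an `mr_model` or a PDB path (B-factor
#'   column kept as true B-factors).
#' @param model predicted model: an `mr_model` or a PDB path. When a path is
#'   given, the B-field is read as RMS error estimates if
#'   `weighting = "error"`, as B-factors otherwise.
#' @param weighting `"error"` (convert per-atom RMS error estimates to
#'   B-factors -- the primary mode), `"constant"` (set all B to
#'   `constant_b`), or `"as_is"` (use the B-field unchanged).
#' @param constant_b constant B (Angstrom^2) for `weighting = "constant"`.
#' @param d_min high-resolution limit (Angstrom).
#' @param pad virtual-cell padding (Angstrom).
#' @param n_shells,min_terms resolution-shell layout.
#' @param superpose pre-superpose the model onto the target via matched
#'   C-alpha atoms (default FALSE: models are assumed pre-oriented).
#' @param prune optional RMS-error threshold (Angstrom): residues with larger
#'   error estimates are removed before scoring (`weighting = "error"` only).
#' @param refine_pose refine the rigid-body pose (default TRUE); the rmsd
#'   parameter is always refined.
#' @param rmsd0 starting rmsd; default: median error estimate if available,
#'   else 1 Angstrom.
#' @param tol,max_cycles,pose_maxit refinement controls (see `refine_rigid`).
#' @param max_grid_points oversize bound on the virtual-cell grid.
#' @param sf_method structure-factor path: `"auto"`, `"direct"` or `"fft"`.
#' @return an object of class `rellg` with components `rellg`, `ellg`,
#'   `ellg_ideal`, `fsc` (per-shell data frame), `rmsd`, `rot`, `trans`,
#'   `llg`, `converged`, `n_terms`, `failure` (NULL on success), `trace`.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `plot`.
#' @examples
#' tgt <- make_toy_structure(12, "helix", seed = 1)
#' mdl <- degrade(tgt, radial_rmsd = 0.4, seed = 2)
#' fit <- rellg(tgt, mdl, weighting = "error")
#' fit
#' coef(fit)
#' @export
rellg <- function(target, model, weighting = c("error", "constant", "as_is"),
                  constant_b = 25, d_min = 2, pad = 10, n_shells = 20,
                  min_terms = 50, superpose = FALSE, prune = NULL,
                  refine_pose = TRUE, rmsd0 = NULL, tol = 0.01,
                  max_cycles = 20, pose_maxit = 25, max_grid_points = 2^24,
                  sf_method = "auto") {
  weighting <- match.arg(weighting)
  cl <- match.call()
  out <- tryCatch({
    if (is.character(target)) target <- read_model(target, "b_factor")
    if (is.character(model))
      model <- read_model(model, if (weighting == "error") "rms_error" else "b_factor")
    if (target$bfield_mode != "b_factor")
      target <- apply_error_weighting(target, "error")
    if (!is.null(prune) && model$bfield_mode == "rms_error")
      model <- prune_by_rmsd(model, prune)
    if (is.null(rmsd0))
      rmsd0 <- if (model$bfield_mode == "rms_error")
        max(stats::median(model$atoms$bfield), 0.05) else 1
    model <- switch(weighting,
      error = apply_error_weighting(model, "error"),
      constant = apply_error_weighting(model, "constant", constant_b = constant_b),
      as_is = {
        if (model$bfield_mode != "b_factor")
          stop_rellg("weighting = 'as_is' requires B-factor mode", "mode_mismatch")
        model
      })
    if (superpose) model <- superpose(model, target)
    ctx <- sf_context(target, model, d_min = d_min, pad = pad,
                      n_shells = n_shells, min_terms = min_terms,
                      max_grid_points = max_grid_points, sf_method = sf_method)
    fit <- refine_rigid(ctx, rmsd0 = rmsd0, tol = tol, max_cycles = max_cycles,
                        pose_maxit = pose_maxit, refine_pose = refine_pose)
    E <- list(Et = ctx$Et, Em = fit$Em, s = ctx$terms$s, shell = ctx$shell,
              shells = ctx$shells)
    fsc <- fsc_curve(E)
    ellg <- ellg_from_fsc(fsc)
    ideal <- ideal_ellg(ctx$terms$s, rmsd = 0.4)
    structure(list(rellg = ellg / ideal, ellg = ellg, ellg_ideal = ideal,
                   fsc = fsc, rot = fit$rot, trans = fit$trans,
                   rmsd = fit$rmsd, llg = fit$llg, converged = fit$converged,
                   n_terms = length(ctx$terms$s), d_min = d_min,
                   weighting = weighting, failure = NULL, trace = fit$trace,
                   call = cl),
              class = "rellg")
  },
  rellg_oversize = function(e) zero_result(conditionMessage(e), cl, weighting),
  rellg_degenerate = function(e) zero_result(conditionMessage(e), cl, weighting),
  rellg_empty_model = function(e) zero_result(conditionMessage(e), cl, weighting),
  rellg_input = function(e) zero_result(conditionMessage(e), cl, weighting))
  out
}

#' @export
print.rellg <- function(x, digits = 4, ...) {
  if (!is.null(x$failure)) {
    cat("reLLG: 0 (failed: ", x$failure, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("reLLG = %.*f  (eLLG %.1f / ideal %.1f, %d terms to %.2f A)\n",
              digits, x$rellg, x$ellg, x$ellg_ideal, x$n_terms, x$d_min))
  cat(sprintf("refined rmsd %.3f A, phased LLG %.1f, %sconverged, weighting '%s'\n",
              x$rmsd, x$llg, if (x$converged) "" else "NOT ", x$weighting))
  invisible(x)
}

#' @export
summary.rellg <- function(object, ...) {
  structure(list(fit = object), class = "summary.rellg")
}

#' @export
print.summary.rellg <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$fsc)) {
    cat("\nFourier shell correlation:\n")
    df <- x$fit$fsc
    df$d <- 1 / df$s_mean
    print(data.frame(shell = seq_len(nrow(df)), d_A = round(df$d, 2),
                     n = df$n, fsc = round(df$fsc, 4)), row.names = FALSE)
    cat(sprintf("\npose: rot (%.4f, %.4f, %.4f) rad, trans (%.3f, %.3f, %.3f) A\n",
                x$fit$rot[1], x$fit$rot[2], x$fit$rot[3],
                x$fit$trans[1], x$fit$trans[2], x$fit$trans[3]))
  }
  invisible(x)
}

#' @export
coef.rellg <- function(object, ...) {
  c(rmsd = object$rmsd,
    rot_x = object$rot[1], rot_y = object$rot[2], rot_z = object$rot[3],
    trans_x = object$trans[1], trans_y = object$trans[2], trans_z = object$trans[3])
}

#' @export
logLik.rellg <- function(object, ...) {
  structure(object$llg, df = 7L, nobs = object$n_terms, class = "logLik")
}

#' Plot the FSC curve of a fitted reLLG score
#'
#' Per-shell Fourier shell correlation against resolution, with the sigmaA
#' curve implied by the refined rmsd parameter overlaid.
#'
#' @param x an `rellg` object.
#' @param ... passed to `plot()`.
#' @export
plot.rellg <- function(x, ...) {
  if (is.null(x$fsc)) {
    warning("no FSC curve: scoring failed (", x$failure, ")")
    return(invisible(x))
  }
  plot(x$fsc$s_mean, x$fsc$fsc, ylim = c(0, 1), pch = 19,
       xlab = expression(s ~ (ring(A)^-1)), ylab = "FSC", ...)
  ss <- seq(0, max(x$fsc$s_mean), length.out = 200)
  lines(ss, sigma_a(x$rmsd, ss), lty = 2)
  legend("topright", bty = "n",
         legend = c("FSC", sprintf("sigmaA(rmsd = %.2f A)", x$rmsd)),
         pch = c(19, NA), lty = c(NA, 2))
  invisible(x)
}
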