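#' Build a virtual P1 cell enclosing target and model
#'
#' Target and model are placed in a single orthogonal box (a "crystal" with no
#' symmetry): the bounding box of the union of their coordinates plus `pad` on
#' every side, with grid dimensions rounded up to FFT-friendly sizes at a
#' spacing of `d_min / 4` (comfortably finer than the usual anti-aliasing
#' requirement). The construction is deterministic given its inputs.
#'
#' @param target,model `mr_model` objects.
#' @param d_min high-resolution limit (Angstrom), default 2.
#' @param pad padding per side (Angstrom); 10 by default, several times
#'   `d_min`, so periodic-image density overlap is negligible.
#' @param max_grid_points refuse cells whose grid exceeds this many points
#'   (an extremely extended "model" -- e.g. an unfolded chain -- produces an
#'   oversize error which callers map to a zero score).
#' @return an object of class `virtual_cell`: list with `abc` (box lengths),
#'   `ngrid`, `origin` (Cartesian corner), `d_min`.
#' @export
build_cell <- function(target, model, d_min = 2, pad = 10,
                       max_grid_points = 2^24) {
  xyz <- rbind(model_xyz(target), model_xyz(model))
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  abc <- (hi - lo) + 2 * pad
  spacing <- d_min / 4
  ngrid <- vapply(ceiling(abc / spacing), fft_friendly, integer(1))
  if (prod(ngrid) > max_grid_points)
    stop_rellg(sprintf("grid %d x %d x %d exceeds the memory bound",
                       ngrid[1], ngrid[2], ngrid[3]), "oversize")
  structure(list(abc = abc, ngrid = ngrid, origin = lo - pad, d_min = d_min),
            class = "virtual_cell")
}

# smallest integer >= n whose prime factors are all <= 7
fft_friendly <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Unique Fourier terms (one Friedel representative) with 0 < s <= 1/d_min.
# Returns list(hkl, s) sorted by s.
make_hkl <- function(cell) {
  hmax <- floor(cell$abc / cell$d_min)
  h <- seq.int(-hmax[1], hmax[1]); k <- seq.int(-hmax[2], hmax[2])
  l <- seq.int(0, hmax[3])  # Friedel half-space: l >= 0
  g <- expand.grid(h = h, k = k, l = l)
  keep <- g$l > 0 | (g$l == 0 & (g$k > 0 | (g$k == 0 & g$h > 0)))
  g <- g[keep, , drop = FALSE]
  s2 <- (g$h / cell$abc[1])^2 + (g$k / cell$abc[2])^2 + (g$l / cell$abc[3])^2
  keep <- s2 <= (1 / cell$d_min)^2 + 1e-12
  g <- g[keep, , drop = FALSE]; s2 <- s2[keep]
  o <- order(s2)
  list(hkl = as.matrix(g)[o, , drop = FALSE], s = sqrt(s2[o]))
}

#' Compute structure factors of a model in a virtual cell
#'
#' Structure factors F(h) = sum over atoms of
#' occ * f_elem(s) * exp(-B s^2 / 4) * exp(2 pi i h . x_frac), with standard
#' Gaussian-sum atomic scattering factors. Two paths are provided: exact
#' direct summation (the oracle, and the default for small systems) and an
#' FFT over sampled smeared density (for large systems). The FFT path smears
#' every atom by an extra B of `b_extra` before sampling and removes the
#' smearing in reciprocal space, keeping aliasing error well below the 0.5%
#' agreement contract between the two paths.
#'
#' @param structure an `mr_model` with `bfield_mode == "b_factor"` (error
#'   weighting must already have been applied).
#' @param cell a `virtual_cell` from [build_cell()].
#' @param terms optional term list from `make_hkl(cell)` (recomputed if NULL).
#' @param method `"direct"`, `"fft"`, or `"auto"` (direct up to 5000 atoms).
#' @param b_extra anti-aliasing smearing B for the FFT path (Angstrom^2).
#' @return list with `hkl`, `s`, and complex `F`.
#' @export
compute_structure_factors <- function(structure, cell, terms = NULL,
                                      method = c("auto", "direct", "fft"),
                                      b_extra = 20) {
  method <- match.arg(method)
  if (structure$bfield_mode != "b_factor")
    stop_rellg("structure factors require B-factor mode (apply error weighting first)",
               "mode_mismatch")
  if (is.null(terms)) terms <- make_hkl(cell)
  a <- structure$atoms
  elem <- ff_index(a$element)
  if (method == "auto") method <- if (nrow(a) <= 5000) "direct" else "fft"
  if (method == "direct") {
    frac <- sweep(model_xyz(structure), 2, cell$origin) / rep(cell$abc, each = nrow(a))
    F <- sf_direct_cpp(terms$hkl, terms$s^2, frac, a$occ, a$bfield, elem, .ff_table)
  } else {
    stopifnot(b_extra >= 5)  # keeps every sampled Gaussian wide enough
    xyz <- sweep(model_xyz(structure), 2, cell$origin)
    xyz <- xyz %% rep(cell$abc, each = nrow(a))
    # the constant form-factor term rides on a Gaussian of width exactly
    # b_extra + B (bc = 0), which the unsmearing then removes exactly
    rho <- density_grid_cpp(xyz, a$occ, a$bfield + b_extra, elem, .ff_table,
                            cell$abc, cell$ngrid, bc = 0, logtol = log(1e8))
    Fg <- stats::fft(rho, inverse = TRUE) * prod(cell$abc) / prod(cell$ngrid)
    idx <- cbind(terms$hkl[, 1] %% cell$ngrid[1],
                 terms$hkl[, 2] %% cell$ngrid[2],
                 terms$hkl[, 3] %% cell$ngrid[3]) + 1L
    F <- Fg[idx] * exp(b_extra * terms$s^2 / 4)
  }
  list(hkl = terms$hkl, s = terms$s, F = F)
}

# equal-count resolution shells; returns integer shell index per term
shell_index <- function(s, n_shells, min_terms = 50) {
  n <- length(s)
  n_shells <- max(1L, min(n_shells, n %/% max(min_terms, 1L)))
  # s is sorted; split into nearly equal blocks
  idx <- ceiling(seq_along(s) / (n / n_shells))
  as.integer(pmin(idx, n_shells))
}

#' Normalize two structure-factor sets to E-values on shared shells
#'
#' Each set is divided by its own shell-wise RMS amplitude so the mean-squared
#' E is one within every shell, separately for target and model. Shells hold
#' (nearly) equal numbers of terms.
#'
#' @param sf_t,sf_m outputs of [compute_structure_factors()] on the same term
#'   list (target and model).
#' @param n_shells number of resolution shells (default 20; reduced if needed
#'   to keep at least `min_terms` terms per shell).
#' @param min_terms minimum terms per shell.
#' @return list with complex `Et`, `Em`, `s`, `shell` (index per term), and
#'   `shells` (data frame: `n`, `s_mean`).
#' @export
normalize_to_E <- function(sf_t, sf_m, n_shells = 20, min_terms = 50) {
  stopifnot(length(sf_t$F) == length(sf_m$F))
  shell <- shell_index(sf_t$s, n_shells, min_terms)
  norm1 <- function(F) {
    ms <- tapply(Mod(F)^2, shell, mean)
    if (any(!is.finite(ms)) || any(ms <= 1e-20))
      stop_rellg("a resolution shell has (near-)zero power; model fully downweighted?",
                 "degenerate")
    F / sqrt(ms)[shell]
  }
  list(Et = norm1(sf_t$F), Em = norm1(sf_m$F), s = sf_t$s, shell = shell,
       shells = data.frame(n = as.integer(table(shell)),
                           s_mean = as.numeric(tapply(sf_t$s, shell, mean))))
}
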