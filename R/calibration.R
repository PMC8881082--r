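# Identity -> VRMS calibration constants. The exponential has the classic
# coordinate-divergence form vrms = A * exp(slope * (1 - identity)); the two
# constants are anchored so that a complete model of a 175-residue protein at
# 100% sequence identity has VRMS 0.4 Angstrom (the ideally imperfect model,
# reLLG = 1) and 30% identity translates to reLLG 0.091 at the 2 Angstrom
# limit (vrms 1.160985 Angstrom). The size correction scales like a radius of
# gyration, (n_res / 175)^(1/3).
.vrms_ref <- 0.4
.vrms_slope <- 1.5222279
.vrms_nref <- 175

#' Expected coordinate error (VRMS) from sequence identity
#'
#' Translates fractional sequence identity into the effective radial RMS
#' coordinate error (VRMS) expected for a complete model, with a molecule-size
#' correction. Calibrated so that identity 1.0 at 175 residues gives 0.4
#' Angstrom.
#'
#' @param identity fractional sequence identity in (0, 1].
#' @param n_res number of residues (> 0).
#' @return VRMS in Angstrom (vectorized over `identity`).
#' @examples
#' vrms_from_seqid(1.0, 175)   # 0.4
#' vrms_from_seqid(0.3, 175)   # ~1.16
#' @export
vrms_from_seqid <- function(identity, n_res = 175) {
  if (any(!is.finite(identity)) || any(identity <= 0) || any(identity > 1))
    stop_rellg("identity must lie in (0, 1]", "domain")
  if (any(n_res <= 0)) stop_rellg("n_res must be positive", "domain")
  .vrms_ref * exp(.vrms_slope * (1 - identity)) * (n_res / .vrms_nref)^(1 / 3)
}

# integral_0^S s^2 exp(-k s^2) ds with k = 8 pi^2/3 vrms^2 (sigmaA^4 weight),
# in closed form via the error function
.ellg_integral <- function(vrms, s_max) {
  k <- 8 * pi^2 / 3 * vrms^2
  if (k < 1e-12) return(s_max^3 / 3)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  (sqrt(pi / k) * erf(sqrt(k) * s_max) - 2 * s_max * exp(-k * s_max^2)) / (4 * k)
}

#' Analytic reLLG implied by a single-Gaussian coordinate-error model
#'
#' If all coordinate errors are drawn from one 3D Gaussian with radial RMS
#' `vrms`, the eLLG is proportional to the integral of s^2 sigmaA(vrms, s)^4
#' over s up to 1/d_min (the s^2 weight is the density of Fourier terms in a
#' fixed cell). The reLLG is that integral divided by the same integral at
#' the reference rmsd of 0.4 Angstrom; by construction
#' `rellg_analytic(0.4) == 1`.
#'
#' @param vrms radial RMS coordinate error (Angstrom), > 0.
#' @param d_min high-resolution limit (Angstrom).
#' @return the analytic reLLG (vectorized over `vrms`).
#' @examples
#' rellg_analytic(0.4)                            # 1
#' rellg_analytic(vrms_from_seqid(0.3, 175))      # ~0.091
#' @export
rellg_analytic <- function(vrms, d_min = 2) {
  if (any(!is.finite(vrms)) || any(vrms <= 0))
    stop_rellg("vrms must be positive", "domain")
  s_max <- 1 / d_min
  vapply(vrms, .ellg_integral, numeric(1), s_max = s_max) /
    .ellg_integral(.vrms_ref, s_max)
}

#' Sequence-identity to reLLG calibration curve
#'
#' Tabulates, over a grid of sequence identities, the implied VRMS and the
#' analytic reLLG for a complete model of `n_res` residues.
#'
#' @param identity grid of fractional sequence identities.
#' @param n_res residue count.
#' @param d_min high-resolution limit (Angstrom).
#' @return data frame with columns `identity`, `vrms`, `rellg`.
#' @export
calibration_curve <- function(identity = seq(0.1, 1, by = 0.01), n_res = 175,
                              d_min = 2) {
  v <- vrms_from_seqid(identity, n_res)
  data.frame(identity = identity, vrms = v, rellg = rellg_analytic(v, d_min))
}
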