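#' The sigmaA curve implied by a radial coordinate-error parameter
#'
#' sigmaA(rmsd; s) = fp * exp(-2 pi^2 / 3 * rmsd^2 * s^2): the resolution
#' -dependent complex correlation between normalized structure factors of
#' model and target when coordinate errors are drawn from a single 3D
#' Gaussian with radial RMS `rmsd`, and the model accounts for a fraction
#' `fp` of the target (taken as one throughout this package).
#'
#' @param rmsd radial RMS coordinate error (Angstrom), >= 0.
#' @param s magnitude of the diffraction vector, 1/d (1/Angstrom); vectorized.
#' @param fp fraction of the target explained by the model.
#' @return sigmaA values in (0, fp].
#' @examples
#' sigma_a(0.4, 0.5)   # at the 2 Angstrom limit
#' @export
sigma_a <- function(rmsd, s, fp = 1) {
  stopifnot(rmsd >= 0, all(s >= 0), fp > 0, fp <= 1)
  fp * exp(-2 * pi^2 / 3 * rmsd^2 * s^2)
}

#' Phased log-likelihood-gain contribution of single Fourier terms
#'
#' The contribution of one term to the phased LLG, derived from the
#' conditional complex-normal distribution of the target E-value given the
#' model E-value:
#' \deqn{[2 E_t \sigma_A E_m \cos\Delta\phi - \sigma_A^2 (E_t^2 + E_m^2)] /
#'       (1 - \sigma_A^2) - \ln(1 - \sigma_A^2)}
#' At sigmaA = 0 the conditional distribution collapses to the Wilson null and
#' the gain is zero. Values of sigmaA at or above one (the degenerate
#' perfect-correlation limit) are clamped just below one with a warning.
#'
#' @param e_t,e_m complex normalized structure factors (vectorized).
#' @param sig_a sigmaA, in `[0, 1)`; scalar or per-term.
#' @return per-term LLG contributions (nats).
#' @examples
#' llg_term(1 + 0i, 1 + 0i, 0.5)    #  0.9543
#' llg_term(1 + 0i, -1 + 0i, 0.5)   # -1.7123 (anti-phase penalty)
#' @export
llg_term <- function(e_t, e_m, sig_a) {
  if (any(sig_a >= 1)) {
    warning("sigmaA >= 1 clamped below one")
    sig_a <- pmin(sig_a, 1 - 1e-6)
  }
  stopifnot(all(sig_a >= 0))
  et2 <- Mod(e_t)^2; em2 <- Mod(e_m)^2
  cross <- Re(e_t * Conj(e_m))               # Et Em cos(dphi)
  (2 * sig_a * cross - sig_a^2 * (et2 + em2)) / (1 - sig_a^2) - log1p(-sig_a^2)
}

# total phased LLG over all terms for a given rmsd parameter
llg_total <- function(e_t, e_m, s, rmsd, fp = 1)
  sum(llg_term(e_t, e_m, sigma_a(rmsd, s, fp)))
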