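# --- synthetic coordinate and score fixtures ------------------------------
#
# Everything the test-suite and demos need is generated in code: toy
# protein-like backbones, controlled Gaussian degradations with error-estimate
# profiles, and score tables with planted group skills. All randomness sits
# behind explicit seeds on a private RNG stream.

#' Generate a toy protein-like structure
#'
#' Backbone (N, CA, C, O) plus CB coordinates for one chain. `"helix"` uses
#' ideal alpha-helix geometry (rise 1.5 Angstrom and 100 degrees per residue
#' on a 2.3 Angstrom C-alpha radius, giving the canonical 3.8 Angstrom
#' CA-CA distance); `"sheet-pair"` builds two packed antiparallel strands;
#' `"random-coil"` is a seeded 3.8 Angstrom-step random walk of the C-alpha
#' trace (compact, unlike the rod-like helix). Deterministic for a given
#' seed.
#'
#' @param n_res number of residues (>= 5).
#' @param motif `"helix"`, `"sheet-pair"`, or `"random-coil"`.
#' @param seed RNG seed (only the coil uses randomness).
#' @return an `mr_model` (bfield 0, B-factor mode, chain A, residues ALA).
#' @export
make_toy_structure <- function(n_res, motif = c("helix", "sheet-pair", "random-coil"),
                               seed = 1) {
  motif <- match.arg(motif)
  if (n_res < 5) stop_rellg("n_res must be >= 5", "domain")
  ca <- switch(motif,
    helix = {
      th <- (seq_len(n_res) - 1) * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n_res) - 1))
    },
    `sheet-pair` = {
      n1 <- ceiling(n_res / 2); n2 <- n_res - n1
      s1 <- cbind(3.3 * (seq_len(n1) - 1), 0.5 * (-1)^(seq_len(n1)), 0)
      s2 <- cbind(3.3 * (n2 - seq_len(n2)), 0.5 * (-1)^(seq_len(n2)), 4.8)
      rbind(s1, s2)
    },
    `random-coil` = with_seed(seed, {
      dirs <- matrix(rnorm(3 * (n_res - 1)), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      apply(rbind(c(0, 0, 0), 3.8 * dirs), 2, cumsum)
    }))
  # place N, C, O, CB at fixed offsets in a local frame that follows the trace
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    e1 <- if (i < n_res) ca[i + 1, ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
    e1 <- e1 / sqrt(sum(e1^2))
    up <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e2 <- up - sum(up * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    off <- rbind(N = -1.45 * e1 + 0.4 * e2, CA = c(0, 0, 0),
                 C = 1.52 * e1 + 0.3 * e2, O = 1.8 * e1 + 1.3 * e2,
                 CB = -0.5 * e1 - 1.3 * e2 + 0.8 * e3)
    data.frame(element = c("N", "C", "C", "O", "C"),
               name = c("N", "CA", "C", "O", "CB"), resid = "ALA",
               chain = "A", resseq = i, icode = "",
               x = ca[i, 1] + off[, 1], y = ca[i, 2] + off[, 2],
               z = ca[i, 3] + off[, 3], occ = 1, bfield = 0,
               stringsAsFactors = FALSE)
  }))
  new_model(atoms, "b_factor")
}

#' Degrade a structure into a synthetic "predicted model"
#'
#' Displaces every atom by iid 3D Gaussian noise (per-axis sigma =
#' radial_rmsd / sqrt(3), realizing the single-Gaussian error model behind
#' sigmaA), optionally applies a rigid pose perturbation, and writes an
#' RMS-error estimate profile into the B-field:
#' `"truthful"` stores each atom's true expected radial error, `"constant"`
#' one shared value (the RMS of the profile), `"misleading"` a shuffled copy
#' of the truthful profile. Reproducible: same inputs and seed give the same
#' model.
#'
#' @param target an `mr_model`.
#' @param radial_rmsd radial RMS displacement (Angstrom); scalar, or one
#'   value per atom for spatially varying noise.
#' @param rot,trans rigid pose perturbation applied after the noise
#'   (radians / Angstrom).
#' @param fidelity error-estimate profile written to the B-field.
#' @param seed RNG seed.
#' @return an `mr_model` with `bfield_mode = "rms_error"`.
#' @export
degrade <- function(target, radial_rmsd = 0, rot = c(0, 0, 0),
                    trans = c(0, 0, 0),
                    fidelity = c("truthful", "constant", "misleading"),
                    seed = 1) {
  fidelity <- match.arg(fidelity)
  n <- nrow(target$atoms)
  sig <- rep(radial_rmsd, length.out = n) / sqrt(3)
  out <- with_seed(seed, {
    xyz <- model_xyz(target) + matrix(rnorm(3 * n, sd = rep(sig, 3)), ncol = 3)
    m <- set_model_xyz(target, xyz)
    m <- apply_pose(m, rot, trans)
    m$atoms$bfield <- switch(fidelity,
      truthful = sig * sqrt(3),
      constant = rep(sqrt(mean(3 * sig^2)), n),
      misleading = sample(sig * sqrt(3)))
    m
  })
  out$bfield_mode <- "rms_error"
  out
}

#' Generate a score table with planted group skills
#'
#' Scores follow `skill[group] + difficulty[target] + noise`, five models per
#' (group, target) with a small decrement per model rank so model #1 is the
#' best; GDT_HA values are a monotone transform of the same signal. Supports
#' injection of missing (group, target) pairs. The planted skill order is the
#' ground truth that ranking should recover.
#'
#' @param n_groups,n_targets table dimensions.
#' @param skill_step skill separation between consecutive groups (group 1
#'   strongest).
#' @param noise_sd score noise SD.
#' @param missing optional data frame with columns `group`, `target`: pairs
#'   to drop.
#' @param seed RNG seed.
#' @return data frame with columns `group`, `target`, `model`, `gdt_ha`,
#'   `score`, `variant`, plus attribute `"skills"` (the planted values).
#' @export
make_score_table <- function(n_groups = 8, n_targets = 6, skill_step = 10,
                             noise_sd = 0, missing = NULL, seed = 1) {
  groups <- sprintf("G%02d", seq_len(n_groups))
  targets <- sprintf("T%02d", seq_len(n_targets))
  skills <- setNames(skill_step * (n_groups - seq_len(n_groups)), groups)
  tab <- with_seed(seed, {
    diff <- setNames(rnorm(n_targets, 0, 5), targets)
    g <- expand.grid(group = groups, target = targets, model = 1:5,
                     stringsAsFactors = FALSE)
    base <- skills[g$group] + diff[g$target] - 2 * (g$model - 1)
    g$score <- base + rnorm(nrow(g), 0, noise_sd)
    g$gdt_ha <- pmin(100, pmax(0, 30 + 0.5 * g$score + rnorm(nrow(g), 0, noise_sd)))
    g$variant <- "error_weighted"
    g
  })
  if (!is.null(missing))
    tab <- tab[!(paste(tab$group, tab$target) %in%
                   paste(missing$group, missing$target)), , drop = FALSE]
  attr(tab, "skills") <- skills
  tab
}
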